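#' Configuration bundle for the full two-arm experiment
#'
#' Defaults define the desk-scale synthetic study: 200 images at 64 x 64 in
#' the four-category mix of a DR grading cohort (52/12/4/32%), split
#' 75/8/17% stratified by category, one FCN training run, run-once fusion,
#' and three classifier trials per arm with distinct seeds.
#'
#' @param counts_per_category images per category 0..3.
#' @param size image side length in pixels.
#' @param fractions train/val/test fractions.
#' @param n_trials classifier trials per arm.
#' @param master_seed single seed from which all stage seeds derive.
#' @param seg named list of [seg_config()] overrides for the desk-scale
#'   segmenter.
#' @param cls named list of [cls_config()] overrides for the classifiers.
#' @param seg_train_n,seg_val_n images sampled (from classifier-training
#'   rows only) for segmentation training/validation.
#' @param lesion_density see [lesion_density_defaults()].
#' @return an `exp_config` list.
#' @export
exp_config <- function(counts_per_category = c(104, 24, 8, 64), size = 64,
                       fractions = c(0.75, 0.08, 0.17), n_trials = 3,
                       master_seed = 1L,
                       seg = list(), cls = list(),
                       seg_train_n = 40, seg_val_n = 5,
                       lesion_density = lesion_density_defaults()) {
  seg_defaults <- list(epochs = 50, learning_rate = 0.05, decay = 0.98,
                       dropout = 0.1, image_size = size, backbone_width = 8,
                       upsample_stride = 2, upsample_filter = 4,
                       pos_weight = 12)
  cls_defaults <- list(epochs = 24, learning_rate = 0.02, decay = 0.99,
                       dropout = 0.1, image_size = size, backbone_width = 12,
                       batch_size = 5)
  structure(list(counts_per_category = counts_per_category, size = size,
                 fractions = fractions, n_trials = n_trials,
                 master_seed = as.integer(master_seed),
                 seg = utils::modifyList(seg_defaults, seg),
                 cls = utils::modifyList(cls_defaults, cls),
                 seg_train_n = seg_train_n, seg_val_n = seg_val_n,
                 lesion_density = lesion_density), class = "exp_config")
}

new_trial_report <- function(arm, trials, per_category_auc, confusion) {
  structure(list(arm = arm, trials = trials,
                 per_trial_accuracy = trials$accuracy,
                 mean_accuracy = mean(trials$accuracy),
                 sd_accuracy = sd(trials$accuracy),
                 per_category_auc = per_category_auc,
                 confusion = confusion), class = "trial_report")
}

#' @export
print.trial_report <- function(x, ...) {
  cat(sprintf("Trial report [%s]: mean accuracy %.4f (SD %.4f) over %d trials\n",
              x$arm, x$mean_accuracy, x$sd_accuracy, nrow(x$trials)))
  cat("  per-category AUC:",
      paste(sprintf("%d: %.3f", 0:3, x$per_category_auc), collapse = ", "),
      "\n")
  invisible(x)
}

run_arm <- function(arm, manifest, cls_over, n_trials, trial_seeds,
                    input_channels) {
  trials <- list()
  aucs <- matrix(NA_real_, n_trials, 4)
  confusions <- list()
  test_rows <- manifest[manifest$split == "test", ]
  for (tr in seq_len(n_trials)) {
    cfg <- do.call(cls_config, c(cls_over,
                                 list(rng_seed = trial_seeds[tr],
                                      input_channels = input_channels)))
    fit <- train_classifier(manifest, cfg)
    preds <- predict_batch(fit$model, test_rows)
    cm <- confusion(preds, test_rows$category)
    confusions[[tr]] <- cm
    for (k in 0:3) {
      truths <- test_rows$category == k
      if (any(truths) && !all(truths)) {
        aucs[tr, k + 1] <- auc_ovr(preds[[paste0("p", k)]], truths)
      }
    }
    trials[[tr]] <- tibble::tibble(trial = tr, seed = trial_seeds[tr],
                                   accuracy = accuracy(cm))
  }
  new_trial_report(arm, dplyr::bind_rows(trials),
                   colMeans(aucs, na.rm = TRUE), confusions[[1]])
}

#' Run the full baseline-versus-assisted experiment
#'
#' Generates (or accepts) a dataset, assigns stratified splits, trains the
#' FCN once on a segmentation subset drawn from classifier-training rows
#' only, fuses probability maps once into a provenance-checked cache, then
#' runs `n_trials` classifier trials per arm (baseline: 3-channel RGB;
#' assisted: 4-channel fused) with distinct seeds, and compares the arms
#' with Welch's t-test. Deterministic given `master_seed`.
#'
#' @param config an [exp_config()].
#' @param work_dir directory for the dataset, fused cache and reports
#'   (default: a temporary directory).
#' @param manifest optional pre-built manifest (with masks); skips dataset
#'   generation.
#' @return an `experiment_result`: list with `baseline` and `assisted`
#'   `trial_report`s, `comparison` (an `arm_comparison`), `segmentation`
#'   (a `seg_metrics` on the test rows), `seg_history`, and `manifest`.
#' @export
run_experiment <- function(config = exp_config(), work_dir = tempfile(),
                           manifest = NULL) {
  stopifnot(inherits(config, "exp_config"))
  dir.create(work_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- withr::with_seed(config$master_seed,
                            sample.int(1e6, 4 + 2 * config$n_trials))
  data_seed <- seeds[1]; split_seed <- seeds[2]
  seg_pick_seed <- seeds[3]; seg_seed <- seeds[4]
  base_seeds <- seeds[4 + seq_len(config$n_trials)]
  asst_seeds <- seeds[4 + config$n_trials + seq_len(config$n_trials)]

  if (is.null(manifest)) {
    manifest <- generate_dataset(config$counts_per_category, data_seed,
                                 config$size,
                                 file.path(work_dir, "images"),
                                 config$lesion_density)
  }
  manifest <- assign_splits(manifest,
                            split_spec(config$fractions, TRUE, split_seed))

  # Segmentation subset: classifier-training rows only, half of them NV.
  train_rows <- manifest[manifest$split == "train", ]
  n_seg <- min(config$seg_train_n + config$seg_val_n, nrow(train_rows))
  seg_rows <- withr::with_seed(seg_pick_seed, {
    nv <- train_rows[train_rows$category == 3, ]
    other <- train_rows[train_rows$category != 3, ]
    n_nv <- min(nrow(nv), ceiling(n_seg / 2))
    picked <- dplyr::bind_rows(nv[sample.int(nrow(nv), n_nv), ],
                               other[sample.int(nrow(other),
                                                n_seg - n_nv), ])
    picked <- picked[sample.int(nrow(picked)), ]
    picked$split <- rep(c("train", "val"),
                        c(nrow(picked) - config$seg_val_n,
                          config$seg_val_n))
    picked
  })
  seg_cfg <- do.call(seg_config, c(config$seg, list(rng_seed = seg_seed)))
  seg_fit <- train_fcn(seg_rows, seg_cfg)

  fused <- batch_fuse(manifest, seg_fit$model,
                      file.path(work_dir, "fused"))

  # Segmentation quality on the classification test rows (never seen by
  # the FCN) plus image-level presence accuracy.
  test_rows <- fused[fused$split == "test", ]
  maps <- lapply(seq_len(nrow(test_rows)), function(i) {
    img <- read_fundus_png(test_rows$image_path[i], test_rows$image_id[i])
    predict_map(seg_fit$model, extract_green(img))
  })
  truths <- lapply(test_rows$mask_path, read_mask_png)
  segm <- seg_metrics(maps, truths, threshold = seg_cfg$threshold)

  baseline <- run_arm("baseline", fused, config$cls, config$n_trials,
                      base_seeds, 3L)
  assisted <- run_arm("assisted", fused, config$cls, config$n_trials,
                      asst_seeds, 4L)
  comparison <- compare_arms(baseline$per_trial_accuracy,
                             assisted$per_trial_accuracy)

  structure(list(baseline = baseline, assisted = assisted,
                 comparison = comparison, segmentation = segm,
                 seg_history = seg_fit$history, manifest = fused,
                 config = config, work_dir = work_dir),
            class = "experiment_result")
}

#' @export
print.experiment_result <- function(x, ...) {
  print(x$baseline); print(x$assisted); print(x$comparison)
  cat(sprintf("Segmentation (test rows): mean Dice %.4f, mean IOU %.4f, presence accuracy %.4f\n",
              x$segmentation$mean_dice, x$segmentation$mean_iou,
              x$segmentation$presence_accuracy))
  invisible(x)
}

#' Write experiment reports to disk
#'
#' Emits `report.json` (per-trial accuracies, means, SDs, improvement and
#' the t-test), `auc_table.csv` (categories 0..3 by baseline/assisted),
#' and per-arm confusion matrices as CSV.
#'
#' @param result an `experiment_result`.
#' @param out_dir output directory.
#' @return `out_dir`, invisibly.
#' @export
write_experiment_reports <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(
    baseline = list(per_trial_accuracy = result$baseline$per_trial_accuracy,
                    mean_accuracy = result$baseline$mean_accuracy,
                    sd_accuracy = result$baseline$sd_accuracy),
    assisted = list(per_trial_accuracy = result$assisted$per_trial_accuracy,
                    mean_accuracy = result$assisted$mean_accuracy,
                    sd_accuracy = result$assisted$sd_accuracy),
    comparison = unclass(result$comparison),
    segmentation = list(mean_dice = result$segmentation$mean_dice,
                        mean_iou = result$segmentation$mean_iou,
                        presence_accuracy =
                          result$segmentation$presence_accuracy))
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  auc_tab <- tibble::tibble(category = 0:3,
                            baseline = result$baseline$per_category_auc,
                            segmentation_assisted =
                              result$assisted$per_category_auc)
  readr::write_csv(auc_tab, file.path(out_dir, "auc_table.csv"))
  for (arm in c("baseline", "assisted")) {
    cm <- as.data.frame(unclass(result[[arm]]$confusion))
    utils::write.csv(cm, file.path(out_dir, paste0("confusion_", arm,
                                                   ".csv")))
  }
  invisible(out_dir)
}
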
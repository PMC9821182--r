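# A miniature end-to-end run: small dataset, short training. This checks the
# pipeline contract (structure, determinism, reporting), not classification
# quality — that lives in the acceptance suite.

mini_config <- function(master_seed = 1) {
  exp_config(counts_per_category = c(8, 4, 3, 7), size = 64,
             n_trials = 2, master_seed = master_seed,
             seg = list(epochs = 2, backbone_width = 4),
             cls = list(epochs = 2, backbone_width = 4),
             seg_train_n = 6, seg_val_n = 2)
}

res <- run_experiment(mini_config(), work_dir = file.path(tempdir(), "mini"))

test_that("the experiment emits both arms' reports with n_trials entries", {
  expect_s3_class(res$baseline, "trial_report")
  expect_s3_class(res$assisted, "trial_report")
  expect_length(res$baseline$per_trial_accuracy, 2)
  expect_length(res$assisted$per_trial_accuracy, 2)
  expect_true(all(res$baseline$per_trial_accuracy >= 0 &
                    res$baseline$per_trial_accuracy <= 1))
  expect_equal(res$comparison$improvement,
               res$assisted$mean_accuracy - res$baseline$mean_accuracy)
  expect_equal(sum(res$baseline$confusion),
               sum(res$manifest$split == "test"))
})

test_that("reported SD is the sample (n-1) standard deviation", {
  acc <- res$baseline$per_trial_accuracy
  expect_equal(res$baseline$sd_accuracy,
               sqrt(sum((acc - mean(acc))^2) / (length(acc) - 1)))
})

test_that("segmentation metrics cover exactly the test rows", {
  expect_equal(nrow(res$segmentation$per_image),
               sum(res$manifest$split == "test"))
  expect_true(all(res$segmentation$per_image$dice >= 0 &
                    res$segmentation$per_image$dice <= 1))
})

test_that("the same master seed reproduces the experiment", {
  res2 <- run_experiment(mini_config(), work_dir = file.path(tempdir(),
                                                             "mini2"))
  expect_equal(res2$baseline$per_trial_accuracy,
               res$baseline$per_trial_accuracy)
  expect_equal(res2$assisted$per_trial_accuracy,
               res$assisted$per_trial_accuracy)
  expect_equal(res2$comparison$p_value, res$comparison$p_value)
  expect_identical(res2$segmentation$mean_dice, res$segmentation$mean_dice)
})

test_that("reports are written in the documented layout", {
  out <- file.path(tempdir(), "mini_reports")
  write_experiment_reports(res, out)
  rep <- jsonlite::read_json(file.path(out, "report.json"))
  expect_length(rep$baseline$per_trial_accuracy, 2)
  expect_equal(rep$comparison$improvement, res$comparison$improvement,
               tolerance = 1e-12)
  auc_tab <- readr::read_csv(file.path(out, "auc_table.csv"),
                             show_col_types = FALSE)
  expect_equal(auc_tab$category, 0:3, ignore_attr = TRUE)
  expect_identical(names(auc_tab),
                   c("category", "baseline", "segmentation_assisted"))
  expect_true(file.exists(file.path(out, "confusion_baseline.csv")))
})

test_that("tidy and glance summarise the experiment", {
  td <- tidy(res)
  expect_equal(nrow(td), 4)
  expect_setequal(unique(td$arm), c("baseline", "assisted"))
  g <- glance(res)
  expect_identical(nrow(g), 1L)
  expect_true(all(c("improvement", "p_value", "mean_dice") %in% names(g)))
})

test_that("experiment plots build without error", {
  p1 <- autoplot(res)
  expect_s3_class(p1, "ggplot")
  p2 <- plot_confusion(res$baseline$confusion)
  expect_s3_class(p2, "ggplot")
  scores <- c(0.9, 0.3, 0.8, 0.2, 0.7)
  p3 <- autoplot(roc_ovr(scores, c(TRUE, FALSE, TRUE, FALSE, FALSE)))
  expect_s3_class(p3, "ggplot")
})
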
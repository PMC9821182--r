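#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy per-trial accuracies of a trial report
#'
#' @param x a `trial_report`.
#' @param ... unused.
#' @return tibble with one row per trial: arm, trial, seed, accuracy.
#' @export
tidy.trial_report <- function(x, ...) {
  dplyr::mutate(x$trials, arm = x$arm, .before = 1)
}

#' @rdname tidy.trial_report
#' @return for `glance()`: a one-row summary tibble.
#' @export
glance.trial_report <- function(x, ...) {
  tibble::tibble(arm = x$arm, n_trials = nrow(x$trials),
                 mean_accuracy = x$mean_accuracy,
                 sd_accuracy = x$sd_accuracy)
}

#' Tidy an arm comparison
#'
#' @param x an `arm_comparison`.
#' @param ... unused.
#' @return a one-row tibble with the improvement and Welch test summary.
#' @export
tidy.arm_comparison <- function(x, ...) {
  tibble::tibble(improvement = x$improvement, t_statistic = x$t_statistic,
                 df = x$df, p_value = x$p_value, test_kind = x$test_kind,
                 mean_baseline = x$mean_baseline,
                 mean_assisted = x$mean_assisted,
                 sd_baseline = x$sd_baseline, sd_assisted = x$sd_assisted)
}

#' @rdname tidy.arm_comparison
#' @export
glance.arm_comparison <- tidy.arm_comparison

#' Tidy per-image segmentation metrics
#'
#' @param x a `seg_metrics`.
#' @param ... unused.
#' @return the per-image tibble (`tidy`) or a one-row summary (`glance`).
#' @export
tidy.seg_metrics <- function(x, ...) x$per_image

#' @rdname tidy.seg_metrics
#' @export
glance.seg_metrics <- function(x, ...) {
  tibble::tibble(mean_dice = x$mean_dice, mean_iou = x$mean_iou,
                 presence_accuracy = x$presence_accuracy,
                 n_images = nrow(x$per_image))
}

#' Tidy an experiment result
#'
#' @param x an `experiment_result`.
#' @param ... unused.
#' @return `tidy()`: per-trial accuracies of both arms; `glance()`: one row
#'   with both arms' means/SDs and the comparison.
#' @export
tidy.experiment_result <- function(x, ...) {
  dplyr::bind_rows(tidy(x$baseline), tidy(x$assisted))
}

#' @rdname tidy.experiment_result
#' @export
glance.experiment_result <- function(x, ...) {
  dplyr::bind_cols(tidy(x$comparison),
                   glance(x$segmentation)[1:3])
}
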
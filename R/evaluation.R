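#' Confusion matrix of four-category predictions
#'
#' @param preds predictions: an integer vector of predicted categories
#'   (0..3) or a tibble from [predict_batch()].
#' @param truths integer vector of true categories (0..3).
#' @return a `confusion_matrix`: 4 x 4 integer matrix, rows = truth,
#'   columns = predicted.
#' @export
confusion <- function(preds, truths) {
  if (is.data.frame(preds)) preds <- preds$predicted_category
  if (length(preds) != length(truths)) {
    abort("predictions and truths must have equal length.",
          class = "segassist_input_error")
  }
  cm <- table(factor(truths, levels = 0:3), factor(preds, levels = 0:3))
  m <- matrix(as.integer(cm), 4, 4,
              dimnames = list(truth = paste0("truth_", 0:3),
                              predicted = paste0("pred_", 0:3)))
  structure(m, class = c("confusion_matrix", "matrix"))
}

#' Overall accuracy from a confusion matrix
#'
#' @param cm a `confusion_matrix` (or any square count matrix).
#' @return trace / total, a fraction in `[0, 1]`.
#' @export
accuracy <- function(cm) {
  total <- sum(cm)
  if (total == 0) {
    abort("empty confusion matrix.", class = "segassist_input_error")
  }
  sum(diag(unclass(cm))) / total
}

#' One-vs-rest ROC curve and AUC
#'
#' Sweeps every distinct score as a threshold (call positive when
#' `score >= threshold`), from high to low, producing nondecreasing
#' TPR/FPR sequences with both endpoints (0,0) and (1,1). `auc_trapezoid()`
#' integrates the curve; with ties this equals the probability that a
#' random positive outscores a random negative, ties counted one half.
#'
#' @param scores per-image probability of the category of interest.
#' @param truths logical (or 0/1) vector: is the image truly of that
#'   category? Needs at least one positive and one negative.
#' @param category optional category label carried on the curve.
#' @return a `roc_curve` tibble: `threshold`, `tpr`, `fpr`.
#' @export
roc_ovr <- function(scores, truths, category = NA_integer_) {
  truths <- as.logical(truths)
  stopifnot(length(scores) == length(truths))
  n_pos <- sum(truths); n_neg <- sum(!truths)
  if (n_pos == 0 || n_neg == 0) {
    abort("ROC needs at least one positive and one negative.",
          class = "segassist_degenerate_error")
  }
  th <- c(Inf, sort(unique(scores), decreasing = TRUE))
  pts <- purrr::map(th, function(t) {
    call_pos <- scores >= t
    tibble::tibble(threshold = t,
                   tpr = sum(call_pos & truths) / n_pos,
                   fpr = sum(call_pos & !truths) / n_neg)
  })
  out <- dplyr::bind_rows(pts)
  structure(out, class = c("roc_curve", class(out)),
            category = category)
}

#' @rdname roc_ovr
#' @param curve a `roc_curve`.
#' @export
auc_trapezoid <- function(curve) {
  x <- curve$fpr; y <- curve$tpr
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' @rdname roc_ovr
#' @export
auc_ovr <- function(scores, truths) {
  auc_trapezoid(roc_ovr(scores, truths))
}

#' Compare baseline and assisted arms across repeated trials
#'
#' Improvement is the difference of mean accuracies (assisted − baseline);
#' significance uses Welch's two-sample t-test evaluated in closed form
#' (two arms of identical constant accuracies give t = 0, p = 1; unequal
#' constants give p = 0).
#'
#' @param baseline_acc,assisted_acc per-trial accuracies (length >= 2).
#' @return an `arm_comparison` list: `improvement`, `t_statistic`, `df`,
#'   `p_value`, `test_kind`, per-arm means and sample SDs.
#' @export
compare_arms <- function(baseline_acc, assisted_acc) {
  if (length(baseline_acc) < 2 || length(assisted_acc) < 2) {
    abort("each arm needs at least 2 trials.",
          class = "segassist_sample_size_error")
  }
  mb <- mean(baseline_acc); ma <- mean(assisted_acc)
  vb <- stats::var(baseline_acc); va <- stats::var(assisted_acc)
  nb <- length(baseline_acc); na <- length(assisted_acc)
  se2 <- vb / nb + va / na
  if (se2 == 0) {
    t_stat <- 0; df <- NA_real_
    p <- if (ma == mb) 1 else 0
    if (ma != mb) t_stat <- Inf * sign(ma - mb)
  } else {
    t_stat <- (ma - mb) / sqrt(se2)
    df <- se2^2 / ((vb / nb)^2 / (nb - 1) + (va / na)^2 / (na - 1))
    p <- 2 * pt(-abs(t_stat), df)
  }
  structure(list(improvement = ma - mb, t_statistic = t_stat, df = df,
                 p_value = p, test_kind = "welch_two_sample",
                 mean_baseline = mb, mean_assisted = ma,
                 sd_baseline = sd(baseline_acc),
                 sd_assisted = sd(assisted_acc),
                 n_baseline = nb, n_assisted = na),
            class = "arm_comparison")
}

#' @export
print.arm_comparison <- function(x, ...) {
  cat(sprintf(
    "Arm comparison (%s)\n  baseline: mean %.4f (SD %.4f, n=%d)\n  assisted: mean %.4f (SD %.4f, n=%d)\n  improvement: %.4f   t = %.3f, df = %.2f, p = %.4g\n",
    x$test_kind, x$mean_baseline, x$sd_baseline, x$n_baseline,
    x$mean_assisted, x$sd_assisted, x$n_assisted,
    x$improvement, x$t_statistic, x$df, x$p_value))
  invisible(x)
}
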
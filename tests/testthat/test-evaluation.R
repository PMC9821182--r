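test_that("confusion matrices tally truth rows against predicted columns", {
  cm <- confusion(c(0L, 1L, 2L, 3L), c(0L, 1L, 2L, 3L))
  expect_equal(unname(diag(unclass(cm))), rep(1L, 4))
  expect_equal(sum(cm), 4)

  cm2 <- confusion(3L, 1L)
  expect_equal(unname(unclass(cm2)["truth_1", "pred_3"]), 1L)
  expect_equal(sum(cm2), 1)

  set.seed(5)
  truths <- sample(0:3, 10, TRUE)
  preds <- sample(0:3, 10, TRUE)
  cm3 <- unclass(confusion(preds, truths))
  for (t in 0:3) for (p in 0:3) {
    expect_equal(unname(cm3[t + 1, p + 1]), sum(truths == t & preds == p))
  }
  expect_error(confusion(c(1L, 2L), 1L), class = "segassist_input_error")
})

test_that("accuracy is trace over total and matches direct pair counting", {
  expect_equal(accuracy(diag(c(2, 3, 4, 5))), 1)
  m <- matrix(1, 4, 4); diag(m) <- 0
  expect_equal(accuracy(m), 0)

  set.seed(6)
  truths <- sample(0:3, 25, TRUE)
  preds <- sample(0:3, 25, TRUE)
  expect_equal(accuracy(confusion(preds, truths)), mean(preds == truths))
  expect_error(accuracy(matrix(0, 4, 4)), class = "segassist_input_error")
})

test_that("ROC endpoints, monotonicity and canonical AUC values hold", {
  sep <- roc_ovr(c(0.9, 0.8, 0.2, 0.1), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(auc_trapezoid(sep), 1)
  expect_equal(sep$tpr[1], 0); expect_equal(sep$fpr[1], 0)
  expect_equal(sep$tpr[nrow(sep)], 1); expect_equal(sep$fpr[nrow(sep)], 1)
  expect_true(all(diff(sep$tpr) >= 0))
  expect_true(all(diff(sep$fpr) >= 0))

  ties <- roc_ovr(rep(0.5, 6), c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE))
  expect_equal(auc_trapezoid(ties), 0.5)

  mixed <- auc_ovr(c(0.9, 0.8, 0.7, 0.1), c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(mixed, 0.75)

  expect_error(roc_ovr(c(0.1, 0.2), c(TRUE, TRUE)),
               class = "segassist_degenerate_error")
})

test_that("trapezoidal AUC equals pairwise concordance on random score sets", {
  set.seed(7)
  for (k in 1:120) {
    n <- sample(6:20, 1)
    scores <- if (k %% 3 == 0) {
      sample(seq(0, 1, by = 0.25), n, TRUE)  # heavy ties
    } else {
      runif(n)
    }
    truths <- c(TRUE, FALSE, sample(c(TRUE, FALSE), n - 2, TRUE))
    expect_equal(auc_ovr(scores, truths), auc_concordance(scores, truths),
                 tolerance = 1e-9)
  }
})

test_that("our AUC agrees with pROC on a few random inputs", {
  skip_if_not_installed("pROC")
  set.seed(8)
  for (k in 1:5) {
    scores <- runif(30)
    truths <- c(TRUE, FALSE, sample(c(TRUE, FALSE), 28, TRUE))
    ref <- as.numeric(pROC::auc(pROC::roc(truths, scores, quiet = TRUE,
                                          direction = "<")))
    expect_equal(auc_ovr(scores, truths), ref, tolerance = 1e-9)
  }
})

test_that("arm comparison handles identical arms and known summaries", {
  same <- compare_arms(c(0.8, 0.8, 0.8), c(0.8, 0.8, 0.8))
  expect_equal(same$improvement, 0)
  expect_equal(same$t_statistic, 0)
  expect_equal(same$p_value, 1)

  base <- c(77.05, 79.97, 82.89)   # mean 79.97, SD 2.92
  asst <- c(80.00, 87.71, 95.42)   # mean 87.71, SD 7.71
  cmp <- compare_arms(base, asst)
  expect_equal(cmp$improvement, 7.74, tolerance = 1e-9)
  expect_equal(cmp$t_statistic,
               (87.71 - 79.97) / sqrt(sd(base)^2 / 3 + sd(asst)^2 / 3),
               tolerance = 1e-9)
  expect_error(compare_arms(0.5, c(0.6, 0.7)),
               class = "segassist_sample_size_error")
})

test_that("Welch closed form matches stats::t.test and is antisymmetric", {
  set.seed(9)
  for (k in 1:20) {
    a <- runif(sample(3:6, 1))
    b <- runif(sample(3:6, 1))
    cmp <- compare_arms(a, b)
    ref <- t.test(b, a)
    expect_equal(cmp$t_statistic, unname(ref$statistic), tolerance = 1e-9)
    expect_equal(cmp$p_value, ref$p.value, tolerance = 1e-9)
    expect_equal(cmp$df, unname(ref$parameter), tolerance = 1e-9)
    rev <- compare_arms(b, a)
    expect_equal(rev$improvement, -cmp$improvement)
  }
})

test_that("tidiers expose the comparison as tibbles", {
  cmp <- compare_arms(c(0.7, 0.75, 0.8), c(0.85, 0.9, 0.95))
  td <- tidy(cmp)
  expect_s3_class(td, "tbl_df")
  expect_equal(td$improvement, 0.15, tolerance = 1e-12)
  expect_identical(td$test_kind, "welch_two_sample")
})
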
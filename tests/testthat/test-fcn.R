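test_that("config invariants are enforced", {
  expect_error(seg_config(upsample_stride = 3),
               class = "segassist_architecture_error")
  expect_error(seg_config(image_size = 100, upsample_stride = 32),
               class = "segassist_architecture_error")
  expect_error(seg_config(upsample_filter = 16, upsample_stride = 32),
               class = "segassist_architecture_error")
  expect_error(seg_config(upsample_filter = 33, upsample_stride = 32),
               class = "segassist_architecture_error")
  expect_error(seg_config(learning_rate = 0))
  expect_error(seg_config(dropout = 1))
})

test_that("FCN output is H x W x 2 with per-pixel softmax at size 64", {
  cfg <- tiny_seg_config()
  model <- build_fcn(cfg)
  set.seed(1)
  g <- matrix(sample(0:255, 64 * 64, TRUE), 64)
  ns <- asNamespace("segassist")
  fw <- ns$fcn_probs(model, g)
  expect_identical(dim(fw$scores), c(64L, 64L, 2L))
  expect_true(all(abs(apply(fw$probs, c(1, 2), sum) - 1) < 1e-6))
})

test_that("probability maps are bounded, deterministic and shape-checked", {
  cfg <- tiny_seg_config()
  model <- build_fcn(cfg)
  set.seed(2)
  g <- matrix(sample(0:255, 64 * 64, TRUE), 64)
  m1 <- predict_map(model, g)
  m2 <- predict_map(model, g)
  expect_identical(m1$pixels, m2$pixels)
  expect_gte(min(m1$pixels), 0)
  expect_lte(max(m1$pixels), 1)
  expect_identical(dim(m1$pixels), dim(g))
  expect_error(predict_map(model, matrix(0, 32, 32)),
               class = "segassist_shape_error")
})

test_that("decay 1 keeps the learning rate constant; 0 epochs returns init", {
  m <- fixture_dataset(c(1, 0, 0, 2), seed = 51)
  m$split <- c("train", "train", "val")
  fit <- train_fcn(m, tiny_seg_config(decay = 1))
  expect_equal(fit$history$lr, rep(fit$history$lr[1], nrow(fit$history)))

  fit0 <- train_fcn(m, tiny_seg_config(epochs = 0))
  expect_equal(nrow(fit0$history), 0)
  init <- build_fcn(tiny_seg_config(epochs = 0))
  expect_identical(fit0$model$net$layers, init$net$layers)
})

test_that("training is deterministic for a fixed seed and records history", {
  m <- fixture_dataset(c(1, 0, 0, 2), seed = 51)
  m$split <- c("train", "train", "val")
  cfg <- tiny_seg_config(epochs = 3)
  f1 <- train_fcn(m, cfg)
  f2 <- train_fcn(m, cfg)
  expect_identical(f1$model$net$layers, f2$model$net$layers)
  expect_identical(f1$history, f2$history)
  expect_equal(nrow(f1$history), 3)
  expect_true(all(is.finite(f1$history$loss)))
  expect_true(all(f1$history$val_dice >= 0 & f1$history$val_dice <= 1))
})

test_that("training requires rows with masks", {
  m <- fixture_dataset(c(1, 0, 0, 2), seed = 51)
  m$split <- "train"
  m$mask_path <- NA_character_
  expect_error(train_fcn(m, tiny_seg_config()),
               class = "segassist_data_error")
})

test_that("a short training run raises map probability inside the true mask", {
  m <- fixture_dataset(c(0, 0, 0, 3), seed = 61)
  m$split <- "train"
  fit <- train_fcn(m, tiny_seg_config(epochs = 12, backbone_width = 8,
                                      learning_rate = 0.05))
  s <- m[1, ]
  g <- extract_green(read_fundus_png(s$image_path))
  mk <- read_mask_png(s$mask_path)$pixels
  pm <- predict_map(fit$model, g)$pixels
  expect_gt(mean(pm[mk == 1]), mean(pm[mk == 0]))
})

test_that("training loss trends downward on a tiny overfit problem", {
  m <- fixture_dataset(c(0, 0, 0, 3), seed = 61)
  m$split <- "train"
  fit <- train_fcn(m, tiny_seg_config(epochs = 10, backbone_width = 8,
                                      learning_rate = 0.05))
  loss <- fit$history$loss
  expect_lt(mean(loss[6:10]), mean(loss[1:5]))
})
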
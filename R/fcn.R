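#' Configuration for FCN segmentation training
#'
#' Defaults follow the reference training regime for full-scale (512 px)
#' fundus segmentation: 300 epochs, learning rate 0.001 with a per-epoch
#' multiplicative decay of 0.99, dropout 0.5, and a transposed-convolution
#' head with stride 32 and filter size 64 producing an H x W x 2 score map.
#' Desk-scale runs shrink `image_size`, `upsample_stride`/`upsample_filter`
#' and `epochs`.
#'
#' @param epochs training epochs.
#' @param learning_rate initial SGD learning rate (> 0).
#' @param decay multiplicative per-epoch learning-rate factor in (0, 1].
#' @param dropout drop probability in [0, 1), applied before the
#'   transposed-convolution head.
#' @param rng_seed seed for initialisation, shuffling and dropout.
#' @param image_size input side length in pixels.
#' @param backbone_width channel count of the first backbone stage.
#' @param upsample_stride stride of the transposed-convolution head; equals
#'   the backbone's total downsampling factor (a power of 2 dividing
#'   `image_size`).
#' @param upsample_filter kernel size of the transposed convolution
#'   (>= stride, same parity).
#' @param pos_weight loss weight of NV pixels (1 = unweighted); NV regions
#'   are small, so a weight > 1 counters the class imbalance.
#' @param momentum SGD momentum.
#' @param threshold probability cutoff used when binarizing maps for
#'   Dice/IOU.
#' @return a `seg_config` list.
#' @export
seg_config <- function(epochs = 300, learning_rate = 0.001, decay = 0.99,
                       dropout = 0.5, rng_seed = 1L, image_size = 512,
                       backbone_width = 8, upsample_stride = 32,
                       upsample_filter = 64, pos_weight = 1,
                       momentum = 0.9, threshold = 0.5) {
  stopifnot(learning_rate > 0, decay > 0, decay <= 1,
            dropout >= 0, dropout < 1, epochs >= 0, pos_weight > 0)
  s <- upsample_stride
  if (s < 2 || bitwAnd(s, s - 1L) != 0) {
    abort("upsample_stride must be a power of 2.",
          class = "segassist_architecture_error")
  }
  if (image_size %% s != 0) {
    abort("image_size must be divisible by the total downsampling factor.",
          class = "segassist_architecture_error")
  }
  if (upsample_filter < s || (upsample_filter - s) %% 2 != 0) {
    abort("upsample_filter must be >= stride with the same parity.",
          class = "segassist_architecture_error")
  }
  structure(as.list(environment())[c(
    "epochs", "learning_rate", "decay", "dropout", "rng_seed", "image_size",
    "backbone_width", "upsample_stride", "upsample_filter", "pos_weight",
    "momentum", "threshold")], class = "seg_config")
}

fcn_layers <- function(config) {
  n_stages <- as.integer(round(log2(config$upsample_stride)))
  w <- config$backbone_width
  ch <- w * 2^pmin(seq_len(n_stages) - 1, 2)
  layers <- list()
  cin <- 1L
  for (st in seq_len(n_stages)) {
    layers <- c(layers, list(nn_conv(3L, cin, ch[st]), nn_relu(),
                             nn_conv(3L, ch[st], ch[st]), nn_relu(),
                             nn_pool()))
    cin <- ch[st]
  }
  layers <- c(layers, list(nn_inception(cin, cin / 2, cin / 2), nn_relu(),
                           nn_dropout(config$dropout)))
  pad <- (config$upsample_filter - config$upsample_stride) / 2
  layers <- c(layers, list(nn_tconv(config$upsample_filter,
                                    config$upsample_stride, pad, cin, 2L)))
  layers
}

#' Build the fully convolutional NV segmenter
#'
#' A miniature inception-style backbone downsamples the green-channel input
#' by `upsample_stride`; a single transposed convolution with the configured
#' stride and kernel upsamples back to an `H x W x 2` score map whose
#' per-pixel softmax gives background/NV probabilities.
#'
#' @param config a [seg_config()].
#' @return an `fcn_model` handle.
#' @export
build_fcn <- function(config) {
  stopifnot(inherits(config, "seg_config"))
  net <- withr::with_seed(config$rng_seed, nn_net(fcn_layers(config)))
  structure(list(net = net, config = config), class = "fcn_model")
}

# Forward pass to per-pixel class probabilities (H x W x 2).
fcn_probs <- function(model, green_pixels, train = FALSE) {
  x <- array(green_pixels / 255, c(dim(green_pixels), 1L))
  fw <- nn_forward(model$net, x, train = train)
  list(probs = softmax_pixelwise(fw$out), caches = fw$caches, scores = fw$out)
}

#' Predict a per-pixel NV probability map
#'
#' @param model a trained `fcn_model`.
#' @param green a `green_image` (or matrix) sized as the model expects.
#' @return a `probability_map`: list with `pixels` (values in `[0, 1]`) and
#'   `image_id`.
#' @export
predict_map <- function(model, green) {
  stopifnot(inherits(model, "fcn_model"))
  px <- if (inherits(green, "green_image")) green$pixels else green
  id <- if (inherits(green, "green_image")) green$image_id else "image"
  sz <- model$config$image_size
  if (!all(dim(px) == sz)) {
    abort(sprintf("expected a %d x %d input.", sz, sz),
          class = "segassist_shape_error")
  }
  p <- fcn_probs(model, px)$probs[, , 2]
  structure(list(pixels = p, image_id = id), class = "probability_map")
}

seg_loss_grad <- function(probs, mask, pos_weight) {
  y <- mask  # 1 = NV
  wts <- ifelse(y == 1, pos_weight, 1)
  W <- sum(wts)
  p_true <- ifelse(y == 1, probs[, , 2], probs[, , 1])
  loss <- -sum(wts * log(pmax(p_true, 1e-12))) / W
  d <- probs
  d[, , 1] <- (probs[, , 1] - (1 - y)) * wts / W
  d[, , 2] <- (probs[, , 2] - y) * wts / W
  list(loss = loss, grad = d)
}

load_seg_pairs <- function(manifest) {
  if (nrow(manifest) == 0 || any(is.na(manifest$mask_path))) {
    abort("segmentation training needs rows with masks.",
          class = "segassist_data_error")
  }
  lapply(seq_len(nrow(manifest)), function(i) {
    img <- read_fundus_png(manifest$image_path[i], manifest$image_id[i])
    list(green = extract_green(img)$pixels,
         mask = read_mask_png(manifest$mask_path[i])$pixels,
         image_id = manifest$image_id[i])
  })
}

#' Train the FCN segmenter
#'
#' Per-pixel two-class cross-entropy (optionally weighted toward the sparse
#' NV class), SGD with momentum, and a learning rate of
#' `learning_rate * decay^k` during epoch `k` (0-based). Rows with
#' `split == "train"` are used for updates and `split == "val"` for the
#' per-epoch validation Dice; with no `val` rows the history column is `NA`.
#'
#' @param manifest manifest rows with image and mask paths.
#' @param config a [seg_config()].
#' @return list with `model` (trained `fcn_model`) and `history`
#'   (tibble: epoch, lr, loss, val_dice).
#' @export
train_fcn <- function(manifest, config) {
  stopifnot(inherits(config, "seg_config"))
  train_rows <- manifest[manifest$split %in% c("train", "unassigned"), ]
  val_rows <- manifest[manifest$split == "val", ]
  train <- load_seg_pairs(train_rows)
  val <- if (nrow(val_rows)) load_seg_pairs(val_rows) else list()

  model <- build_fcn(config)
  history <- list()
  if (config$epochs == 0) {
    return(list(model = model,
                history = tibble::tibble(epoch = integer(), lr = numeric(),
                                         loss = numeric(),
                                         val_dice = numeric())))
  }
  withr::with_seed(config$rng_seed + 1L, {
    for (ep in seq_len(config$epochs)) {
      lr <- config$learning_rate * config$decay^(ep - 1)
      losses <- numeric(length(train))
      for (i in sample.int(length(train))) {
        s <- train[[i]]
        fw <- fcn_probs(model, s$green, train = TRUE)
        lg <- seg_loss_grad(fw$probs, s$mask, config$pos_weight)
        losses[i] <- lg$loss
        grads <- nn_backward(model$net, fw$caches, lg$grad)
        model$net <- nn_sgd_step(model$net, grads, lr, config$momentum)
      }
      vd <- if (length(val)) {
        mean(vapply(val, function(s) {
          p <- fcn_probs(model, s$green)$probs[, , 2]
          dice((p > config$threshold) * 1L, s$mask)
        }, numeric(1)))
      } else NA_real_
      history[[ep]] <- tibble::tibble(epoch = ep, lr = lr,
                                      loss = mean(losses), val_dice = vd)
    }
  })
  list(model = model, history = dplyr::bind_rows(history))
}
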
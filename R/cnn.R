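#' Configuration for the four-category DR classifier
#'
#' Shares the training regime of the segmenter (SGD with momentum,
#' per-epoch multiplicative learning-rate decay, dropout before the head)
#' with an input of either 3 channels (RGB baseline) or 4 channels
#' (segmentation-assisted: RGB plus the NV probability map). The two
#' variants are architecturally identical except for the first layer's
#' input channel count.
#'
#' @inheritParams seg_config
#' @param input_channels 3 (baseline) or 4 (assisted).
#' @param augmentation an [augmentation_spec()] applied to training draws
#'   only, or `NULL` for none.
#' @param select checkpoint used for prediction: `"best_val"` (highest
#'   validation accuracy) or `"final"`.
#' @param batch_size gradients are averaged over minibatches of this size
#'   before each SGD step.
#' @return a `cls_config` list.
#' @export
cls_config <- function(epochs = 300, learning_rate = 0.001, decay = 0.99,
                       dropout = 0.5, rng_seed = 1L, image_size = 512,
                       backbone_width = 8, input_channels = 3,
                       augmentation = augmentation_spec(),
                       momentum = 0.9, select = c("best_val", "final"),
                       batch_size = 5L) {
  stopifnot(learning_rate > 0, decay > 0, decay <= 1,
            dropout >= 0, dropout < 1, epochs >= 0)
  if (!input_channels %in% c(3, 4)) {
    abort("input_channels must be 3 or 4.", class = "segassist_config_error")
  }
  if (image_size %% 8 != 0) {
    abort("image_size must be divisible by 8.",
          class = "segassist_config_error")
  }
  select <- match.arg(select)
  structure(list(epochs = epochs, learning_rate = learning_rate,
                 decay = decay, dropout = dropout,
                 rng_seed = as.integer(rng_seed), image_size = image_size,
                 backbone_width = backbone_width,
                 input_channels = as.integer(input_channels), n_classes = 4L,
                 augmentation = augmentation, momentum = momentum,
                 select = select, batch_size = as.integer(batch_size)),
            class = "cls_config")
}

cnn_layers <- function(config) {
  w <- config$backbone_width
  list(
    nn_conv(3L, config$input_channels, w), nn_relu(), nn_pool(),
    nn_conv(3L, w, 2L * w), nn_relu(), nn_pool(),
    nn_inception(2L * w, w, w), nn_relu(), nn_pool(),
    nn_dropout(config$dropout),
    nn_gpool(),
    nn_dense(4L * w, config$n_classes)
  )
}

#' Build the four-category classifier
#'
#' @param config a [cls_config()].
#' @return a `cnn_model` handle mapping `input_channels x H x W` to 4 class
#'   probabilities.
#' @export
build_cnn <- function(config) {
  stopifnot(inherits(config, "cls_config"))
  net <- withr::with_seed(config$rng_seed, nn_net(cnn_layers(config)))
  structure(list(net = net, config = config), class = "cnn_model")
}

# Inputs are centred by subtracting the approximate mean channel intensity
# of the simulated field so that activations start near zero.
CNN_INPUT_CENTER <- 0.35

cnn_probs <- function(model, x, train = FALSE) {
  fw <- nn_forward(model$net, x - CNN_INPUT_CENTER, train = train)
  list(probs = softmax_vec(fw$out), caches = fw$caches)
}

# Load one classification sample as an H x W x C array in [0, 1].
load_cls_sample <- function(row, input_channels) {
  if (input_channels == 4L) {
    if (!"fused_path" %in% names(row) || is.na(row$fused_path)) {
      abort("4-channel training needs fused_path entries.",
            class = "segassist_data_error")
    }
    read_fused_tiff(row$fused_path, row$image_id)$pixels
  } else {
    read_fundus_png(row$image_path, row$image_id)$pixels / 255
  }
}

load_cls_samples <- function(manifest, input_channels) {
  lapply(seq_len(nrow(manifest)), function(i) {
    list(x = load_cls_sample(manifest[i, ], input_channels),
         y = manifest$category[i], image_id = manifest$image_id[i])
  })
}

#' Train the four-category classifier
#'
#' Four-class cross-entropy, SGD with momentum, per-epoch learning-rate
#' decay, augmentation on training draws only, and per-epoch validation
#' accuracy. The returned model carries the checkpoint selected by
#' `config$select`.
#'
#' @param manifest manifest with `split` assigned; needs `fused_path` for
#'   4-channel training.
#' @param config a [cls_config()].
#' @return list with `model` (a `cnn_model`) and `history` (tibble: epoch,
#'   lr, loss, val_accuracy).
#' @export
train_classifier <- function(manifest, config) {
  stopifnot(inherits(config, "cls_config"))
  train_rows <- manifest[manifest$split %in% c("train", "unassigned"), ]
  val_rows <- manifest[manifest$split == "val", ]
  if (nrow(train_rows) == 0) {
    abort("no training rows in manifest.", class = "segassist_data_error")
  }
  train <- load_cls_samples(train_rows, config$input_channels)
  val <- if (nrow(val_rows)) {
    load_cls_samples(val_rows, config$input_channels)
  } else list()
  d <- dim(train[[1]]$x)
  if (d[3] != config$input_channels) {
    abort("data channel count does not match config$input_channels.",
          class = "segassist_data_error")
  }

  model <- build_cnn(config)
  empty_hist <- tibble::tibble(epoch = integer(), lr = numeric(),
                               loss = numeric(), val_accuracy = numeric())
  if (config$epochs == 0) {
    return(list(model = model, history = empty_hist))
  }
  best <- list(acc = -Inf, layers = NULL)
  history <- vector("list", config$epochs)
  withr::with_seed(config$rng_seed + 1L, {
    for (ep in seq_len(config$epochs)) {
      lr <- config$learning_rate * config$decay^(ep - 1)
      losses <- numeric(length(train))
      ord <- sample.int(length(train))
      for (start in seq(1, length(ord), by = config$batch_size)) {
        idx <- ord[start:min(start + config$batch_size - 1, length(ord))]
        acc <- NULL
        for (i in idx) {
          s <- train[[i]]
          x <- if (is.null(config$augmentation)) s$x else {
            augment(s$x, config$augmentation,
                    draw_seed = sample.int(.Machine$integer.max - 1L, 1))
          }
          fw <- cnn_probs(model, x, train = TRUE)
          yk <- s$y + 1L
          losses[i] <- -log(max(fw$probs[yk], 1e-12))
          dout <- fw$probs
          dout[yk] <- dout[yk] - 1
          grads <- nn_backward(model$net, fw$caches, dout)
          acc <- accumulate_grads(acc, grads)
        }
        model$net <- nn_sgd_step(model$net, scale_grads(acc, length(idx)),
                                 lr, config$momentum)
      }
      va <- if (length(val)) {
        mean(vapply(val, function(s) {
          which.max(cnn_probs(model, s$x)$probs) - 1L == s$y
        }, logical(1)))
      } else NA_real_
      if (!is.na(va) && va > best$acc) {
        best <- list(acc = va, layers = model$net$layers)
      }
      history[[ep]] <- tibble::tibble(epoch = ep, lr = lr,
                                      loss = mean(losses), val_accuracy = va)
    }
  })
  if (config$select == "best_val" && !is.null(best$layers)) {
    model$net$layers <- best$layers
  }
  list(model = model, history = dplyr::bind_rows(history))
}

#' Predict class probabilities for every manifest row
#'
#' @param model a trained `cnn_model`.
#' @param manifest manifest rows to score (order preserved).
#' @return tibble with one row per image: `image_id`, `p0`..`p3`,
#'   `predicted_category` (argmax, ties to the lowest index) and, when the
#'   manifest carries labels, `category`.
#' @export
predict_batch <- function(model, manifest) {
  stopifnot(inherits(model, "cnn_model"))
  samples <- load_cls_samples(manifest, model$config$input_channels)
  if (dim(samples[[1]]$x)[3] != model$config$input_channels) {
    abort("data channel count does not match the model.",
          class = "segassist_data_error")
  }
  rows <- purrr::map(samples, function(s) {
    p <- cnn_probs(model, s$x)$probs
    tibble::tibble(image_id = s$image_id, p0 = p[1], p1 = p[2], p2 = p[3],
                   p3 = p[4], predicted_category = which.max(p) - 1L)
  })
  out <- dplyr::bind_rows(rows)
  if ("category" %in% names(manifest)) out$category <- manifest$category
  out
}
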
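# Shared fixtures, built in code at test time.

# Small on-disk dataset; memoised per (counts, seed, size) within a session.
.fixture_env <- new.env(parent = emptyenv())

fixture_dataset <- function(counts = c(3, 2, 2, 4), seed = 11, size = 64) {
  key <- paste(c(counts, seed, size), collapse = "_")
  if (is.null(.fixture_env[[key]])) {
    dir <- file.path(tempdir(), paste0("segassist_fix_", key))
    manifest <- generate_dataset(counts, seed, size, dir)
    .fixture_env[[key]] <- manifest
  }
  .fixture_env[[key]]
}

random_mask <- function(n = 8, p = 0.4) {
  matrix(rbinom(n * n, 1L, p), n)
}

# Independent pixel-counting oracle for overlap metrics: explicit loops,
# no vectorised set algebra.
dice_oracle <- function(pred, truth) {
  inter <- 0L; np <- 0L; nt <- 0L
  for (i in seq_len(nrow(pred))) {
    for (j in seq_len(ncol(pred))) {
      if (pred[i, j] == 1L) np <- np + 1L
      if (truth[i, j] == 1L) nt <- nt + 1L
      if (pred[i, j] == 1L && truth[i, j] == 1L) inter <- inter + 1L
    }
  }
  if (np + nt == 0L) return(1)
  2 * inter / (np + nt)
}

iou_oracle <- function(pred, truth) {
  inter <- 0L; uni <- 0L
  for (i in seq_len(nrow(pred))) {
    for (j in seq_len(ncol(pred))) {
      if (pred[i, j] == 1L && truth[i, j] == 1L) inter <- inter + 1L
      if (pred[i, j] == 1L || truth[i, j] == 1L) uni <- uni + 1L
    }
  }
  if (uni == 0L) return(1)
  inter / uni
}

# Pairwise-concordance AUC oracle (ties counted one half).
auc_concordance <- function(scores, truths) {
  pos <- scores[as.logical(truths)]
  neg <- scores[!as.logical(truths)]
  total <- 0
  for (p in pos) {
    for (n in neg) {
      total <- total + (p > n) + 0.5 * (p == n)
    }
  }
  total / (length(pos) * length(neg))
}

tiny_seg_config <- function(...) {
  defaults <- list(epochs = 2, learning_rate = 0.02, decay = 0.97,
                   dropout = 0.1, image_size = 64, backbone_width = 4,
                   upsample_stride = 2, upsample_filter = 4, pos_weight = 10,
                   rng_seed = 3)
  do.call(seg_config, utils::modifyList(defaults, list(...)))
}

tiny_cls_config <- function(...) {
  defaults <- list(epochs = 2, learning_rate = 0.02, decay = 0.99,
                   dropout = 0, image_size = 64, backbone_width = 4,
                   input_channels = 3, augmentation = NULL, rng_seed = 5)
  do.call(cls_config, utils::modifyList(defaults, list(...), keep.null = TRUE))
}
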
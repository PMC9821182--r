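#' Augmentation settings for classifier training
#'
#' Geometric transforms (rotation, flips, integer-pixel translation) apply
#' identically to every channel; the brightness multiplier applies to the
#' colour channels only and never to a probability channel, whose values
#' are calibrated probabilities rather than photometric intensities.
#'
#' @param rotation maximum rotation in degrees (either direction).
#' @param flip_horizontal,flip_vertical allow the corresponding flip
#'   (each applied with probability 1/2 when allowed).
#' @param translate maximum translation as a fraction of width/height.
#' @param brightness maximum deviation of the multiplicative brightness
#'   factor from 1 (factor drawn in `[1 - b, 1 + b]`).
#' @return an `augmentation_spec` list.
#' @export
augmentation_spec <- function(rotation = 15, flip_horizontal = TRUE,
                              flip_vertical = TRUE, translate = 0.1,
                              brightness = 0.2) {
  stopifnot(rotation >= 0, translate >= 0, brightness >= 0)
  structure(list(rotation = rotation, flip_horizontal = flip_horizontal,
                 flip_vertical = flip_vertical, translate = translate,
                 brightness = brightness), class = "augmentation_spec")
}

# Nearest-neighbour rotation about the image centre; out-of-field pixels 0.
rotate_nn <- function(arr, angle_deg) {
  d <- dim(arr)
  H <- d[1]; W <- d[2]
  th <- angle_deg * pi / 180
  ci <- (H + 1) / 2; cj <- (W + 1) / 2
  ii <- rep(seq_len(H), W) - ci
  jj <- rep(seq_len(W), each = H) - cj
  si <- round(cos(th) * ii - sin(th) * jj + ci)
  sj <- round(sin(th) * ii + cos(th) * jj + cj)
  ok <- si >= 1 & si <= H & sj >= 1 & sj <= W
  src <- (sj - 1) * H + si
  out <- array(0, d)
  plane <- H * W
  for (ch in seq_len(d[3])) {
    dst <- arr[, , ch]
    v <- numeric(plane)
    v[ok] <- dst[src[ok]]
    out[, , ch] <- v
  }
  out
}

shift_int <- function(arr, di, dj) {
  if (di == 0 && dj == 0) return(arr)
  d <- dim(arr)
  out <- array(0, d)
  src_i <- seq_len(d[1]) - di
  src_j <- seq_len(d[2]) - dj
  ok_i <- src_i >= 1 & src_i <= d[1]
  ok_j <- src_j >= 1 & src_j <= d[2]
  out[ok_i, ok_j, ] <- arr[src_i[ok_i], src_j[ok_j], , drop = FALSE]
  out
}

#' Randomly augment a 3- or 4-channel training sample
#'
#' Deterministic for a fixed `(spec, draw_seed)`. A spec with all
#' magnitudes zero and flips disabled is the identity. The sample's label
#' and channel count are never changed, and channel 4 (when present) is
#' bit-identical under brightness changes.
#'
#' @param sample numeric array H x W x C (C = 3 or 4), channels in `[0, 1]`.
#' @param spec an [augmentation_spec()].
#' @param draw_seed integer seed for this draw.
#' @return an array of the same shape.
#' @export
augment <- function(sample, spec = augmentation_spec(), draw_seed = 1L) {
  stopifnot(length(dim(sample)) == 3)
  withr::with_seed(draw_seed, {
    out <- sample
    if (spec$rotation > 0) {
      ang <- runif(1, -spec$rotation, spec$rotation)
      out <- rotate_nn(out, ang)
    }
    if (spec$translate > 0) {
      d <- dim(out)
      di <- round(runif(1, -spec$translate, spec$translate) * d[1])
      dj <- round(runif(1, -spec$translate, spec$translate) * d[2])
      out <- shift_int(out, di, dj)
    }
    if (isTRUE(spec$flip_horizontal) && runif(1) < 0.5) {
      out <- out[, rev(seq_len(dim(out)[2])), , drop = FALSE]
    }
    if (isTRUE(spec$flip_vertical) && runif(1) < 0.5) {
      out <- out[rev(seq_len(dim(out)[1])), , , drop = FALSE]
    }
    if (spec$brightness > 0) {
      f <- runif(1, 1 - spec$brightness, 1 + spec$brightness)
      nc <- min(3, dim(out)[3])
      out[, , seq_len(nc)] <- pmin(pmax(out[, , seq_len(nc)] * f, 0), 1)
    }
    out
  })
}
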
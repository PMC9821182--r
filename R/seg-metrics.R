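mask_px <- function(x) {
  px <- if (inherits(x, "nv_mask")) x$pixels else x
  if (!all(px %in% c(0, 1))) {
    abort("masks must be binary (values in {0, 1}).",
          class = "segassist_domain_error")
  }
  px
}

check_same_shape <- function(a, b) {
  if (!identical(dim(a), dim(b))) {
    abort("mask shapes differ.", class = "segassist_shape_error")
  }
}

#' Dice score and intersection-over-union of two binary masks
#'
#' `dice = 2|A∩B| / (|A| + |B|)`, `iou = |A∩B| / |A∪B|`; the two are linked
#' by `dice = 2·iou / (1 + iou)`. The undefined empty/empty case (0/0) is
#' defined as 1 (perfect agreement on absence); exactly one empty mask gives
#' 0. Both are symmetric in their arguments.
#'
#' @param pred,truth binary masks (`nv_mask` or 0/1 matrices) of equal
#'   shape.
#' @return a fraction in `[0, 1]`.
#' @export
dice <- function(pred, truth) {
  p <- mask_px(pred); t <- mask_px(truth)
  check_same_shape(p, t)
  sp <- sum(p); st <- sum(t)
  if (sp + st == 0) return(1)
  2 * sum(p * t) / (sp + st)
}

#' @rdname dice
#' @export
iou <- function(pred, truth) {
  p <- mask_px(pred); t <- mask_px(truth)
  check_same_shape(p, t)
  u <- sum(p | t)
  if (u == 0) return(1)
  sum(p * t) / u
}

#' Image-level NV presence accuracy from probability maps
#'
#' An image is called NV-present when any pixel's probability exceeds
#' `pixel_threshold`; the return value is the fraction of images whose call
#' matches the image-level truth.
#'
#' @param maps list of `probability_map`s (or probability matrices).
#' @param truths logical vector: does the image truly contain NV?
#' @param pixel_threshold per-pixel probability cutoff in (0, 1).
#' @return fraction of correct presence calls.
#' @export
presence_accuracy <- function(maps, truths, pixel_threshold = 0.5) {
  stopifnot(pixel_threshold > 0, pixel_threshold < 1)
  if (length(maps) != length(truths)) {
    abort("maps and truths must have equal length.",
          class = "segassist_input_error")
  }
  calls <- vapply(maps, function(m) {
    px <- if (inherits(m, "probability_map")) m$pixels else m
    any(px > pixel_threshold)
  }, logical(1))
  mean(calls == truths)
}

#' Segmentation metrics over a set of predictions
#'
#' Binarizes each probability map at `threshold` and reports per-image and
#' mean Dice/IOU plus image-level presence accuracy.
#'
#' @param maps list of `probability_map`s.
#' @param truths list of `nv_mask`s (or binary matrices).
#' @param threshold binarization cutoff for Dice/IOU.
#' @param presence_threshold cutoff for the any-pixel presence call.
#' @return a `seg_metrics` list: `per_image` tibble and `mean_dice`,
#'   `mean_iou`, `presence_accuracy`.
#' @export
seg_metrics <- function(maps, truths, threshold = 0.5,
                        presence_threshold = 0.5) {
  stopifnot(length(maps) == length(truths))
  rows <- purrr::map2(maps, truths, function(m, t) {
    px <- if (inherits(m, "probability_map")) m$pixels else m
    bin <- (px > threshold) * 1L
    tibble::tibble(
      image_id = if (inherits(m, "probability_map")) m$image_id else NA,
      dice = dice(bin, t), iou = iou(bin, t),
      truth_present = sum(mask_px(t)) > 0)
  })
  per_image <- dplyr::bind_rows(rows)
  structure(list(
    per_image = per_image,
    mean_dice = mean(per_image$dice),
    mean_iou = mean(per_image$iou),
    presence_accuracy = presence_accuracy(maps, per_image$truth_present,
                                          presence_threshold)
  ), class = "seg_metrics")
}
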
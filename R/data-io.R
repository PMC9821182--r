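#' @title Image and mask containers
#' @description `fundus_image` wraps an H x W x 3 integer array (values
#'   0..255, channel order R,G,B); `nv_mask` wraps an H x W \{0,1\} matrix;
#'   `green_image` wraps the isolated green channel. All use (row, col)
#'   indexing with origin at the top-left.
#' @param pixels pixel array/matrix as described above.
#' @param image_id identifier string.
#' @return An object of the corresponding class.
#' @name image-containers
NULL

new_fundus_image <- function(pixels, image_id) {
  structure(list(pixels = pixels, image_id = image_id),
            class = "fundus_image")
}
new_nv_mask <- function(pixels, image_id) {
  structure(list(pixels = pixels, image_id = image_id), class = "nv_mask")
}
new_green_image <- function(pixels, image_id) {
  structure(list(pixels = pixels, image_id = image_id),
            class = "green_image")
}

#' @rdname image-containers
#' @export
fundus_image <- function(pixels, image_id = "image") {
  stopifnot(length(dim(pixels)) == 3, dim(pixels)[3] == 3,
            min(pixels) >= 0, max(pixels) <= 255)
  storage.mode(pixels) <- "integer"
  new_fundus_image(pixels, image_id)
}

#' @rdname image-containers
#' @export
nv_mask <- function(pixels, image_id = "mask") {
  stopifnot(is.matrix(pixels), all(pixels %in% c(0, 1)))
  storage.mode(pixels) <- "integer"
  new_nv_mask(pixels, image_id)
}

#' Read and write images and masks as 8-bit PNG
#'
#' Masks are written with on-disk values \{0, 255\} and mapped back to
#' \{0, 1\} on read.
#'
#' @param x a `fundus_image` or `nv_mask`.
#' @param path PNG file path.
#' @param image_id identifier to attach on read (defaults to the file stem).
#' @return the written path (writers, invisibly) or the object (readers).
#' @name png-io
NULL

#' @rdname png-io
#' @export
write_fundus_png <- function(x, path) {
  stopifnot(inherits(x, "fundus_image"))
  png::writePNG(x$pixels / 255, path)
  invisible(path)
}

#' @rdname png-io
#' @export
read_fundus_png <- function(path, image_id = NULL) {
  arr <- png::readPNG(path)
  if (length(dim(arr)) == 3 && dim(arr)[3] == 4) arr <- arr[, , 1:3]
  if (length(dim(arr)) != 3 || dim(arr)[3] != 3) {
    abort("expected a 3-channel PNG image.",
          class = "segassist_channel_error")
  }
  px <- round(arr * 255)
  storage.mode(px) <- "integer"
  new_fundus_image(px, image_id %||% sub("\\.png$", "", basename(path)))
}

#' @rdname png-io
#' @export
write_mask_png <- function(x, path) {
  stopifnot(inherits(x, "nv_mask"))
  png::writePNG(x$pixels * 1.0, path)
  invisible(path)
}

#' @rdname png-io
#' @export
read_mask_png <- function(path, image_id = NULL) {
  arr <- png::readPNG(path)
  if (length(dim(arr)) == 3) arr <- arr[, , 1]
  px <- (arr > 0.5) * 1L
  new_nv_mask(matrix(as.integer(px), nrow(arr)),
              image_id %||% sub("\\.png$", "", basename(path)))
}

#' Resize an image or mask to a uniform square size
#'
#' Images use bilinear interpolation; masks use nearest-neighbour so values
#' stay binary. An input already at the target size is returned unchanged.
#'
#' @param x a `fundus_image` or `nv_mask`.
#' @param target side length in pixels (>= 8); output is `target x target`.
#' @return the same kind of object at the target size.
#' @export
resize_uniform <- function(x, target) {
  stopifnot(target >= 8)
  UseMethod("resize_uniform")
}

#' @export
resize_uniform.fundus_image <- function(x, target) {
  d <- dim(x$pixels)
  if (any(d[1:2] == 0)) {
    abort("degenerate zero-size image.", class = "segassist_shape_error")
  }
  if (d[1] == target && d[2] == target) return(x)
  out <- EBImage::resize(EBImage::Image(x$pixels / 255), w = target,
                         h = target, filter = "bilinear")
  px <- round(pmin(pmax(EBImage::imageData(out), 0), 1) * 255)
  storage.mode(px) <- "integer"
  new_fundus_image(px, x$image_id)
}

#' @export
resize_uniform.nv_mask <- function(x, target) {
  d <- dim(x$pixels)
  if (any(d == 0)) {
    abort("degenerate zero-size mask.", class = "segassist_shape_error")
  }
  if (d[1] == target && d[2] == target) return(x)
  out <- EBImage::resize(EBImage::Image(x$pixels), w = target, h = target,
                         filter = "none")
  new_nv_mask(matrix(as.integer(EBImage::imageData(out)), target),
              x$image_id)
}

#' Isolate the green channel of a fundus image
#'
#' NV vessels are red on imaging, so the green channel carries the strongest
#' vessel/NV contrast; segmentation operates on it alone.
#'
#' @param image a `fundus_image` (3 channels).
#' @return a `green_image` whose pixels equal channel 2 of the input,
#'   bit-exact.
#' @export
extract_green <- function(image) {
  if (!inherits(image, "fundus_image") || length(dim(image$pixels)) != 3 ||
      dim(image$pixels)[3] != 3) {
    abort("green extraction needs a 3-channel fundus image.",
          class = "segassist_channel_error")
  }
  new_green_image(image$pixels[, , 2], image$image_id)
}

# --- manifests --------------------------------------------------------------

manifest_cols <- c("image_id", "image_path", "mask_path", "category", "split")

empty_manifest <- function() {
  tibble::tibble(image_id = character(), image_path = character(),
                 mask_path = character(), category = integer(),
                 split = character())
}

validate_manifest <- function(m) {
  missing <- setdiff(manifest_cols, names(m))
  if (length(missing)) {
    abort(paste("manifest is missing columns:",
                paste(missing, collapse = ", ")),
          class = "segassist_schema_error")
  }
  if (anyDuplicated(m$image_id)) {
    abort("manifest image_id values must be unique.",
          class = "segassist_schema_error")
  }
  if (nrow(m) > 0 && !all(m$category %in% 0:3)) {
    abort("manifest category values must be in 0..3.",
          class = "segassist_domain_error")
  }
  ok <- c("train", "val", "test", "unassigned")
  if (nrow(m) > 0 && !all(m$split %in% ok)) {
    abort("manifest split values must be train/val/test/unassigned.",
          class = "segassist_domain_error")
  }
  m
}

#' Read or write a dataset manifest CSV
#'
#' The manifest has columns `image_id,image_path,mask_path,category,split`
#' and one row per image; `read_manifest(write_manifest(m, f))` returns `m`.
#'
#' @param path CSV path.
#' @param manifest a manifest tibble.
#' @return `read_manifest()` returns a validated tibble; `write_manifest()`
#'   returns `path` invisibly.
#' @export
read_manifest <- function(path) {
  m <- readr::read_csv(path, show_col_types = FALSE)
  missing <- setdiff(manifest_cols, names(m))
  if (length(missing)) {
    abort(paste("manifest is missing columns:",
                paste(missing, collapse = ", ")),
          class = "segassist_schema_error")
  }
  m <- tibble::as_tibble(m[manifest_cols])
  m$category <- as.integer(m$category)
  for (col in c("image_id", "image_path", "mask_path", "split")) {
    m[[col]] <- as.character(m[[col]])
  }
  validate_manifest(m)
}

#' @rdname read_manifest
#' @export
write_manifest <- function(manifest, path) {
  validate_manifest(manifest)
  readr::write_csv(manifest[union(manifest_cols,
                                  names(manifest))], path)
  invisible(path)
}

#' Specification of a train/validation/test split
#'
#' @param fractions three proportions (train, val, test) summing to 1.
#' @param stratified assign per category when `TRUE`.
#' @param rng_seed integer seed for the shuffling.
#' @return a `split_spec` list.
#' @export
split_spec <- function(fractions = c(train = 0.75, val = 0.08, test = 0.17),
                       stratified = TRUE, rng_seed = 1L) {
  stopifnot(length(fractions) == 3, all(fractions >= 0), all(fractions <= 1))
  if (abs(sum(fractions) - 1) > 1e-9) {
    abort("split fractions must sum to 1.", class = "segassist_spec_error")
  }
  structure(list(fractions = unname(fractions), stratified = stratified,
                 rng_seed = as.integer(rng_seed)), class = "split_spec")
}

# Largest-remainder apportionment of n into parts proportional to fractions.
largest_remainder <- function(n, fractions) {
  raw <- n * fractions
  base <- floor(raw)
  left <- n - sum(base)
  if (left > 0) {
    ord <- order(raw - base, decreasing = TRUE)
    base[ord[seq_len(left)]] <- base[ord[seq_len(left)]] + 1
  }
  as.integer(base)
}

#' Assign train/validation/test splits to a manifest
#'
#' Per category (when stratified), split sizes are the fractions rounded by
#' largest remainder so they sum exactly to the category total; assignment
#' within a category is a seeded shuffle. An explicit per-category count
#' override reproduces a printed partition exactly.
#'
#' @param manifest a manifest tibble.
#' @param spec a [split_spec()].
#' @param counts_override optional 4 x 3 matrix (rows categories 0..3,
#'   columns train/val/test) of exact counts; overrides the fractions.
#' @return the manifest with `split` filled in.
#' @export
assign_splits <- function(manifest, spec = split_spec(),
                          counts_override = NULL) {
  validate_manifest(manifest)
  if (nrow(manifest) == 0) {
    abort("cannot split an empty manifest.",
          class = "segassist_empty_error")
  }
  splits <- c("train", "val", "test")
  withr::with_seed(spec$rng_seed, {
    if (isTRUE(spec$stratified) || !is.null(counts_override)) {
      parts <- lapply(0:3, function(cat) {
        rows <- manifest[manifest$category == cat, ]
        n <- nrow(rows)
        if (n == 0) return(rows)
        counts <- if (!is.null(counts_override)) {
          as.integer(counts_override[cat + 1, ])
        } else {
          largest_remainder(n, spec$fractions)
        }
        if (sum(counts) != n) {
          abort("override counts do not sum to the category total.",
                class = "segassist_spec_error")
        }
        rows <- rows[sample.int(n), ]
        rows$split <- rep(splits, counts)
        rows
      })
      out <- dplyr::bind_rows(parts)
    } else {
      n <- nrow(manifest)
      counts <- largest_remainder(n, spec$fractions)
      out <- manifest[sample.int(n), ]
      out$split <- rep(splits, counts)
    }
  })
  out <- out[match(manifest$image_id, out$image_id), ]
  tibble::as_tibble(out)
}
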
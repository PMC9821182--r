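#' Seeded synthetic fundus photographs with ground-truth NV masks
#'
#' The simulator emulates the statistical structure of a proliferative
#' diabetic retinopathy (PDR) grading dataset: a circular fundus field with an
#' optic disc and a branching vessel tree, plus five lesion kinds —
#' thin web-like neovascularization (`nv_web`, the only mask-positive kind),
#' regular laser-scar dot grids (visually salient but mask-negative),
#' tortuous IRMA-like vessel segments (mask-negative look-alikes of NV),
#' and confounding hemorrhages and exudates. Image-level categories follow
#' the four NV-related stages: 0 = NPDR without NV, 1 = past NV (laser
#' scars), 2 = ambiguous lesions, 3 = active NV.
#'
#' @param category integer stage label in 0..3.
#' @param rng_seed integer seed; scenes are bit-reproducible per
#'   `(category, rng_seed, size, lesion_density)`.
#' @param size image side length in pixels (square output, >= 32).
#' @param lesion_density per-kind rate parameters, see
#'   [lesion_density_defaults()].
#' @return A `scene_description`: list with `image_id`, `category`,
#'   `lesions` (tibble of lesion specs), `disc_center`, `disc_radius`,
#'   `vessel_seed`, `field_radius`, `size`.
#' @examples
#' sc <- generate_scene(3, rng_seed = 7, size = 64)
#' table(sc$lesions$lesion_kind)
#' @export
generate_scene <- function(category, rng_seed, size = 64,
                           lesion_density = lesion_density_defaults()) {
  if (!is.numeric(category) || length(category) != 1 ||
      !category %in% 0:3) {
    abort("`category` must be a single integer in 0..3.",
          class = "segassist_category_error")
  }
  if (size < 32) {
    abort("`size` must be at least 32 pixels.",
          class = "segassist_size_error")
  }
  category <- as.integer(category)
  size <- as.integer(size)
  ld <- lesion_density

  withr::with_seed(rng_seed, {
    centre <- (size + 1) / 2
    field_radius <- 0.47 * size
    disc_radius <- 0.11 * size
    ang <- runif(1, 0, 2 * pi)
    dd <- 0.55 * field_radius
    disc_center <- c(centre + dd * sin(ang), centre + dd * cos(ang))

    sc <- size / 64  # lesion geometry scales with image side

    place_uniform <- function() {
      repeat {
        r <- field_radius * 0.85 * sqrt(runif(1))
        a <- runif(1, 0, 2 * pi)
        p <- c(centre + r * sin(a), centre + r * cos(a))
        return(p)
      }
    }
    place_near_disc <- function() {
      # within 1.5 disc radii of the disc centre, clipped into the field
      for (try in 1:50) {
        r <- 1.5 * disc_radius * sqrt(runif(1))
        a <- runif(1, 0, 2 * pi)
        p <- c(disc_center[1] + r * sin(a), disc_center[2] + r * cos(a))
        if (sqrt(sum((p - centre)^2)) < field_radius * 0.92) return(p)
      }
      place_uniform()
    }

    lesion <- function(kind, center, extent, delta, mask_positive) {
      tibble::tibble(lesion_kind = kind, row = center[1], col = center[2],
                     extent = extent, dr = delta[1], dg = delta[2],
                     db = delta[3], mask_positive = mask_positive)
    }
    n_at_least <- function(rate, minimum = 0L) max(minimum, rpois(1, rate))

    specs <- list()
    add <- function(x) specs[[length(specs) + 1]] <<- x

    if (category == 3L) {
      for (i in seq_len(n_at_least(ld$nv_web_rate, 1L))) {
        ctr <- if (runif(1) < ld$nv_near_disc_prob) place_near_disc()
               else place_uniform()
        add(lesion("nv_web", ctr, runif(1, 3, 6) * sc,
                   c(18, -42, -8), TRUE))
      }
    }
    scar_rate <- switch(category + 1L, 0, ld$scar_rate_cat1, 0,
                        ld$scar_rate_cat3)
    for (i in seq_len(n_at_least(scar_rate, if (category == 1L) 1L else 0L)))
      add(lesion("laser_scar", place_uniform(), runif(1, 6, 10) * sc,
                 c(55, 120, 115), FALSE))
    if (category == 2L) {
      for (i in seq_len(n_at_least(ld$irma_rate, 1L)))
        add(lesion("ambiguous_irma", place_uniform(), runif(1, 4, 7) * sc,
                   c(18, -42, -8), FALSE))
    }
    conf <- ld$confounder_rate[category + 1L]
    for (i in seq_len(n_at_least(conf)))
      add(lesion("hemorrhage", place_uniform(), runif(1, 2, 4) * sc,
                 c(-30, -45, -15), FALSE))
    for (i in seq_len(n_at_least(conf * 0.8)))
      add(lesion("exudate", place_uniform(), runif(1, 1.5, 3) * sc,
                 c(60, 125, 75), FALSE))

    lesions <- if (length(specs)) dplyr::bind_rows(specs) else
      tibble::tibble(lesion_kind = character(), row = numeric(),
                     col = numeric(), extent = numeric(), dr = numeric(),
                     dg = numeric(), db = numeric(), mask_positive = logical())

    structure(list(
      image_id = sprintf("scene_c%d_s%d_%dpx", category, rng_seed, size),
      category = category,
      lesions = lesions,
      disc_center = disc_center,
      disc_radius = disc_radius,
      vessel_seed = sample.int(.Machine$integer.max - 1L, 1),
      field_radius = field_radius,
      size = size
    ), class = "scene_description")
  })
}

#' Default lesion rate parameters for the fundus simulator
#'
#' Rates are Poisson means per scene. Category 3 scenes carry more
#' confounding (non-NV) lesions than category 0, and NV webs are placed near
#' the optic disc with probability `nv_near_disc_prob`, mirroring the
#' clinical tendency of NV to cluster at the disc.
#'
#' @return Named list of rate parameters.
#' @export
lesion_density_defaults <- function() {
  list(
    nv_web_rate = 1.5,        # category 3 only; at least one is guaranteed
    nv_near_disc_prob = 0.7,  # fraction of webs seeded within 1.5 disc radii
    scar_rate_cat1 = 2.5,     # category 1; at least one is guaranteed
    scar_rate_cat3 = 0.6,     # past-treatment scars can coexist with NV
    irma_rate = 1.8,          # category 2; at least one is guaranteed
    confounder_rate = c(0.6, 0.6, 0.8, 1.5)  # hemorrhage mean by category
  )
}

# --- painting helpers (row/col coordinates, 1-based) ------------------------

disk_pixels <- function(center, radius, size) {
  r0 <- max(1L, floor(center[1] - radius)); r1 <- min(size, ceiling(center[1] + radius))
  c0 <- max(1L, floor(center[2] - radius)); c1 <- min(size, ceiling(center[2] + radius))
  if (r0 > r1 || c0 > c1) return(cbind(integer(0), integer(0)))
  g <- expand.grid(i = r0:r1, j = c0:c1)
  d2 <- (g$i - center[1])^2 + (g$j - center[2])^2
  as.matrix(g[d2 <= radius^2, , drop = FALSE])
}

paint_delta <- function(img, px, delta, alpha = 1) {
  if (nrow(px) == 0) return(img)
  for (ch in 1:3) {
    idx <- cbind(px, ch)
    img[idx] <- img[idx] + alpha * delta[ch]
  }
  img
}

paint_color <- function(img, px, color, alpha = 1) {
  if (nrow(px) == 0) return(img)
  for (ch in 1:3) {
    idx <- cbind(px, ch)
    img[idx] <- (1 - alpha) * img[idx] + alpha * color[ch]
  }
  img
}

# Random-walk curve clipped to the field; returns unique pixel coordinates.
walk_curve <- function(start, n_steps, wobble, centre, field_radius,
                       dir0 = runif(1, 0, 2 * pi)) {
  pos <- start
  a <- dir0
  out <- matrix(0, n_steps + 1, 2)
  out[1, ] <- round(pos)
  for (k in seq_len(n_steps)) {
    a <- a + rnorm(1, sd = wobble)
    pos <- pos + c(sin(a), cos(a))
    if (sqrt(sum((pos - centre)^2)) > field_radius * 0.97) break
    out[k + 1, ] <- round(pos)
  }
  out <- out[rowSums(out) > 0, , drop = FALSE]
  unique(out)
}

#' Render a scene description into an image and its NV mask
#'
#' Deterministic for a fixed scene: all stochastic texture (vessel tree,
#' lesion strands, pixel noise) is drawn from the scene's `vessel_seed`.
#' The mask is 1 exactly where a mask-positive lesion (an NV web) painted a
#' pixel; laser scars, IRMA-like lesions and confounders alter the image but
#' never the mask.
#'
#' @param scene a `scene_description` from [generate_scene()].
#' @return list with `image` (a `fundus_image`) and `mask` (an `nv_mask`).
#' @export
render_scene <- function(scene) {
  stopifnot(inherits(scene, "scene_description"))
  size <- scene$size
  centre <- (size + 1) / 2
  if (nrow(scene$lesions) > 0) {
    d <- sqrt((scene$lesions$row - centre)^2 + (scene$lesions$col - centre)^2)
    if (any(d > scene$field_radius)) {
      abort("lesion centre lies outside the fundus field.",
            class = "segassist_render_error")
    }
  }

  withr::with_seed(scene$vessel_seed, {
    img <- render_canvas(scene)
    mask <- matrix(0L, size, size)

    sc <- size / 64
    for (k in seq_len(nrow(scene$lesions))) {
      L <- scene$lesions[k, ]
      ctr <- c(L$row, L$col)
      delta <- c(L$dr, L$dg, L$db)
      px <- switch(
        L$lesion_kind,
        nv_web = {
          n_strands <- 7L + round(L$extent / sc)
          do.call(rbind, lapply(seq_len(n_strands), function(s) {
            st <- ctr + runif(2, -1, 1)
            w <- walk_curve(st, n_steps = round(runif(1, 1, 2) * L$extent),
                            wobble = 0.55, centre = centre,
                            field_radius = scene$field_radius)
            # keep strands inside the web's extent
            keep <- (w[, 1] - ctr[1])^2 + (w[, 2] - ctr[2])^2 <= L$extent^2
            w[keep, , drop = FALSE]
          }))
        },
        laser_scar = {
          sp <- max(3, round(4 * sc))
          offs <- seq(-floor(L$extent), floor(L$extent), by = sp)
          dots <- expand.grid(di = offs, dj = offs)
          do.call(rbind, lapply(seq_len(nrow(dots)), function(q) {
            disk_pixels(ctr + c(dots$di[q], dots$dj[q]),
                        max(1, 1.1 * sc), size)
          }))
        },
        ambiguous_irma = {
          do.call(rbind, lapply(1:3, function(s) {
            w <- walk_curve(ctr + runif(2, -1.5, 1.5),
                            n_steps = round(2 * L$extent),
                            wobble = 0.85, centre = centre,
                            field_radius = scene$field_radius)
            rbind(w, sweep(w, 2, c(1, 0), "+"))  # 2 px thick
          }))
        },
        hemorrhage = disk_pixels(ctr, L$extent, size),
        exudate = disk_pixels(ctr, L$extent, size)
      )
      if (is.null(px) || nrow(px) == 0) px <- matrix(round(ctr), 1)
      px <- px[px[, 1] >= 1 & px[, 1] <= size &
               px[, 2] >= 1 & px[, 2] <= size, , drop = FALSE]
      # clip to the circular field
      inside <- (px[, 1] - centre)^2 + (px[, 2] - centre)^2 <=
        scene$field_radius^2
      px <- px[inside, , drop = FALSE]
      if (nrow(px) == 0) px <- matrix(round(ctr), 1)
      img <- paint_delta(img, px, delta)
      if (isTRUE(L$mask_positive)) mask[px] <- 1L
    }

    img <- round(pmin(pmax(img, 0), 255))
    storage.mode(img) <- "integer"
    list(image = new_fundus_image(img, scene$image_id),
         mask = new_nv_mask(mask, scene$image_id))
  })
}

# Background field + optic disc + vessel tree (lesion-free canvas).
render_canvas <- function(scene) {
  size <- scene$size
  centre <- (size + 1) / 2
  base <- c(175, 95, 45)
  rr <- matrix(rep(seq_len(size), size), size)
  cc <- t(rr)
  d <- sqrt((rr - centre)^2 + (cc - centre)^2)
  fade <- pmax(0, 1 - 0.25 * (d / scene$field_radius)^2)
  inside <- d <= scene$field_radius
  img <- array(0, c(size, size, 3))
  for (ch in 1:3) {
    img[, , ch] <- (base[ch] * fade + rnorm(size * size, sd = 4)) * inside
  }

  disc_px <- disk_pixels(scene$disc_center, scene$disc_radius, size)
  keep <- (disc_px[, 1] - centre)^2 + (disc_px[, 2] - centre)^2 <=
    scene$field_radius^2
  img <- paint_color(img, disc_px[keep, , drop = FALSE],
                     c(235, 200, 140), alpha = 0.9)

  n_branches <- sample(5:7, 1)
  for (b in seq_len(n_branches)) {
    w <- walk_curve(scene$disc_center, n_steps = round(1.6 * scene$field_radius),
                    wobble = 0.12, centre = centre,
                    field_radius = scene$field_radius,
                    dir0 = 2 * pi * b / n_branches + runif(1, -0.3, 0.3))
    w <- w[w[, 1] >= 1 & w[, 1] <= size & w[, 2] >= 1 & w[, 2] <= size, ,
           drop = FALSE]
    img <- paint_color(img, w, c(125, 58, 35), alpha = 0.85)
  }
  img
}

#' Generate a synthetic dataset on disk with a manifest
#'
#' Writes one RGB PNG and one binary mask PNG per scene, and returns a
#' manifest tibble with columns `image_id`, `image_path`, `mask_path`,
#' `category`, `split` (all `"unassigned"`). Masks are stored with values
#' \{0, 255\} on disk and map back to \{0, 1\} in memory.
#'
#' @param counts_per_category integer vector of length 4: number of images
#'   for categories 0..3.
#' @param rng_seed master seed; per-image seeds are derived from it.
#' @param size image side length in pixels.
#' @param out_dir output directory (created if needed).
#' @param lesion_density see [lesion_density_defaults()].
#' @return The manifest tibble (also written to `out_dir/manifest.csv`).
#' @export
generate_dataset <- function(counts_per_category, rng_seed, size = 64,
                             out_dir,
                             lesion_density = lesion_density_defaults()) {
  stopifnot(length(counts_per_category) == 4, all(counts_per_category >= 0))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) {
    abort(paste("cannot create output directory:", out_dir),
          class = "segassist_io_error")
  }
  rows <- list()
  idx <- 0L
  for (cat in 0:3) {
    for (i in seq_len(counts_per_category[cat + 1])) {
      idx <- idx + 1L
      seed_i <- (rng_seed + 7919L * idx) %% .Machine$integer.max
      scene <- generate_scene(cat, seed_i, size, lesion_density)
      scene$image_id <- sprintf("img%05d_c%d", idx, cat)
      rend <- render_scene(scene)
      img_path <- file.path(out_dir, paste0(scene$image_id, ".png"))
      msk_path <- file.path(out_dir, paste0(scene$image_id, "_mask.png"))
      write_fundus_png(rend$image, img_path)
      write_mask_png(rend$mask, msk_path)
      rows[[idx]] <- tibble::tibble(
        image_id = scene$image_id, image_path = img_path,
        mask_path = msk_path, category = cat, split = "unassigned")
    }
  }
  manifest <- if (length(rows)) dplyr::bind_rows(rows) else empty_manifest()
  write_manifest(manifest, file.path(out_dir, "manifest.csv"))
  manifest
}
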
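test_that("scenes honour the category composition rules", {
  kinds_of <- function(cat, seed) {
    generate_scene(cat, seed, 64)$lesions$lesion_kind
  }
  for (seed in c(1, 7, 23)) {
    expect_false("nv_web" %in% kinds_of(0, seed))
    k1 <- kinds_of(1, seed)
    expect_true("laser_scar" %in% k1)
    expect_false("nv_web" %in% k1)
    k2 <- kinds_of(2, seed)
    expect_true("ambiguous_irma" %in% k2)
    expect_false("nv_web" %in% k2)
    expect_true("nv_web" %in% kinds_of(3, seed))
  }
})

test_that("only NV webs are mask-positive and centres stay in the field", {
  for (cat in 0:3) {
    sc <- generate_scene(cat, 13, 64)
    L <- sc$lesions
    expect_equal(L$mask_positive, L$lesion_kind == "nv_web")
    centre <- (sc$size + 1) / 2
    d <- sqrt((L$row - centre)^2 + (L$col - centre)^2)
    expect_true(all(d <= sc$field_radius))
  }
})

test_that("scene generation is deterministic and validates inputs", {
  expect_identical(generate_scene(2, 42, 64), generate_scene(2, 42, 64))
  expect_error(generate_scene(5, 1, 64), class = "segassist_category_error")
  expect_error(generate_scene(-1, 1, 64), class = "segassist_category_error")
  expect_error(generate_scene(0, 1, 16), class = "segassist_size_error")
})

test_that("rendering is deterministic and mask matches NV painting", {
  sc <- generate_scene(3, 7, 64)
  r1 <- render_scene(sc)
  r2 <- render_scene(sc)
  expect_identical(r1, r2)
  expect_gt(sum(r1$mask$pixels), 0)
  expect_true(all(r1$image$pixels >= 0 & r1$image$pixels <= 255))
  expect_identical(dim(r1$mask$pixels), dim(r1$image$pixels)[1:2])

  r0 <- render_scene(generate_scene(0, 7, 64))
  expect_identical(sum(r0$mask$pixels), 0L)
})

test_that("mask pixels lie inside the circular fundus field", {
  sc <- generate_scene(3, 19, 64)
  r <- render_scene(sc)
  centre <- (sc$size + 1) / 2
  idx <- which(r$mask$pixels == 1L, arr.ind = TRUE)
  d <- sqrt((idx[, 1] - centre)^2 + (idx[, 2] - centre)^2)
  expect_true(all(d <= sc$field_radius + 1e-9))
})

test_that("laser scars are visible in the image but absent from the mask", {
  sc <- generate_scene(1, 31, 64)
  r <- render_scene(sc)
  expect_identical(sum(r$mask$pixels), 0L)
  bare <- sc
  bare$lesions <- sc$lesions[0, ]
  rb <- render_scene(bare)
  expect_gt(sum(r$image$pixels != rb$image$pixels), 0)
})

test_that("NV clusters near the disc and stays sparse across many scenes", {
  near <- logical(100)
  frac <- numeric(100)
  field_area <- pi * (0.47 * 64)^2
  for (s in 1:100) {
    sc <- generate_scene(3, s, 64)
    L <- sc$lesions[sc$lesions$lesion_kind == "nv_web", ]
    d <- sqrt((L$row - sc$disc_center[1])^2 + (L$col - sc$disc_center[2])^2)
    near[s] <- any(d <= 1.5 * sc$disc_radius)
    frac[s] <- sum(render_scene(sc)$mask$pixels) / field_area
  }
  expect_gte(mean(near), 0.5)
  expect_lt(mean(frac), 0.05)
})

test_that("generate_dataset writes files and a counted manifest", {
  m <- fixture_dataset(c(3, 2, 2, 4), seed = 11)
  expect_equal(nrow(m), 11)
  expect_equal(sum(m$category == 3), 4)
  expect_true(all(file.exists(m$image_path)))
  expect_true(all(file.exists(m$mask_path)))
  expect_true(all(m$split == "unassigned"))

  empty <- generate_dataset(c(0, 0, 0, 0), 1, 64, tempfile())
  expect_equal(nrow(empty), 0)
})

test_that("masks on disk are nonzero exactly for category-3 images", {
  m <- fixture_dataset(c(3, 2, 2, 4), seed = 11)
  npos <- vapply(m$mask_path, function(p) sum(read_mask_png(p)$pixels),
                 numeric(1))
  expect_equal(unname(npos > 0), m$category == 3)
})
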
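test_that("resize produces the target square size from uneven inputs", {
  set.seed(1)
  px <- array(sample(0:255, 433 * 289 * 3, TRUE), c(433, 289, 3))
  img <- fundus_image(px)
  out <- resize_uniform(img, 512)
  expect_identical(dim(out$pixels), c(512L, 512L, 3L))
  expect_true(all(out$pixels >= 0 & out$pixels <= 255))
})

test_that("mask resize keeps values binary; identity input is untouched", {
  set.seed(2)
  mk <- nv_mask(random_mask(50))
  out <- resize_uniform(mk, 64)
  expect_identical(dim(out$pixels), c(64L, 64L))
  expect_true(all(out$pixels %in% c(0L, 1L)))

  img <- fundus_image(array(7L, c(32, 32, 3)))
  expect_identical(resize_uniform(img, 32), img)
  expect_error(resize_uniform(img, 4))
})

test_that("green extraction picks channel 2 bit-exactly", {
  px <- array(0L, c(4, 4, 3))
  px[, , 1] <- 10L; px[, , 2] <- 20L; px[, , 3] <- 30L
  g <- extract_green(fundus_image(px))
  expect_true(all(g$pixels == 20L))

  set.seed(3)
  px <- array(sample(0:255, 6 * 6 * 3, TRUE), c(6, 6, 3))
  g <- extract_green(fundus_image(px))
  # elementwise oracle
  for (i in 1:6) for (j in 1:6) expect_identical(g$pixels[i, j], px[i, j, 2])

  bad <- structure(list(pixels = matrix(0, 4, 4), image_id = "x"),
                   class = "fundus_image")
  expect_error(extract_green(bad), class = "segassist_channel_error")
})

test_that("fundus and mask PNGs round-trip through disk", {
  set.seed(4)
  px <- array(sample(0:255, 24 * 24 * 3, TRUE), c(24, 24, 3))
  img <- fundus_image(px, "rt")
  f <- tempfile(fileext = ".png")
  write_fundus_png(img, f)
  expect_identical(read_fundus_png(f, "rt")$pixels, img$pixels)

  mk <- nv_mask(random_mask(24), "rtm")
  fm <- tempfile(fileext = ".png")
  write_mask_png(mk, fm)
  expect_identical(read_mask_png(fm, "rtm")$pixels, mk$pixels)
})

test_that("manifest CSV round-trips and schema violations are caught", {
  m <- fixture_dataset(c(3, 2, 2, 4), seed = 11)
  f <- tempfile(fileext = ".csv")
  write_manifest(m, f)
  expect_equal(read_manifest(f), m)

  bad <- m[, setdiff(names(m), "category")]
  fb <- tempfile(fileext = ".csv")
  readr::write_csv(bad, fb)
  expect_error(read_manifest(fb), class = "segassist_schema_error")

  m2 <- m
  m2$category[1] <- 5L
  f2 <- tempfile(fileext = ".csv")
  readr::write_csv(m2, f2)
  expect_error(read_manifest(f2), class = "segassist_domain_error")
})

test_that("split fractions are apportioned exactly per category", {
  m <- tibble::tibble(image_id = sprintf("i%03d", 1:100),
                      image_path = "x.png", mask_path = "m.png",
                      category = 0L, split = "unassigned")
  out <- assign_splits(m, split_spec(c(0.75, 0.08, 0.17), TRUE, 1))
  expect_equal(unname(table(out$split)[c("train", "val", "test")]),
               c(75L, 8L, 17L), ignore_attr = TRUE)
})

test_that("splits partition rows, stratify per category and are seeded", {
  m <- fixture_dataset(c(20, 10, 6, 14), seed = 31)
  sp <- split_spec(c(0.75, 0.08, 0.17), TRUE, 9)
  a <- assign_splits(m, sp)
  b <- assign_splits(m, sp)
  expect_identical(a, b)
  expect_false(any(a$split == "unassigned"))
  expect_setequal(a$image_id, m$image_id)
  for (cat in 0:3) {
    n <- sum(m$category == cat)
    expect_equal(sum(a$category == cat & a$split != "unassigned"), n)
  }
})

test_that("an explicit per-category count override reproduces a partition", {
  totals <- c(604, 141, 42, 376)
  counts <- rbind(c(434, 55, 115), c(103, 13, 25), c(31, 3, 8),
                  c(299, 27, 50))
  m <- tibble::tibble(
    image_id = sprintf("i%05d", seq_len(sum(totals))),
    image_path = "x.png", mask_path = "m.png",
    category = rep(0:3, totals), split = "unassigned")
  out <- assign_splits(m, split_spec(rng_seed = 2), counts_override = counts)
  tab <- table(out$category, out$split)
  expect_equal(sum(out$split == "train"), 867)
  expect_equal(sum(out$split == "val"), 98)
  expect_equal(sum(out$split == "test"), 198)
  expect_equal(nrow(out), 1163)
  expect_equal(unname(tab["3", "train"]), 299)
})

test_that("empty manifests cannot be split", {
  expect_error(assign_splits(tibble::tibble(
    image_id = character(), image_path = character(),
    mask_path = character(), category = integer(), split = character())),
    class = "segassist_empty_error")
})
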
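one_square_bank <- function(kind = "real", h = 2L, w = 2L, value = 0.9) {
  co <- wheatseg:::new_cutout(array(value, c(h, w, 3L)), matrix(1, h, w),
                              c(0L, 0L, h, w), kind, "test")
  wheatseg:::new_cutout_set(list(co), kind, "test")
}

test_that("identity augmentation returns the cutout bit-for-bit", {
  sc <- small_scene()
  co <- sc$real$cutouts[[1]]
  out <- augment_cutout(co, rng_seed = 4, params = identity_aug_params())
  expect_identical(out$patch, co$patch)
  expect_identical(out$footprint, co$footprint)
})

test_that("horizontal flip is an involution on the footprint", {
  sc <- small_scene()
  co <- sc$real$cutouts[[2]]
  flip_only <- aug_params(p_flip_h = 1, p_flip_v = 0, rotation = c(0, 0),
                          scale = c(1, 1), elastic = list(p = 0, alpha = 0, sigma = 1))
  once <- augment_cutout(co, 1, flip_only)
  twice <- augment_cutout(once, 1, flip_only)
  expect_identical(twice$footprint, co$footprint)
  expect_identical(twice$patch, co$patch)
})

test_that("resizing scales the footprint area approximately quadratically", {
  co <- wheatseg:::new_cutout(array(0.5, c(2, 2, 3)), matrix(1, 2, 2),
                              c(0L, 0L, 2L, 2L), "real", "t")
  scale2 <- aug_params(p_flip_h = 0, p_flip_v = 0, rotation = c(0, 0),
                       scale = c(2, 2), elastic = list(p = 0, alpha = 0, sigma = 1))
  out <- augment_cutout(co, 3, scale2)
  expect_gte(sum(out$footprint), 12)
  expect_lte(sum(out$footprint), 20)
})

test_that("augmentation is seed-deterministic and transforms patch and footprint together", {
  sc <- small_scene()
  co <- sc$real$cutouts[[1]]
  a1 <- augment_cutout(co, rng_seed = 10)
  a2 <- augment_cutout(co, rng_seed = 10)
  expect_identical(a1$patch, a2$patch)
  expect_identical(a1$footprint, a2$footprint)
  expect_identical(dim(a1$patch)[1:2], dim(a1$footprint))
  expect_gt(sum(a1$footprint), 0)
})

test_that("an empty placement budget reproduces the background exactly", {
  bg <- small_background()
  s <- compose(bg, one_square_bank("real"), one_square_bank("fake"),
               rng_seed = 1, n_range = c(0L, 0L), color_aug = FALSE)
  expect_identical(s$image, bg$image)
  expect_identical(sum(s$mask), 0)
  expect_length(s$placements, 0L)
})

test_that("a forced single placement writes the translated footprint into the mask", {
  canvas <- array(0, c(12, 12, 3))
  patch <- array(0.9, c(2, 2, 3))
  res <- wheatseg:::paste_cutout(canvas, patch, matrix(1, 2, 2), c(5L, 5L))
  expect_identical(sum(res$fp), 4)
  expect_identical(res$fp[4:5, 4:5], matrix(1, 2, 2))
  expect_identical(res$canvas[4, 4, 1], 0.9)
  # border clipping keeps only in-canvas pixels
  res2 <- wheatseg:::paste_cutout(canvas, patch, matrix(1, 2, 2), c(1L, 1L))
  expect_lt(sum(res2$fp), 4)
  expect_gt(sum(res2$fp), 0)
})

test_that("the stored mask equals an independent re-rasterization of the placement log", {
  sc <- small_scene()
  bg <- small_background()
  for (seed in c(1, 7, 23)) {
    s <- compose(bg, sc$real, sc$fake, rng_seed = seed, n_range = c(5L, 15L))
    expect_identical(s$mask, rasterize_placements(s))
    fakes <- Filter(function(p) p$kind == "fake", s$placements)
    expect_gt(length(fakes), 0)
  }
})

test_that("color augmentation changes the image but never the mask", {
  sc <- small_scene()
  bg <- small_background()
  s_on <- compose(bg, sc$real, sc$fake, rng_seed = 11, n_range = c(5L, 10L),
                  color_aug = TRUE)
  s_off <- compose(bg, sc$real, sc$fake, rng_seed = 11, n_range = c(5L, 10L),
                   color_aug = FALSE)
  expect_identical(s_on$mask, s_off$mask)
  expect_false(identical(s_on$image, s_off$image))
})

test_that("compose validates empty banks", {
  bg <- small_background()
  empty <- wheatseg:::new_cutout_set(list(), "real", "t")
  expect_error(compose(bg, empty, one_square_bank("fake"), rng_seed = 1,
                       n_range = c(2L, 2L)), "real bank is empty")
})

test_that("synthesize_dataset writes n pairs deterministically", {
  sc <- small_scene()
  bgs <- list(small_background(1), small_background(2))
  d1 <- tempfile("syn1"); d2 <- tempfile("syn2")
  m1 <- synthesize_dataset(bgs, sc$real, sc$fake, n_images = 3, base_seed = 42,
                           out_dir = d1, n_range = c(3L, 6L))
  m2 <- synthesize_dataset(bgs, sc$real, sc$fake, n_images = 3, base_seed = 42,
                           out_dir = d2, n_range = c(3L, 6L))
  expect_identical(nrow(m1), 3L)
  expect_true(all(file.exists(m1$image_path)))
  expect_true(all(file.exists(m1$mask_path)))
  for (i in 1:3) {
    expect_identical(readBin(m1$mask_path[i], "raw", 1e6),
                     readBin(m2$mask_path[i], "raw", 1e6))
    expect_identical(readBin(m1$image_path[i], "raw", 1e6),
                     readBin(m2$image_path[i], "raw", 1e6))
  }
  # empty dataset: manifest only
  d0 <- tempfile("syn0")
  m0 <- synthesize_dataset(bgs, sc$real, sc$fake, n_images = 0, base_seed = 1,
                           out_dir = d0)
  expect_identical(nrow(m0), 0L)
  expect_length(list.files(file.path(d0, "images")), 0L)
})

test_that("manifests round-trip and validate", {
  sc <- small_scene()
  d <- tempfile("syn")
  m <- synthesize_dataset(list(small_background()), sc$real, sc$fake,
                          n_images = 2, base_seed = 0, out_dir = d,
                          n_range = c(2L, 4L))
  rt <- read_manifest(file.path(d, "manifest.csv"))
  expect_identical(rt$id, m$id)
  expect_silent(wheatseg:::validate_manifest(rt))
  file.remove(rt$mask_path[1])
  expect_error(wheatseg:::validate_manifest(rt), "missing files")
})
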
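test_that("tissue table places water and bone where expected", {
  tt <- default_tissues()
  expect_equal(tt$water, c(0, 0))
  expect_equal(tt$air, c(-1000, -1000))
  # bone at kV 1000 maps near 411 HU on the MV scale
  expect_equal(tt$bone[1], 1000)
  expect_equal(tt$bone[2], 0.70 * 1000 - 288.56, tolerance = 1e-12)
})

test_that("a single water ellipse is modality-invariant", {
  spec <- phantom_spec(canvas_size = 64, pixel_spacing = 4,
                       ellipses = list(list(center = c(0, 0),
                                            axes = c(80, 60), rot = 0,
                                            tissue = "water")))
  ph <- make_phantom(spec)
  expect_identical(ph$kv$values, ph$mv$values)
  inside <- ph$mask$values > 0
  expect_true(all(ph$kv$values[inside] == 0))
  expect_true(all(ph$kv$values[!inside] == -1000))
})

test_that("ellipses outside the canvas are rejected", {
  expect_error(
    phantom_spec(canvas_size = 64, pixel_spacing = 4,
                 ellipses = list(list(center = c(120, 0), axes = c(40, 30),
                                      rot = 0, tissue = "soft"))),
    "outside canvas")
})

test_that("generation is bit-identical under a fixed seed", {
  a <- make_phantom(random_phantom_spec(42))
  b <- make_phantom(random_phantom_spec(42))
  expect_identical(a$kv$values, b$kv$values)
  expect_identical(a$mv$values, b$mv$values)
  expect_identical(a$mask$values, b$mask$values)
})

test_that("paired images share geometry and the configured regression line", {
  for (seed in c(3, 17, 31, 59)) {
    ph <- make_phantom(random_phantom_spec(seed))
    b <- ph$mask$values > 0
    # identical label geometry: air pixels agree exactly
    expect_identical(ph$kv$values == -1000, ph$mv$values == -1000)
    fit <- hu_regression(ph$mv$values, ph$kv$values, b * 1)
    expect_lt(abs(fit$slope - 0.70), 0.05)
    expect_lt(fit$intercept, 0)
  }
})

test_that("body-pixel HU values span the clinical range across a dataset", {
  vals <- unlist(lapply(1:40, function(i) {
    ph <- make_phantom(random_phantom_spec(i))
    ph$kv$values[ph$mask$values > 0]
  }))
  expect_lt(min(vals), -900)
  expect_gt(max(vals), 300)
})

test_that("threshold masking keeps the body, fills holes, drops satellites", {
  expect_error(body_mask_from_threshold(
    image_grid(matrix(-1000, 32, 32), 4), -300), "no body found")
  n <- 96
  xy <- (seq_len(n) - (n + 1) / 2) * 4
  X <- matrix(xy, n, n, byrow = TRUE); Y <- matrix(xy, n, n)
  disc <- (X^2 + Y^2) <= 120^2
  img <- matrix(-1000, n, n); img[disc] <- 0
  m <- body_mask_from_threshold(image_grid(img, 4), -300)
  expect_identical(m$values > 0, disc)
  # satellite blob is excluded; a low-density hole is filled
  img2 <- img
  img2[2:4, 2:4] <- 200
  hole <- (X - 40)^2 + Y^2 <= 30^2
  img2[hole] <- -800
  m2 <- body_mask_from_threshold(image_grid(img2, 4), -300)
  expect_true(all(m2$values[2:4, 2:4] == 0))
  expect_true(all(m2$values[hole] == 1))
})

test_that("affine augmentation honours identity, translation and rotation", {
  ph <- small_phantom(7)
  ident <- affine_augment(ph$mv, list(rotation = 0, translation = c(0, 0),
                                      scale = 1))
  expect_identical(ident$values, ph$mv$values)
  expect_error(affine_augment(ph$mv, list(scale = 0)), "positive")
  # +5 pixel shift of a delta image moves the delta by 5 pixels
  dm <- matrix(-1000, 64, 64); dm[30, 20] <- 1000
  delta <- image_grid(dm, 4)
  sh <- affine_augment(delta, list(translation = c(5 * 4, 0)))
  expect_equal(which(sh$values == max(sh$values), arr.ind = TRUE)[1, ],
               c(row = 30, col = 25))
  # four 90-degree rotations return the original within interpolation error
  img <- ph$mv
  for (k in 1:4) img <- affine_augment(img, list(rotation = 90))
  inner <- 10:86
  expect_lt(mean(abs(img$values[inner, inner] - ph$mv$values[inner, inner])), 1)
  # masks are warped jointly and stay binary
  pair <- affine_augment(list(ph$mv, ph$mask),
                         list(rotation = 10, translation = c(8, -4)))
  expect_true(all(pair[[2]]$values %in% c(0, 1)))
  body_moved <- pair[[1]]$values > -950
  expect_gt(mean(body_moved == (pair[[2]]$values > 0)), 0.95)
})

test_that("affine ranges sample one joint transform reproducibly", {
  ph <- small_phantom(9)
  rg <- list(rot_range = c(-10, 10), trans_range = c(-8, 8),
             scale_range = c(0.9, 1.1))
  a <- affine_augment(ph$kv, rg, seed = 5)
  b <- affine_augment(ph$kv, rg, seed = 5)
  expect_identical(a$values, b$values)
})

test_that("make_dataset writes a reproducible manifest and files", {
  d1 <- file.path(tempdir(), "ds1"); d2 <- file.path(tempdir(), "ds2")
  m1 <- make_dataset(4, d1, seed = 7)
  m2 <- make_dataset(4, d2, seed = 7)
  expect_length(m1$slices, 4)
  expect_true(file.exists(file.path(d1, "manifest.json")))
  for (i in 1:4) {
    a <- read_image(m1$slices[[i]]$kv)
    b <- read_image(m2$slices[[i]]$kv)
    expect_identical(a$values, b$values)
  }
  splits <- vapply(m1$slices, `[[`, "", "split")
  expect_true(all(c("train", "test") %in% splits))
  unlink(c(d1, d2), recursive = TRUE)
})
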
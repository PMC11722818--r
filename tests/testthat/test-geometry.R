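test_that("HU <-> attenuation conversion is the stated linear map", {
  img <- image_grid(matrix(c(0, -1000, 1000, 500), 2, 2), 1)
  mu <- hu_to_mu(img, 0.02)
  expect_equal(as.numeric(mu$values), c(0.02, 0, 0.04, 0.03))
  back <- mu_to_hu(mu, 0.02)
  expect_equal(back$values, img$values)
})

test_that("analytic disc projection matches the chord formula", {
  g <- scan_geometry("parallel", n_det = 401, det_spacing = 1,
                     n_views = 180, ang_range = 180)
  s <- analytic_disc_projection(c(0, 0), 100, 0.02, g)
  t <- (seq_len(g$n_det) - (g$n_det + 1) / 2) * g$det_spacing
  # at the centre: 2*mu*R; at d = 60: 2*mu*sqrt(100^2-60^2) = 3.2; outside: 0
  expect_equal(s$values[1, t == 0], 4, tolerance = 1e-12)
  expect_equal(s$values[1, t == 60], 2 * 0.02 * 80, tolerance = 1e-12)
  expect_true(all(s$values[, abs(t) > 100.5] == 0))
})

test_that("numeric forward projection agrees with the analytic oracle", {
  g <- scan_geometry("parallel", n_det = 128, det_spacing = 2,
                     n_views = 45, ang_range = 180)
  img <- disc_image(n = 128, spacing = 2, radius = 80, mu = 0.02)
  s_num <- forward_project(img, g)
  s_ana <- analytic_disc_projection(c(0, 0), 80, 0.02, g)
  expect_lt(sqrt(mean((s_num$values - s_ana$values)^2)) / max(s_ana$values),
            0.01)
})

test_that("projection is a linear operator and zero maps to zero", {
  g <- scan_geometry("parallel", n_det = 64, det_spacing = 4,
                     n_views = 16, ang_range = 180)
  z <- forward_project(image_grid(matrix(0, 48, 48), 5, unit = "mu"), g)
  expect_true(all(z$values == 0))
  set.seed(4)
  a <- matrix(runif(48 * 48, 0, 0.03), 48, 48)
  b <- matrix(runif(48 * 48, 0, 0.03), 48, 48)
  pa <- forward_project(image_grid(a, 5, unit = "mu"), g)$values
  pb <- forward_project(image_grid(b, 5, unit = "mu"), g)$values
  pab <- forward_project(image_grid(a + b, 5, unit = "mu"), g)$values
  expect_equal(pab, pa + pb, tolerance = 1e-9)
})

test_that("forward projection requires attenuation units", {
  g <- disc_geom()
  expect_error(forward_project(image_grid(matrix(0, 8, 8), 1, unit = "HU"), g),
               "hu_to_mu")
})

test_that("rotating the phantom cyclically shifts parallel-beam views", {
  g <- scan_geometry("parallel", n_det = 96, det_spacing = 3,
                     n_views = 36, ang_range = 360)
  s1 <- analytic_disc_projection(c(50, 0), 60, 0.02, g)
  # rotate the disc by one view increment (10 degrees)
  th <- 10 * pi / 180
  c2 <- c(50 * cos(th), 50 * sin(th))
  s2 <- analytic_disc_projection(c2, 60, 0.02, g)
  expect_equal(s2$values[2:36, ], s1$values[1:35, ], tolerance = 1e-9)
})

test_that("FBP round trip recovers a disc and a phantom", {
  g <- scan_geometry("parallel", n_det = 360, det_spacing = 1,
                     n_views = 360, ang_range = 180)
  s <- ref_disc_sino(g)
  rec <- fbp_reconstruct(s, out_size = 128, spacing = 2)
  xy <- (seq_len(128) - 64.5) * 2
  X <- matrix(xy, 128, 128, byrow = TRUE); Y <- matrix(xy, 128, 128)
  interior <- ((X - 40)^2 + (Y + 25)^2) <= 90^2
  expect_lt(abs(mean(rec$values[interior]) - 0.02) / 0.02, 0.03)
  z <- fbp_reconstruct(sinogram(matrix(0, g$n_views, g$n_det), g), 64, 4)
  expect_true(all(z$values == 0))
  expect_error(fbp_reconstruct(sinogram(matrix(0, 1, 16),
                                        scan_geometry("parallel", 16, 4, 1, 180)),
                               32, 4),
               "2 views")
})

test_that("fan-beam projection and reconstruction agree with the disc", {
  gf <- scan_geometry("fan", n_det = 256, det_spacing = 0.0015,
                      n_views = 240, ang_range = 360, sad = 600)
  s <- analytic_disc_projection(c(20, -10), 100, 0.02, gf)
  rec <- fbp_reconstruct(s, out_size = 128, spacing = 2.5)
  xy <- (seq_len(128) - 64.5) * 2.5
  X <- matrix(xy, 128, 128, byrow = TRUE); Y <- matrix(xy, 128, 128)
  interior <- ((X - 20)^2 + (Y + 10)^2) <= 80^2
  expect_lt(abs(mean(rec$values[interior]) - 0.02) / 0.02, 0.05)
})

test_that("sinograms round-trip through disk serialization", {
  g <- scan_geometry("parallel", n_det = 32, det_spacing = 4, n_views = 8,
                     ang_range = 180)
  s <- truncate_sinogram(analytic_disc_projection(c(0, 0), 50, 0.02, g), 4)
  p <- tempfile(fileext = ".rds")
  write_sinogram(s, p, json_sidecar = TRUE)
  s2 <- read_sinogram(p)
  expect_identical(s2$values, s$values)
  expect_identical(s2$measured_mask, s$measured_mask)
  expect_true(file.exists(paste0(p, ".json")))
  unlink(c(p, paste0(p, ".json")))
})

test_that("images round-trip through NIfTI", {
  ph <- small_phantom(3)
  p <- tempfile(fileext = ".nii")
  write_image(ph$mv, p)
  back <- read_image(p)
  expect_equal(back$values, ph$mv$values, tolerance = 1e-6)
  expect_equal(back$spacing, 4)
  unlink(p)
})
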
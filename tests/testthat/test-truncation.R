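test_that("truncation zeroes and flags exactly the edge channels", {
  g <- disc_geom()
  s <- ref_disc_sino(g)
  expect_identical(truncate_sinogram(s, 0), s)
  tr <- truncate_sinogram(s, 30)
  expect_equal(sum(colSums(tr$measured_mask) == 0), 60)
  expect_true(all(tr$values[, c(1:30, 227:256)] == 0))
  expect_identical(tr$values[, 31:226], s$values[, 31:226])
  expect_error(truncate_sinogram(s, 128), "n_cut")
})

test_that("edge statistics reproduce exact lines and the chord derivative", {
  prof <- c(1, 2, 3, 4)
  es <- edge_stats(prof, rep(1L, 4), "right", n_fit = 4, det_spacing = 1)
  expect_equal(es$p_edge, 4)
  expect_equal(es$slope, 1)
  expect_equal(edge_stats(rep(2, 6), rep(1L, 6), "left", 3)$slope, 0)
  expect_equal(edge_stats(rep(0, 6), rep(1L, 6), "right", 3),
               list(p_edge = 0, slope = 0))
  # analytic water disc truncated at d = 60: p = 3.2, dp/dt = -2*mu*d/chord
  g <- scan_geometry("parallel", n_det = 401, det_spacing = 1,
                     n_views = 1, ang_range = 180)
  s <- analytic_disc_projection(c(0, 0), 100, 0.02, g)
  t <- (seq_len(401) - 201) * 1
  mask <- as.integer(t <= 60)
  es <- edge_stats(s$values[1, ], mask, "right", n_fit = 3,
                   det_spacing = 1)
  expect_equal(es$p_edge, 3.2, tolerance = 1e-9)
  expect_equal(es$slope, -2 * 0.02 * 60 / 80, tolerance = 0.05)
})

test_that("the water-cylinder fit solves the chord equations", {
  # p = 3.2, s = -0.03 is the disc of radius 100 seen 60 mm off-centre
  fit <- fit_water_cylinder(3.2, -0.03, 0.02)
  expect_equal(abs(fit$x_offset), 60, tolerance = 1e-9)
  expect_equal(fit$radius, 100, tolerance = 1e-9)
  # zero magnitude -> degenerate cylinder
  f0 <- fit_water_cylinder(0, -0.5, 0.02)
  expect_equal(c(f0$x_offset, f0$radius), c(0, 0))
  # zero slope -> apex: R = p / (2 mu)
  fa <- fit_water_cylinder(4, 0, 0.02)
  expect_equal(fa$x_offset, 0)
  expect_equal(fa$radius, 100)
})

test_that("per-view cylinder fits recover the disc in every affected view", {
  g <- disc_geom()
  s <- ref_disc_sino(g)
  for (cut in c(30, 64)) {
    tr <- truncate_sinogram(s, cut)
    fits <- fit_cylinders(tr, 0.02, n_fit = 3)
    t <- (seq_len(g$n_det) - (g$n_det + 1) / 2) * g$det_spacing
    th <- (fits$view - 1) * pi / 180
    c_t <- ref_disc$center[1] * cos(th) + ref_disc$center[2] * sin(th)
    affected <- ifelse(fits$edge == "right",
                       c_t + ref_disc$radius > t[g$n_det - cut],
                       c_t - ref_disc$radius < t[cut + 1])
    expect_gt(sum(affected), 50)
    expect_lt(max(abs(fits$radius[affected] - ref_disc$radius)) /
                ref_disc$radius, 0.02)
    expect_lt(max(abs(fits$t_center[affected] - c_t[affected])) /
                ref_disc$radius, 0.02)
  }
})

test_that("WCE fill is exact on a water disc and leaves measured data alone", {
  g <- disc_geom()
  s <- ref_disc_sino(g)
  expect_identical(extrapolate_wce(s)$values, s$values)
  tr <- truncate_sinogram(s, 64)
  w <- extrapolate_wce(tr, 0.02, n_fit = 3, feather = 4)
  filled <- tr$measured_mask == 0L
  expect_identical(w$values[!filled], tr$values[!filled])
  expect_true(all(w$measured_mask[filled] == 2L))
  expect_lt(sqrt(mean((w$values[filled] - s$values[filled])^2)) /
              max(s$values), 0.01)
  # continuity at the truncation boundary for every view (channel 64 is the
  # outermost filled channel, 65 the innermost measured one)
  jump <- vapply(seq_len(g$n_views), function(v) {
    abs(w$values[v, 64] - w$values[v, 65])
  }, 0)
  step <- max(abs(diff(s$values[1, ])))
  expect_lt(max(jump), 2 * step)
})

test_that("symmetric extrapolation mirrors the edge and tapers to zero", {
  g <- scan_geometry("parallel", n_det = 16, det_spacing = 1, n_views = 1,
                     ang_range = 180)
  prof <- c(rep(0, 4), 1, 2, 3, 4, 5, 6, 7, 8, rep(0, 4))
  s <- sinogram(matrix(prof, 1), g)
  s$measured_mask[, c(1:4, 13:16)] <- 0L
  sy <- extrapolate_symmetric(s)
  expect_identical(extrapolate_symmetric(ref_disc_sino(disc_geom()))$values,
                   ref_disc_sino(disc_geom())$values)
  # right edge: mirror of channels 12, 11, 10, 9 = 8, 7, 6, 5 with taper 1..0
  expect_equal(sy$values[1, 13], 8)
  expect_equal(sy$values[1, 16], 0)
  expect_true(all(diff(sy$values[1, 13:16]) < 0))
  # left edge mirrors 1, 2, 3 outward and filled run length equals the cut
  expect_equal(sy$values[1, 4], 1)
  expect_equal(sum(sy$measured_mask == 2L), 8)
})

test_that("mass is conserved across views and restored by WCE", {
  g <- scan_geometry("parallel", n_det = 360, det_spacing = 1,
                     n_views = 180, ang_range = 180)
  s <- ref_disc_sino(g)
  mc <- mass_consistency(s)
  expect_equal(mean(mc$mass), 0.02 * pi * 100^2, tolerance = 0.005)
  expect_true(all(abs(mc$normalized - 1) < 0.005))
  z <- mass_consistency(sinogram(matrix(0, g$n_views, g$n_det), g))
  expect_true(all(z$mass == 0))
  tr <- truncate_sinogram(s, 64)
  w <- extrapolate_wce(tr, 0.02)
  cv <- function(x) stats::sd(x) / mean(x)
  expect_lt(cv(mass_consistency(w)$mass), cv(mass_consistency(tr)$mass))
  # truncated views fall below 1 exactly where rays cross the cut
  mt <- mass_consistency(tr)
  expect_true(any(mt$normalized < 1 - 0.01))
})

test_that("precorrection reduces the truncated-reconstruction error", {
  ph <- small_phantom(21)
  g <- scan_geometry("parallel", n_det = 144, det_spacing = 3.4,
                     n_views = 120, ang_range = 180)
  sino <- forward_project(hu_to_mu(ph$mv, 0.02), g)
  full <- precorrect(sino, "none", out_size = 96, spacing = 4,
                     mask_threshold = NA)
  plain <- mu_to_hu(fbp_reconstruct(sino, 96, 4), 0.02)
  expect_equal(full$values, plain$values, tolerance = 1e-12)
  tr <- truncate_sinogram(sino, 30)
  bm <- ph$mask$values
  rec <- list(none = precorrect(tr, "none", 96, 4, mask_threshold = NA),
              sym = precorrect(tr, "symmetric", 96, 4, mask_threshold = NA),
              wce = precorrect(tr, "wce", 96, 4, mask_threshold = NA))
  m <- vapply(rec, function(r) mae(r$values, ph$mv$values, bm), 0)
  expect_lt(m[["wce"]], m[["none"]])
})
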
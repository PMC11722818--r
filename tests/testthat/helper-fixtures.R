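# shared fixtures: everything is generated in code, at small sizes

# geometry in which a truncation cut actually crosses the reference disc
disc_geom <- function(n_det = 256, n_views = 180) {
  scan_geometry("parallel", n_det = n_det, det_spacing = 1,
                n_views = n_views, ang_range = 180)
}

# the reference off-centre water disc used throughout the truncation tests
ref_disc <- list(center = c(40, -25), radius = 100, mu = 0.02)

ref_disc_sino <- function(geom = disc_geom()) {
  analytic_disc_projection(ref_disc$center, ref_disc$radius, ref_disc$mu, geom)
}

# small thorax-like phantom (96 px at 4 mm)
small_phantom <- function(seed = 11) make_phantom(random_phantom_spec(seed))

# a disc image_grid in attenuation units on an n x n grid
disc_image <- function(n = 96, spacing = 4, radius = 120, mu = 0.02,
                       center = c(0, 0)) {
  xy <- (seq_len(n) - (n + 1) / 2) * spacing
  X <- matrix(xy, n, n, byrow = TRUE); Y <- matrix(xy, n, n)
  vals <- (((X - center[1])^2 + (Y - center[2])^2) <= radius^2) * mu
  image_grid(vals, spacing, modality = "MV", unit = "mu")
}

# brute-force SSIM oracle: literal local-window formula, plain loops,
# independent of the package's separable-filter implementation
ssim_bruteforce <- function(x, y, dynamic_range = 2524, sigma = 1.5,
                            width = 11) {
  half <- (width - 1) / 2
  g1 <- exp(-((-half):half)^2 / (2 * sigma^2))
  w <- outer(g1, g1); w <- w / sum(w)
  c1 <- (0.01 * dynamic_range)^2; c2 <- (0.03 * dynamic_range)^2
  n <- nrow(x); m <- ncol(x)
  refl <- function(idx, limit) {
    idx <- ifelse(idx < 1, 1 - idx, idx)
    ifelse(idx > limit, 2 * limit + 1 - idx, idx)
  }
  smap <- matrix(NA_real_, n, m)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      ii <- pmin(pmax(refl(i + (-half):half, n), 1), n)
      jj <- pmin(pmax(refl(j + (-half):half, m), 1), m)
      px <- x[ii, jj]; py <- y[ii, jj]
      mx <- sum(w * px); my <- sum(w * py)
      vx <- sum(w * px^2) - mx^2; vy <- sum(w * py^2) - my^2
      cxy <- sum(w * px * py) - mx * my
      smap[i, j] <- ((2 * mx * my + c1) * (2 * cxy + c2)) /
        ((mx^2 + my^2 + c1) * (vx + vy + c2))
    }
  }
  mean(smap)
}
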
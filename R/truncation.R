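#' Simulate detector truncation of a sinogram
#'
#' Zeroes the first and last `n_cut` detector channels of every view and
#' flags them as truncated in the measured mask, emulating a body that
#' extends beyond the scan field of view. The per-side convention follows
#' the symmetric body-larger-than-sFOV geometry and is configurable through
#' `n_cut`.
#'
#' @param sino a [sinogram].
#' @param n_cut channels removed per side (`0 <= n_cut < n_det/2`).
#' @return A [sinogram] with zeroed edge channels and updated mask.
#' @export
truncate_sinogram <- function(sino, n_cut) {
  stopifnot(inherits(sino, "sinogram"), n_cut >= 0,
            n_cut < sino$geometry$n_det / 2)
  if (n_cut == 0) return(sino)
  nd <- sino$geometry$n_det
  cut <- c(seq_len(n_cut), (nd - n_cut + 1):nd)
  out <- sino
  out$values[, cut] <- 0
  out$measured_mask[, cut] <- 0L
  out
}

#' Projection value and slope at a truncation edge
#'
#' Returns the projection amplitude at the last measured channel and the
#' least-squares slope (per mm, or per radian for fan geometry) over the
#' `n_fit` measured channels adjacent to the edge. These are the boundary
#' statistics that drive the water-cylinder fit.
#'
#' @param profile one view's channel vector.
#' @param mask_row measured mask for that view (1 = measured).
#' @param edge `"left"` or `"right"`.
#' @param n_fit number of edge channels used for the slope fit.
#' @param det_spacing channel spacing used to convert the slope to per-mm.
#' @return `list(p_edge, slope)`; `(0, 0)` when the edge region is all zero
#'   or unmeasured.
#' @export
edge_stats <- function(profile, mask_row, edge = c("left", "right"),
                       n_fit = 3, det_spacing = 1) {
  edge <- match.arg(edge)
  measured <- which(mask_row == 1L)
  if (length(measured) < n_fit) return(list(p_edge = 0, slope = 0))
  k_edge <- if (edge == "left") min(measured) else max(measured)
  ks <- if (edge == "left") k_edge + 0:(n_fit - 1) else k_edge - 0:(n_fit - 1)
  ks <- ks[ks %in% measured]
  p_edge <- profile[k_edge]
  if (p_edge <= 0 || length(ks) < 2) return(list(p_edge = max(p_edge, 0), slope = 0))
  tt <- ks * det_spacing
  fit <- stats::lm.fit(cbind(1, tt), profile[ks])
  list(p_edge = p_edge, slope = unname(fit$coefficients[2]))
}

#' Fit a water cylinder to edge statistics
#'
#' Given the projection amplitude `p` and slope `s` at a truncation edge,
#' solves for the offset and radius of the water-equivalent cylinder whose
#' chord profile matches both:
#' `x = s * p / (4 mu_w^2)` and `R = sqrt(p^2 / (4 mu_w^2) + x^2)`.
#' `x` is the signed distance from the truncation edge to the cylinder
#' centre along the detector coordinate (negative = centre inside the
#' measured region, i.e. the profile is already decaying at the edge).
#'
#' @param p_edge projection value at the edge (line integral).
#' @param slope projection slope at the edge, per mm.
#' @param mu_water attenuation of water in mm^-1.
#' @return A `cylinder_fit` list with `p_edge`, `slope`, `x_offset`,
#'   `radius`, `mu_water`.
#' @export
fit_water_cylinder <- function(p_edge, slope, mu_water = 0.02) {
  stopifnot(mu_water > 0)
  if (p_edge <= 0) {
    x <- 0; r <- 0
  } else {
    x <- slope * p_edge / (4 * mu_water^2)
    r <- sqrt(p_edge^2 / (4 * mu_water^2) + x^2)
  }
  structure(list(p_edge = p_edge, slope = slope, x_offset = x,
                 radius = r, mu_water = mu_water),
            class = "cylinder_fit")
}

# Fit a water cylinder to one edge of one profile. The magnitude/slope pair
# of the chord profile satisfies s*p = (p^2)'/2 and p^2 is exactly quadratic
# in t for a cylinder, so p and s are estimated jointly by a least-squares
# line on p^2 over the n_fit edge samples (evaluated at the window centre),
# which makes the fit exact on noise-free cylinder data at any truncation
# depth. Returns NULL when the edge region carries no signal.
wce_fit_edge <- function(profile, t, k_edge, sgn, mu_water, n_fit) {
  ks <- k_edge - sgn * (0:(n_fit - 1))
  ks <- ks[ks >= 1 & ks <= length(profile)]
  ks <- ks[profile[ks] > 0]
  p_edge <- profile[k_edge]
  if (p_edge <= 0 || length(ks) == 0) return(NULL)
  if (length(ks) == 1) {
    # degenerate window: symmetric cylinder matching the edge magnitude
    return(structure(list(p_edge = p_edge, slope = 0, x_offset = 0,
                          radius = p_edge / (2 * mu_water),
                          t_center = t[k_edge], mu_water = mu_water),
                     class = "cylinder_fit"))
  }
  u <- sgn * (t[ks] - t[k_edge])        # outward coordinate from the edge
  y <- profile[ks]^2
  a <- stats::cov(u, y) / stats::var(u) # d(p^2)/du at the window centre
  u_bar <- mean(u); y_bar <- mean(y)
  p_c <- sqrt(max(y_bar, 0))
  s_c <- if (p_c > 0) a / (2 * p_c) else 0
  fit <- fit_water_cylinder(p_c, s_c, mu_water)
  fit$p_edge <- p_edge
  # the fit is referenced to the window centre u_bar; shift the offset so it
  # is measured from the truncation edge (radius is reference-independent)
  fit$x_offset <- fit$x_offset + u_bar
  fit$t_center <- t[k_edge] + sgn * fit$x_offset
  fit
}

# fill one truncated edge with the fitted cylinder chords, cosine-feathering
# any boundary mismatch (zero for true water cylinders) into the fill
wce_fill_edge <- function(profile, t, cut_idx, k_edge, sgn, mu_water, n_fit,
                          feather) {
  fit <- wce_fit_edge(profile, t, k_edge, sgn, mu_water, n_fit)
  if (is.null(fit)) {
    profile[cut_idx] <- 0
    return(profile)
  }
  chord <- function(tt) {
    2 * mu_water * sqrt(pmax(fit$radius^2 - (tt - fit$t_center)^2, 0))
  }
  fill <- chord(t[cut_idx])
  if (feather > 0) {
    # carry the (small) boundary mismatch into the fill so the profile is
    # continuous at the truncation edge even for non-water objects
    delta <- fit$p_edge - chord(t[k_edge])
    nf <- min(feather, length(fill))
    w <- cos(pi * (seq_len(nf) - 1) / (2 * feather))
    fill[seq_len(nf)] <- pmax(fill[seq_len(nf)] + delta * w, 0)
  }
  profile[cut_idx] <- fill
  profile
}

#' Per-view water-cylinder fits of a truncated sinogram
#'
#' Runs the water-cylinder fit on every truncated edge of every view and
#' returns the fitted parameters: the edge magnitude `p_edge`, slope, the
#' signed outward offset `x_offset` from the truncation edge to the
#' cylinder centre (mm), and the radius (mm).
#'
#' @inheritParams extrapolate_wce
#' @return A data frame with one row per (view, edge) carrying a fit.
#' @export
fit_cylinders <- function(sino, mu_water = 0.02, n_fit = 3) {
  stopifnot(inherits(sino, "sinogram"))
  geom <- sino$geometry
  t <- det_coords(geom)
  rows <- list()
  for (v in seq_len(geom$n_views)) {
    mrow <- sino$measured_mask[v, ]
    if (all(mrow == 1L)) next
    measured <- which(mrow == 1L)
    for (edge in c("left", "right")) {
      sgn <- if (edge == "left") -1 else 1
      k_edge <- if (edge == "left") min(measured) else max(measured)
      has_cut <- if (edge == "left") k_edge > 1 else k_edge < geom$n_det
      if (!has_cut) next
      fit <- wce_fit_edge(sino$values[v, ], t, k_edge, sgn, mu_water, n_fit)
      if (is.null(fit)) next
      rows[[length(rows) + 1]] <- data.frame(
        view = v, edge = edge, p_edge = fit$p_edge,
        x_offset = fit$x_offset, radius = fit$radius,
        t_center = fit$t_center)
    }
  }
  if (!length(rows)) {
    return(data.frame(view = integer(), edge = character(),
                      p_edge = numeric(), x_offset = numeric(),
                      radius = numeric(), t_center = numeric()))
  }
  do.call(rbind, rows)
}

#' Water-cylinder extrapolation of a truncated sinogram
#'
#' For every view and each truncated edge, fits a water-equivalent cylinder
#' to the projection value and slope at the truncation boundary and extends
#' the profile with that cylinder's chord lengths,
#' `2 mu_w sqrt(R^2 - d^2)`, clipped at zero. The fill is continuous at the
#' boundary by construction and exact when the object really is a water
#' cylinder. Measured samples are never modified; filled channels are
#' flagged `2` in the mask.
#'
#' @param sino a truncated [sinogram].
#' @param mu_water attenuation of water in mm^-1.
#' @param n_fit edge channels used for the slope estimate.
#' @param feather channels over which the fill is cosine-blended with the
#'   tangent continuation of the measured profile (0 disables).
#' @return A [sinogram] with truncated channels filled.
#' @export
extrapolate_wce <- function(sino, mu_water = 0.02, n_fit = 3, feather = 0) {
  stopifnot(inherits(sino, "sinogram"))
  geom <- sino$geometry
  t <- det_coords(geom)
  out <- sino
  for (v in seq_len(geom$n_views)) {
    mrow <- sino$measured_mask[v, ]
    if (all(mrow == 1L)) next
    measured <- which(mrow == 1L)
    prof <- sino$values[v, ]
    left_cut <- which(mrow != 1L & seq_along(mrow) < min(measured))
    right_cut <- which(mrow != 1L & seq_along(mrow) > max(measured))
    if (length(left_cut)) {
      prof <- wce_fill_edge(prof, t, rev(left_cut), min(measured), -1,
                            mu_water, n_fit, feather)
    }
    if (length(right_cut)) {
      prof <- wce_fill_edge(prof, t, right_cut, max(measured), 1,
                            mu_water, n_fit, feather)
    }
    out$values[v, ] <- prof
    out$measured_mask[v, c(left_cut, right_cut)] <- 2L
  }
  out
}

#' Symmetric-mirror extrapolation of a truncated sinogram
#'
#' Fills each truncated edge by reflecting the measured samples about the
#' truncation boundary, linearly tapered to zero at the detector end. This
#' is the simple padding baseline against which water-cylinder
#' extrapolation is compared.
#'
#' @inheritParams extrapolate_wce
#' @return A [sinogram] with truncated channels filled.
#' @export
extrapolate_symmetric <- function(sino) {
  stopifnot(inherits(sino, "sinogram"))
  out <- sino
  nd <- sino$geometry$n_det
  for (v in seq_len(sino$geometry$n_views)) {
    mrow <- sino$measured_mask[v, ]
    if (all(mrow == 1L)) next
    measured <- which(mrow == 1L)
    prof <- sino$values[v, ]
    k_lo <- min(measured); k_hi <- max(measured)
    # mirror about the boundary between the last measured and first cut
    # channel, so the first filled value repeats the edge value; taper
    # linearly from 1 at the boundary to 0 at the detector end
    taper_w <- function(n_c) if (n_c > 1) (n_c - seq_len(n_c)) / (n_c - 1) else 1
    left_cut <- which(mrow != 1L & seq_along(mrow) < k_lo)
    right_cut <- which(mrow != 1L & seq_along(mrow) > k_hi)
    if (length(left_cut)) {
      ord <- rev(left_cut)  # outward, towards channel 1
      mirror <- pmin(pmax(2 * k_lo - 1 - ord, k_lo), k_hi)
      prof[ord] <- prof[mirror] * taper_w(length(ord))
    }
    if (length(right_cut)) {
      ord <- right_cut
      mirror <- pmin(pmax(2 * k_hi + 1 - ord, k_lo), k_hi)
      prof[ord] <- prof[mirror] * taper_w(length(ord))
    }
    out$values[v, ] <- prof
    out$measured_mask[v, c(left_cut, right_cut)] <- 2L
  }
  out
}

#' Per-view mass of a sinogram
#'
#' For a parallel beam, the integral of every projection view equals the
#' total attenuation mass of the object, so the per-view mass
#' `sum_k p[v, k] * dt` is constant across views for a fully covered
#' object; views whose rays cross a truncated region fall short. The
#' normalized variant (mass / max view mass) is the diagnostic used to
#' visualise truncation severity and to verify restoration after
#' extrapolation.
#'
#' @param sino a [sinogram].
#' @return `list(mass, normalized)`, each a length-`n_views` vector.
#' @export
mass_consistency <- function(sino) {
  stopifnot(inherits(sino, "sinogram"))
  mass <- rowSums(sino$values) * sino$geometry$det_spacing
  mx <- max(mass)
  normalized <- if (mx > 0) mass / mx else mass
  list(mass = mass, normalized = normalized)
}

#' Initial truncation correction (pre-corrected image)
#'
#' Applies the selected sinogram-domain extrapolation to a truncated
#' sinogram and reconstructs by filtered back-projection, returning the
#' pre-corrected image in HU with a thresholded body mask attached.
#' `method = "none"` reconstructs the zero-filled truncated baseline.
#'
#' @param truncated a truncated [sinogram].
#' @param method `"wce"`, `"symmetric"` or `"none"`.
#' @param out_size,spacing reconstruction grid.
#' @param mu_water water attenuation used for extrapolation and the HU scale.
#' @param n_fit,feather passed to [extrapolate_wce].
#' @param mask_threshold HU threshold for the body mask (`NA` skips masking).
#' @return An [image_grid] in HU (modality `"MV"`).
#' @export
precorrect <- function(truncated, method = c("wce", "symmetric", "none"),
                       out_size = 256, spacing = 1.5, mu_water = 0.02,
                       n_fit = 3, feather = 0, mask_threshold = -300) {
  method <- match.arg(method)
  filled <- switch(method,
                   wce = extrapolate_wce(truncated, mu_water, n_fit, feather),
                   symmetric = extrapolate_symmetric(truncated),
                   none = truncated)
  rec <- fbp_reconstruct(filled, out_size = out_size, spacing = spacing)
  hu <- mu_to_hu(rec, mu_water)
  hu$modality <- "MV"
  if (!is.na(mask_threshold)) {
    msk <- try(body_mask_from_threshold(hu, mask_threshold), silent = TRUE)
    if (!inherits(msk, "try-error")) hu$body_mask <- msk$values
  }
  hu
}
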
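#' Scan geometry
#'
#' Describes the acquisition geometry linking images and sinograms. The
#' default is a parallel beam, for which the water-cylinder math and the
#' mass-consistency diagnostic are exact; an equiangular fan beam is
#' available behind the same interface.
#'
#' @param beam `"parallel"` or `"fan"` (equiangular).
#' @param n_det number of detector channels.
#' @param det_spacing channel spacing: mm at the isocentre for parallel
#'   beam, radians for the fan beam.
#' @param n_views number of projection views.
#' @param ang_range angular range in degrees covered by the views (the view
#'   angles are `(0:(n_views-1)) * ang_range / n_views`).
#' @param sad source-axis distance in mm (fan beam only).
#' @return An object of class `scan_geometry`.
#' @export
scan_geometry <- function(beam = c("parallel", "fan"), n_det = 720,
                          det_spacing = 1, n_views = 360, ang_range = 360,
                          sad = 1000) {
  beam <- match.arg(beam)
  stopifnot(n_det >= 2, det_spacing > 0, n_views >= 1, ang_range > 0)
  g <- structure(list(beam = beam, n_det = n_det, det_spacing = det_spacing,
                      n_views = n_views, ang_range = ang_range, sad = sad),
                 class = "scan_geometry")
  g$sfov_radius <- sfov_radius(g)
  g
}

#' Scan-FOV radius of a (possibly truncated) detector
#'
#' Radius in mm at the isocentre covered by the detector after removing
#' `n_cut` channels per side; with `n_cut = 0` the full detector extent.
#'
#' @param geom a [scan_geometry].
#' @param n_cut channels removed per side.
#' @return Radius in mm (>= 0).
#' @export
sfov_radius <- function(geom, n_cut = 0) {
  half <- (geom$n_det / 2 - n_cut) * geom$det_spacing
  if (geom$beam == "fan") half <- geom$sad * sin(half)
  max(half, 0)
}

# signed lateral coordinate (mm for parallel, rad for fan) of each channel
det_coords <- function(geom) {
  (seq_len(geom$n_det) - (geom$n_det + 1) / 2) * geom$det_spacing
}

view_angles <- function(geom) {
  (seq_len(geom$n_views) - 1) * geom$ang_range / geom$n_views * pi / 180
}

#' Sinogram container
#'
#' A `n_views x n_det` matrix of line integrals of linear attenuation
#' (dimensionless) plus its [scan_geometry] and a mask of the same shape:
#' 1 where the channel was measured, 0 where it was truncated, 2 where a
#' truncated channel has been filled by extrapolation.
#'
#' @param values numeric `n_views x n_det` matrix.
#' @param geometry a [scan_geometry].
#' @param measured_mask integer matrix of the same shape (defaults to all 1).
#' @return An object of class `sinogram`.
#' @export
sinogram <- function(values, geometry, measured_mask = NULL) {
  values <- as.matrix(values)
  stopifnot(inherits(geometry, "scan_geometry"),
            nrow(values) == geometry$n_views,
            ncol(values) == geometry$n_det)
  if (is.null(measured_mask)) {
    measured_mask <- matrix(1L, nrow(values), ncol(values))
  }
  stopifnot(identical(dim(measured_mask), dim(values)))
  structure(list(values = values, geometry = geometry,
                 measured_mask = measured_mask),
            class = "sinogram")
}

#' @export
print.sinogram <- function(x, ...) {
  cat(sprintf("<sinogram> %d views x %d channels (%s beam), %d truncated cells\n",
              nrow(x$values), ncol(x$values), x$geometry$beam,
              sum(x$measured_mask == 0L)))
  invisible(x)
}

#' Save / load a sinogram
#'
#' Sinograms are serialized as RDS (values, measured mask and geometry in
#' one object); a human-readable JSON sidecar with the geometry can be
#' written alongside.
#'
#' @param sino a [sinogram].
#' @param path output path (conventionally `.rds`).
#' @param json_sidecar if `TRUE`, also write `<path>.json` with the geometry.
#' @export
write_sinogram <- function(sino, path, json_sidecar = FALSE) {
  stopifnot(inherits(sino, "sinogram"))
  saveRDS(sino, path)
  if (json_sidecar) {
    jsonlite::write_json(unclass(sino$geometry), paste0(path, ".json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_sinogram
#' @export
read_sinogram <- function(path) {
  sino <- readRDS(path)
  stopifnot(inherits(sino, "sinogram"))
  sino
}

#' Forward projection (Radon transform)
#'
#' Computes line integrals of a linear-attenuation image along the rays of
#' the given geometry by ray-driven sampling with bilinear interpolation
#' (step = half a pixel). The projector is linear in the image.
#'
#' @param img an [image_grid] in mm^-1 (`unit = "mu"`).
#' @param geom a [scan_geometry].
#' @param step_frac integration step as a fraction of the pixel spacing.
#' @return A [sinogram] with an all-measured mask.
#' @export
forward_project <- function(img, geom, step_frac = 0.5) {
  stopifnot(inherits(img, "image_grid"), inherits(geom, "scan_geometry"))
  if (img$unit != "mu") {
    stop("forward_project expects a linear-attenuation image; see hu_to_mu()")
  }
  m <- img$values
  n <- nrow(m); h <- img$spacing
  half_diag <- sqrt(2) / 2 * n * h
  ds <- h * step_frac
  angles <- view_angles(geom)
  tk <- det_coords(geom)
  vals <- matrix(0, geom$n_views, geom$n_det)
  if (geom$beam == "parallel") {
    s <- seq(-half_diag - h, half_diag + h, by = ds)
    tt <- rep(tk, times = length(s))
    ss <- rep(s, each = length(tk))
    for (v in seq_along(angles)) {
      th <- angles[v]
      x <- tt * cos(th) - ss * sin(th)
      y <- tt * sin(th) + ss * cos(th)
      fi <- y / h + (n + 1) / 2
      fj <- x / h + (n + 1) / 2
      p <- bilinear_sample(m, fi, fj, fill = 0)
      vals[v, ] <- rowSums(matrix(p, nrow = length(tk))) * ds
    }
  } else {
    sad <- geom$sad
    smax <- sad + half_diag + h
    s <- seq(max(sad - half_diag - h, 0), smax, by = ds)
    gg <- rep(tk, times = length(s))
    ss <- rep(s, each = length(tk))
    for (v in seq_along(angles)) {
      beta <- angles[v]
      # source position
      sx <- -sad * sin(beta); sy <- sad * cos(beta)
      # unit ray direction for fan angle gamma: rotate the central ray
      dirx <- sin(beta + gg); diry <- -cos(beta + gg)
      x <- sx + ss * dirx
      y <- sy + ss * diry
      fi <- y / h + (n + 1) / 2
      fj <- x / h + (n + 1) / 2
      p <- bilinear_sample(m, fi, fj, fill = 0)
      vals[v, ] <- rowSums(matrix(p, nrow = length(tk))) * ds
    }
  }
  sinogram(vals, geom)
}

#' Analytic projection of a uniform disc
#'
#' Closed-form line integrals of a uniform disc: `p(t) = 2 mu sqrt(R^2 - d^2)`
#' where `d` is the ray-to-centre distance, 0 for rays missing the disc.
#' Serves as the exact oracle for the projector and for the water-cylinder
#' extrapolation math.
#'
#' @param center disc centre `c(x, y)` in mm.
#' @param radius disc radius in mm.
#' @param mu disc attenuation in mm^-1.
#' @param geom a [scan_geometry].
#' @return A [sinogram].
#' @export
analytic_disc_projection <- function(center, radius, mu, geom) {
  stopifnot(inherits(geom, "scan_geometry"), radius >= 0)
  angles <- view_angles(geom)
  tk <- det_coords(geom)
  vals <- matrix(0, geom$n_views, geom$n_det)
  for (v in seq_along(angles)) {
    th <- angles[v]
    if (geom$beam == "parallel") {
      # signed distance of each ray to the centre
      d <- tk - (center[1] * cos(th) + center[2] * sin(th))
    } else {
      sx <- -geom$sad * sin(th); sy <- geom$sad * cos(th)
      # distance from centre to the ray through the source with direction
      # (sin(th+g), -cos(th+g))
      dirx <- sin(th + tk); diry <- -cos(th + tk)
      rx <- center[1] - sx; ry <- center[2] - sy
      d <- rx * diry - ry * dirx
    }
    chord <- 2 * mu * sqrt(pmax(radius^2 - d^2, 0))
    vals[v, ] <- chord
  }
  sinogram(vals, geom)
}

# discrete ramp-filter kernel (spatial domain), spacing dt
ramp_kernel <- function(n_pad, dt) {
  k <- numeric(n_pad)
  idx <- c(0:(n_pad %/% 2), -((n_pad - n_pad %/% 2 - 1):1))
  k[idx == 0] <- 1 / (4 * dt^2)
  odd <- idx %% 2 != 0
  k[odd] <- -1 / (pi * idx[odd] * dt)^2
  k
}

# ramp-filter all views of a projection matrix (rows = views)
filter_projections <- function(p, dt, apodization = c("cosine", "ramp")) {
  apodization <- match.arg(apodization)
  n_det <- ncol(p)
  n_pad <- 2^ceiling(log2(2 * n_det))
  H <- Re(stats::fft(ramp_kernel(n_pad, dt)))
  if (apodization == "cosine") {
    f <- c(0:(n_pad / 2), (n_pad / 2 - 1):1) / (n_pad / 2)
    H <- H * cos(pi * f / 2)
  }
  ppad <- cbind(p, matrix(0, nrow(p), n_pad - n_det))
  q <- t(apply(ppad, 1, function(row) {
    Re(stats::fft(stats::fft(row) * H, inverse = TRUE)) / n_pad
  }))
  q[, seq_len(n_det), drop = FALSE] * dt
}

#' Filtered back-projection reconstruction
#'
#' Ramp-filtered back-projection (with optional cosine apodization of the
#' ramp) for parallel-beam sinograms, and the equiangular weighted variant
#' for fan-beam sinograms. Truncated channels are used as stored (zero
#' unless previously filled by an extrapolation step).
#'
#' @param sino a [sinogram].
#' @param out_size output image side in pixels.
#' @param spacing output pixel spacing in mm.
#' @param apodization `"cosine"` (default) or `"ramp"` (no apodization).
#' @return An [image_grid] in mm^-1.
#' @export
fbp_reconstruct <- function(sino, out_size = 256, spacing = 1.5,
                            apodization = c("cosine", "ramp")) {
  stopifnot(inherits(sino, "sinogram"))
  geom <- sino$geometry
  if (geom$n_views < 2) stop("need at least 2 views")
  apodization <- match.arg(apodization)
  angles <- view_angles(geom)
  dth <- geom$ang_range / geom$n_views * pi / 180
  n <- out_size
  xy <- grid_coords(n, spacing)
  X <- matrix(xy, n, n, byrow = TRUE)   # world x per (row, col)
  Y <- matrix(xy, n, n, byrow = FALSE)  # world y per (row, col)
  img <- matrix(0, n, n)
  dt <- geom$det_spacing
  c0 <- (geom$n_det + 1) / 2
  if (geom$beam == "parallel") {
    q <- filter_projections(sino$values, dt, apodization)
    scale <- if (geom$ang_range > 180 + 1e-9) 0.5 else 1
    for (v in seq_along(angles)) {
      th <- angles[v]
      tt <- X * cos(th) + Y * sin(th)
      img <- img + interp_row(q[v, ], tt / dt + c0)
    }
    img <- img * dth * scale
  } else {
    if (geom$ang_range < 360 - 1e-9) {
      stop("fan-beam reconstruction requires a full 360-degree scan")
    }
    gam <- det_coords(geom)
    sad <- geom$sad
    # equiangular weighting: pre-weight by D*cos(gamma); the extra 1/2 of
    # the fan ramp kernel is folded into the final scale. The small-angle
    # (gamma/sin gamma)^2 kernel correction is < 0.5% for the fan angles
    # used here and is omitted.
    p1 <- sweep(sino$values, 2, sad * cos(gam), `*`)
    q <- filter_projections(p1, dt, apodization)
    for (v in seq_along(angles)) {
      beta <- angles[v]
      sx <- -sad * sin(beta); sy <- sad * cos(beta)
      dx <- X - sx; dy <- Y - sy
      L2 <- dx^2 + dy^2
      # signed fan angle of each pixel as seen from the source: angle from
      # the central ray direction (sin beta, -cos beta) to (dx, dy)
      cr <- sin(beta) * dy + cos(beta) * dx
      dt_ <- sin(beta) * dx - cos(beta) * dy
      gpix <- atan2(cr, dt_)
      img <- img + interp_row(q[v, ], gpix / dt + c0) / L2
    }
    img <- img * dth * 0.5
  }
  image_grid(img, spacing = spacing, modality = "MV", unit = "mu")
}

# linear interpolation of a single profile at fractional channel indices
# (matrix-shaped); outside the profile -> 0
interp_row <- function(row, fk) {
  n <- length(row)
  k0 <- floor(fk)
  d <- fk - k0
  inside <- k0 >= 1 & k0 <= n - 1
  out <- fk * 0
  idx <- k0[inside]
  out[inside] <- row[idx] * (1 - d[inside]) + row[idx + 1] * d[inside]
  out
}
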
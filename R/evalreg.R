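#' Masked error metrics
#'
#' Mean absolute error and root-mean-square error between two images,
#' restricted to an optional 0/1 mask. Inputs may be [image_grid]s or plain
#' matrices.
#'
#' @param x,y images of identical shape (HU).
#' @param mask optional 0/1 matrix; `NULL` uses all pixels.
#' @return A scalar, in the units of the inputs.
#' @export
mae <- function(x, y, mask = NULL) {
  d <- metric_diff(x, y, mask)
  mean(abs(d))
}

#' @rdname mae
#' @export
rmse <- function(x, y, mask = NULL) {
  d <- metric_diff(x, y, mask)
  sqrt(mean(d^2))
}

metric_diff <- function(x, y, mask) {
  xv <- if (inherits(x, "image_grid")) x$values else as.matrix(x)
  yv <- if (inherits(y, "image_grid")) y$values else as.matrix(y)
  stopifnot(identical(dim(xv), dim(yv)))
  if (is.null(mask)) return(xv - yv)
  mv <- if (inherits(mask, "image_grid")) mask$values else as.matrix(mask)
  stopifnot(identical(dim(mv), dim(xv)))
  if (!any(mv > 0)) stop("empty mask")
  (xv - yv)[mv > 0]
}

# separable Gaussian filter with symmetric boundary padding
gauss_filter <- function(m, sigma = 1.5, width = 11) {
  half <- (width - 1) / 2
  k <- exp(-((-half):half)^2 / (2 * sigma^2))
  k <- k / sum(k)
  pad_idx <- function(n) {
    idx <- c(rev(seq_len(half)), seq_len(n), n + 1 - seq_len(half))
    pmin(pmax(idx, 1), n)
  }
  mp <- m[pad_idx(nrow(m)), , drop = FALSE]
  rowf <- matrix(0, nrow(m), ncol(m))
  for (o in seq_len(width)) rowf <- rowf + k[o] * mp[o:(o + nrow(m) - 1), , drop = FALSE]
  mp <- rowf[, pad_idx(ncol(m)), drop = FALSE]
  colf <- matrix(0, nrow(m), ncol(m))
  for (o in seq_len(width)) colf <- colf + k[o] * mp[, o:(o + ncol(m) - 1), drop = FALSE]
  colf
}

#' Structural similarity index
#'
#' Mean local SSIM with an 11x11 Gaussian window (sigma 1.5). Local means,
#' variances and covariance are Gaussian-weighted; the stabilising
#' constants are `c1 = (0.01 L)^2`, `c2 = (0.03 L)^2` where `L` is the
#' dynamic range. The mean is taken over `mask` when given.
#'
#' @param x,y images of identical shape.
#' @param mask optional 0/1 matrix restricting the average.
#' @param dynamic_range intensity range `L` (default spans the HU window
#'   from air to dense bone, 2524 HU).
#' @param sigma,width Gaussian window parameters.
#' @return Scalar in `[-1, 1]` (reported as a fraction, not percent).
#' @export
ssim <- function(x, y, mask = NULL, dynamic_range = 2524,
                 sigma = 1.5, width = 11) {
  xv <- if (inherits(x, "image_grid")) x$values else as.matrix(x)
  yv <- if (inherits(y, "image_grid")) y$values else as.matrix(y)
  stopifnot(identical(dim(xv), dim(yv)))
  c1 <- (0.01 * dynamic_range)^2
  c2 <- (0.03 * dynamic_range)^2
  mu_x <- gauss_filter(xv, sigma, width)
  mu_y <- gauss_filter(yv, sigma, width)
  sxx <- gauss_filter(xv * xv, sigma, width) - mu_x^2
  syy <- gauss_filter(yv * yv, sigma, width) - mu_y^2
  sxy <- gauss_filter(xv * yv, sigma, width) - mu_x * mu_y
  smap <- ((2 * mu_x * mu_y + c1) * (2 * sxy + c2)) /
    ((mu_x^2 + mu_y^2 + c1) * (sxx + syy + c2))
  if (is.null(mask)) return(mean(smap))
  mv <- if (inherits(mask, "image_grid")) mask$values else as.matrix(mask)
  if (!any(mv > 0)) stop("empty mask")
  mean(smap[mv > 0])
}

#' HU linear regression between two images
#'
#' Ordinary least squares of `pred` pixel values on `ref` pixel values
#' inside a region of interest; used to quantify the intensity agreement
#' between translated and reference modalities.
#'
#' @param pred,ref images of identical shape.
#' @param mask 0/1 ROI matrix (>= 2 pixels).
#' @return `list(slope, intercept)`.
#' @export
hu_regression <- function(pred, ref, mask = NULL) {
  pv <- if (inherits(pred, "image_grid")) pred$values else as.matrix(pred)
  rv <- if (inherits(ref, "image_grid")) ref$values else as.matrix(ref)
  stopifnot(identical(dim(pv), dim(rv)))
  if (!is.null(mask)) {
    mv <- if (inherits(mask, "image_grid")) mask$values else as.matrix(mask)
    pv <- pv[mv > 0]; rv <- rv[mv > 0]
  }
  if (length(rv) < 2) stop("need at least 2 ROI pixels")
  if (stats::var(as.vector(rv)) == 0) stop("constant reference: slope undefined")
  slope <- stats::cov(as.vector(rv), as.vector(pv)) / stats::var(as.vector(rv))
  list(slope = slope, intercept = mean(pv) - slope * mean(rv))
}

#' Signed difference map
#'
#' `gt - pred` as an image, with a symmetric display window attached as an
#' attribute for plotting.
#'
#' @param pred,gt images of identical shape (HU).
#' @return An [image_grid] of signed HU differences.
#' @export
difference_map <- function(pred, gt) {
  pv <- if (inherits(pred, "image_grid")) pred$values else as.matrix(pred)
  gv <- if (inherits(gt, "image_grid")) gt$values else as.matrix(gt)
  sp <- if (inherits(gt, "image_grid")) gt$spacing else 1
  stopifnot(identical(dim(pv), dim(gv)))
  d <- image_grid(gv - pv, sp, modality = "MV", unit = "HU")
  w <- max(abs(d$values)); if (w == 0) w <- 1
  attr(d, "display_window") <- c(-w, w)
  d
}

#' Rigid registration (rotation + translation)
#'
#' Registers `moving` to `fixed` by maximising normalized cross-correlation
#' over in-plane rotation and translation: a coarse multi-start grid
#' followed by Nelder-Mead refinement. Resampling is bilinear with
#' -1000 HU fill.
#'
#' @param moving,fixed [image_grid]s of the same shape and spacing.
#' @param max_trans,max_rot search bounds (mm, degrees).
#' @return `list(transform = list(rotation, translation), resampled,
#'   score)`; `resampled` is `moving` mapped onto `fixed`.
#' @export
rigid_register <- function(moving, fixed, max_trans = 20, max_rot = 15) {
  stopifnot(inherits(moving, "image_grid"), inherits(fixed, "image_grid"),
            identical(dim(moving$values), dim(fixed$values)))
  fv <- fixed$values
  ncc <- function(par) {
    w <- warp_rigid(moving$values, moving$spacing, par[1], par[2:3],
                    fill = -1000)
    s <- stats::sd(w)
    if (s == 0) return(2)
    -stats::cor(as.vector(w), as.vector(fv))
  }
  if (stats::sd(fv) == 0 || stats::sd(moving$values) == 0) {
    warning("degenerate registration: constant image")
    return(list(transform = list(rotation = 0, translation = c(0, 0)),
                resampled = moving, score = NA_real_))
  }
  starts <- expand.grid(rot = seq(-max_rot, max_rot, length.out = 5),
                        tx = seq(-max_trans, max_trans, length.out = 3),
                        ty = seq(-max_trans, max_trans, length.out = 3))
  vals <- apply(starts, 1, function(p) ncc(as.numeric(p)))
  best <- as.numeric(starts[which.min(vals), ])
  opt <- stats::optim(best, ncc, method = "Nelder-Mead",
                      control = list(maxit = 400, reltol = 1e-10))
  # polish from the optimum with a tighter restart
  opt2 <- stats::optim(opt$par, ncc, method = "Nelder-Mead",
                       control = list(maxit = 200, reltol = 1e-12))
  par <- if (opt2$value < opt$value) opt2$par else opt$par
  res <- moving
  res$values <- warp_rigid(moving$values, moving$spacing, par[1], par[2:3],
                           fill = -1000)
  res$body_mask <- NULL
  list(transform = list(rotation = par[1], translation = par[2:3]),
       resampled = res,
       score = -min(opt$value, opt2$value))
}

#' Evaluate a corrected image against ground truth
#'
#' Computes MAE, RMSE and SSIM inside the scan FOV disc, inside the
#' extended-FOV ring (body minus sFOV disc) and over the whole body, plus
#' the HU regression inside the body.
#'
#' @param pred,gt HU images of identical geometry.
#' @param body_mask 0/1 body matrix.
#' @param sfov_radius radius (mm) of the scan-FOV disc; pixels outside it
#'   but inside the body form the eFOV ring.
#' @param dynamic_range SSIM dynamic range.
#' @return A `metrics_report` list of per-region metric lists.
#' @export
evaluate_run <- function(pred, gt, body_mask, sfov_radius,
                         dynamic_range = 2524) {
  pv <- if (inherits(pred, "image_grid")) pred$values else as.matrix(pred)
  gv <- if (inherits(gt, "image_grid")) gt$values else as.matrix(gt)
  sp <- if (inherits(gt, "image_grid")) gt$spacing else 1
  bm <- if (inherits(body_mask, "image_grid")) body_mask$values else as.matrix(body_mask)
  n <- nrow(gv)
  xy <- grid_coords(n, sp)
  R2 <- outer(xy^2, xy^2, `+`)  # y^2 + x^2 (rows = y, cols = x)
  sfov <- (R2 <= sfov_radius^2) * 1
  ring <- bm * (1 - sfov)
  one <- function(mask, tag) {
    if (!any(mask > 0)) {
      return(list(mask_id = tag, n_pixels = 0, mae = NA_real_,
                  rmse = NA_real_, ssim = NA_real_))
    }
    list(mask_id = tag, n_pixels = sum(mask > 0),
         mae = mae(pv, gv, mask), rmse = rmse(pv, gv, mask),
         ssim = ssim(pv, gv, mask, dynamic_range))
  }
  reg <- hu_regression(pv, gv, bm)
  structure(list(sfov = one(bm * sfov, "sfov_body"),
                 efov = one(ring, "efov_ring"),
                 body = one(bm, "body"),
                 regression = reg,
                 sfov_radius = sfov_radius),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  for (tag in c("sfov", "efov", "body")) {
    m <- x[[tag]]
    cat(sprintf("%-10s n=%6d  MAE %8.2f  RMSE %8.2f  SSIM %6.4f\n",
                m$mask_id, m$n_pixels, m$mae, m$rmse, m$ssim))
  }
  cat(sprintf("regression slope %.4f intercept %.2f\n",
              x$regression$slope, x$regression$intercept))
  invisible(x)
}

#' Serialize a metrics report to JSON
#'
#' @param report a `metrics_report`.
#' @param path optional output path; when `NULL` the JSON string is returned.
#' @export
report_to_json <- function(report, path = NULL) {
  obj <- unclass(report)
  if (is.null(path)) {
    return(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA))
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname report_to_json
#' @export
report_from_json <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  structure(obj, class = "metrics_report")
}
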
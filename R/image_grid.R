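#' 2D image grid
#'
#' Container for a single 2D CT slice: a numeric matrix of pixel values
#' (Hounsfield units or linear attenuation in mm^-1), the isotropic pixel
#' spacing, a modality tag, and an optional binary body mask of the same
#' shape. Pixel centres sit at half-integer offsets from the image centre:
#' pixel `(i, j)` (row, column, 1-based) has world coordinates
#' `x = (j - (n+1)/2) * spacing`, `y = (i - (n+1)/2) * spacing`, with the
#' isocentre at the image centre.
#'
#' @param values numeric matrix of pixel values.
#' @param spacing pixel spacing in mm (> 0).
#' @param modality one of `"KV"`, `"MV"`, `"sMV"`, `"mask"`.
#' @param unit `"HU"` or `"mu"` (linear attenuation, mm^-1).
#' @param body_mask optional 0/1 matrix with the same dimensions.
#' @return An object of class `image_grid`.
#' @export
image_grid <- function(values, spacing = 1.5, modality = "KV",
                       unit = "HU", body_mask = NULL) {
  values <- as.matrix(values)
  stopifnot(is.numeric(values), all(is.finite(values)), spacing > 0)
  modality <- match.arg(modality, c("KV", "MV", "sMV", "mask"))
  unit <- match.arg(unit, c("HU", "mu"))
  if (!is.null(body_mask)) {
    body_mask <- as.matrix(body_mask)
    stopifnot(identical(dim(body_mask), dim(values)),
              all(body_mask %in% c(0, 1)))
  }
  structure(list(values = values, spacing = spacing, modality = modality,
                 unit = unit, body_mask = body_mask),
            class = "image_grid")
}

#' @export
dim.image_grid <- function(x) dim(x$values)

#' @export
print.image_grid <- function(x, ...) {
  cat(sprintf("<image_grid> %dx%d px @ %.3g mm, %s [%s], range [%.1f, %.1f]%s\n",
              nrow(x$values), ncol(x$values), x$spacing, x$modality, x$unit,
              min(x$values), max(x$values),
              if (is.null(x$body_mask)) "" else ", with body mask"))
  invisible(x)
}

#' Convert Hounsfield units to linear attenuation
#'
#' `mu = mu_water * (1 + HU/1000)`, clipped below at zero (air maps to 0).
#'
#' @param img an [image_grid] in HU.
#' @param mu_water linear attenuation of water in mm^-1 (> 0).
#' @return An [image_grid] in mm^-1 (`unit = "mu"`).
#' @export
hu_to_mu <- function(img, mu_water = 0.02) {
  stopifnot(inherits(img, "image_grid"), img$unit == "HU", mu_water > 0)
  v <- pmax(mu_water * (1 + img$values / 1000), 0)
  out <- img
  out$values <- v
  out$unit <- "mu"
  out
}

#' Convert linear attenuation to Hounsfield units
#'
#' Inverse of [hu_to_mu]: `HU = 1000 * (mu/mu_water - 1)`.
#'
#' @inheritParams hu_to_mu
#' @param img an [image_grid] in mm^-1.
#' @export
mu_to_hu <- function(img, mu_water = 0.02) {
  stopifnot(inherits(img, "image_grid"), img$unit == "mu", mu_water > 0)
  out <- img
  out$values <- 1000 * (img$values / mu_water - 1)
  out$unit <- "HU"
  out
}

# world x/y (mm) of pixel column/row centres
grid_coords <- function(n, spacing) (seq_len(n) - (n + 1) / 2) * spacing

#' Bilinear sampling of a matrix at fractional (row, col) indices
#'
#' Samples outside the matrix return `fill`. Used by the projector, the
#' affine augmenter and the rigid resampler so that all share one
#' interpolation convention.
#'
#' @param m numeric matrix.
#' @param fi,fj fractional row/column indices (1-based), equal-length vectors.
#' @param fill value returned outside the matrix extent.
#' @return Numeric vector of sampled values.
#' @keywords internal
bilinear_sample <- function(m, fi, fj, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  # pad with one ring of `fill` so out-of-extent samples blend into `fill`
  # without any logical subsetting (hot path of the projector)
  nrp <- nr + 2L
  mp <- matrix(fill, nrp, nc + 2L)
  mp[2:(nr + 1L), 2:(nc + 1L)] <- m
  fi <- pmin(pmax(fi + 1, 1), nr + 2 - 1e-7)
  fj <- pmin(pmax(fj + 1, 1), nc + 2 - 1e-7)
  i0 <- floor(fi); j0 <- floor(fj)
  di <- fi - i0; dj <- fj - j0
  idx <- i0 + (j0 - 1) * nrp
  mp[idx] * (1 - di) * (1 - dj) + mp[idx + 1] * di * (1 - dj) +
    mp[idx + nrp] * (1 - di) * dj + mp[idx + nrp + 1] * di * dj
}

#' Write / read images as NIfTI
#'
#' Images are written with their pixel spacing in the NIfTI header; `.nii`
#' and `.nii.gz` are supported. The modality tag and unit are not stored in
#' the NIfTI header and default to `"MV"`/`"HU"` on read.
#'
#' @param img an [image_grid].
#' @param path output file path ending in `.nii` or `.nii.gz`.
#' @return `write_image` returns `path` invisibly; `read_image` returns an
#'   [image_grid].
#' @export
write_image <- function(img, path) {
  stopifnot(inherits(img, "image_grid"))
  nif <- RNifti::asNifti(img$values)
  RNifti::pixdim(nif) <- c(img$spacing, img$spacing)
  RNifti::writeNifti(nif, path)
  invisible(path)
}

#' @rdname write_image
#' @param modality,unit tags to attach to the image read from `path`.
#' @export
read_image <- function(path, modality = "MV", unit = "HU") {
  nif <- RNifti::readNifti(path)
  sp <- RNifti::pixdim(nif)[1]
  image_grid(as.matrix(nif[, ]), spacing = sp, modality = modality, unit = unit)
}
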
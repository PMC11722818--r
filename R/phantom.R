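#' Phantom specification
#'
#' Describes a 2D ellipse phantom: a canvas, a set of ellipses painted in
#' order, and a tissue table giving each tissue label its kV and MV
#' Hounsfield values. The background is air (-1000 HU in both modalities).
#'
#' The default tissue table places body-tissue MV values on the configured
#' cross-modality regression line `MV = slope * KV + intercept`
#' (slope 0.70, intercept -288.56 by default), so the least-squares
#' regression of MV on KV over body pixels reproduces that line by
#' construction regardless of the tissue mixture, emulating the intensity
#' relation between kilovoltage and megavoltage CT.
#'
#' @param canvas_size image side in pixels.
#' @param pixel_spacing pixel spacing in mm.
#' @param ellipses list of ellipses, each
#'   `list(center = c(x, y) mm, axes = c(a, b) mm, rot = degrees, tissue = label)`.
#'   Painted in order (later ellipses overwrite earlier ones).
#' @param tissue_table named list `label -> c(HU_kv, HU_mv)`; must contain at
#'   least `air`, `fat`, `soft` and `bone` entries.
#' @param noise_sd per-pixel HU noise added independently to each modality
#'   inside the body (0 = noise-free).
#' @param seed integer seed controlling the noise.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(canvas_size = 256, pixel_spacing = 1.5,
                         ellipses = list(), tissue_table = default_tissues(),
                         noise_sd = 0, seed = 1L) {
  stopifnot(canvas_size >= 8, pixel_spacing > 0, noise_sd >= 0)
  required <- c("air", "fat", "soft", "bone")
  if (!all(required %in% names(tissue_table))) {
    stop("tissue_table must contain air/fat/soft/bone entries")
  }
  if (any(tissue_table$air != c(-1000, -1000))) {
    stop("air must be -1000 HU in both modalities")
  }
  half <- canvas_size * pixel_spacing / 2
  for (e in ellipses) {
    if (!e$tissue %in% names(tissue_table)) {
      stop("unknown tissue label: ", e$tissue)
    }
    reach <- sqrt(sum(e$axes^2))  # bound on the rotated ellipse extent
    if (any(abs(e$center) + pmin(reach, max(e$axes)) > half)) {
      stop("ellipse outside canvas")
    }
  }
  structure(list(canvas_size = canvas_size, pixel_spacing = pixel_spacing,
                 ellipses = ellipses, tissue_table = tissue_table,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Default tissue table
#'
#' kV Hounsfield values are typical diagnostic-energy values; MV values of
#' body tissues sit on the regression line `MV = slope * KV + intercept`.
#'
#' @param slope,intercept the kV-to-MV regression line.
#' @return Named list `label -> c(HU_kv, HU_mv)`.
#' @export
default_tissues <- function(slope = 0.70, intercept = -288.56) {
  on_line <- function(kv) c(kv, slope * kv + intercept)
  list(air = c(-1000, -1000),
       lung = on_line(-850),
       fat = on_line(-100),
       soft = on_line(40),
       muscle = on_line(55),
       lesion = on_line(90),
       bone = on_line(1000),
       water = c(0, 0))
}

# 0/1 matrix of an ellipse on the canvas grid
rasterize_ellipse <- function(n, spacing, center, axes, rot_deg) {
  xy <- grid_coords(n, spacing)
  X <- matrix(xy, n, n, byrow = TRUE); Y <- matrix(xy, n, n)
  th <- rot_deg * pi / 180
  u <- (X - center[1]) * cos(th) + (Y - center[2]) * sin(th)
  v <- -(X - center[1]) * sin(th) + (Y - center[2]) * cos(th)
  (u / axes[1])^2 + (v / axes[2])^2 <= 1
}

#' Generate a paired kV/MV phantom
#'
#' Rasterizes the ellipses of a [phantom_spec] into a kV image and an MV
#' image with identical geometry (pixelwise identical label maps), adds
#' seeded per-modality noise inside the body, and returns the body mask
#' (union of all ellipses). Fully deterministic given `(spec, seed)`.
#'
#' @param spec a [phantom_spec].
#' @return `list(kv, mv, mask)` of [image_grid]s.
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  n <- spec$canvas_size; sp <- spec$pixel_spacing
  kv <- matrix(-1000, n, n); mv <- matrix(-1000, n, n)
  body <- matrix(FALSE, n, n)
  for (e in spec$ellipses) {
    m <- rasterize_ellipse(n, sp, e$center, e$axes, e$rot)
    hu <- spec$tissue_table[[e$tissue]]
    kv[m] <- hu[1]; mv[m] <- hu[2]
    body <- body | m
  }
  if (spec$noise_sd > 0 && any(body)) {
    set.seed(spec$seed)
    nb <- sum(body)
    kv[body] <- kv[body] + stats::rnorm(nb, 0, spec$noise_sd)
    mv[body] <- mv[body] + stats::rnorm(nb, 0, spec$noise_sd)
  }
  list(kv = image_grid(kv, sp, modality = "KV", body_mask = body * 1),
       mv = image_grid(mv, sp, modality = "MV", body_mask = body * 1),
       mask = image_grid(body * 1, sp, modality = "mask"))
}

#' Random phantom family
#'
#' Draws a thorax- or pelvis-like [phantom_spec]: a large body ellipse with
#' a soft-tissue interior and fat rim, optional lungs, several bones and
#' soft-tissue lesions, all with jittered positions, sizes and HU values.
#' Bodies are sized so that moderate detector truncation cuts into them.
#'
#' @param seed integer seed.
#' @param canvas_size,pixel_spacing canvas (default 96 px at 4 mm, i.e. a
#'   384 mm field; use 256 at 1.5 mm for a finer grid of the same extent).
#' @param slope,intercept kV-to-MV map for the tissue table.
#' @param noise_sd per-modality HU noise.
#' @return A [phantom_spec].
#' @export
random_phantom_spec <- function(seed, canvas_size = 96, pixel_spacing = 4,
                                slope = 0.70, intercept = -288.56,
                                noise_sd = 12) {
  set.seed(as.integer(seed))
  on_line <- function(kv) c(kv, slope * kv + intercept)
  tt <- default_tissues(slope, intercept)
  tt$lung <- on_line(stats::runif(1, -920, -760))
  tt$bone <- on_line(stats::runif(1, 850, 1150))
  tt$lesion <- on_line(stats::runif(1, -60, 140))
  thorax <- stats::runif(1) < 0.5
  a <- stats::runif(1, 150, 180); b <- stats::runif(1, 100, 132)
  ctr <- c(stats::runif(1, -6, 6), stats::runif(1, -6, 6))
  rot <- stats::runif(1, -8, 8)
  ell <- list(
    list(center = ctr, axes = c(a, b), rot = rot, tissue = "fat"),
    list(center = ctr, axes = c(a, b) * 0.88, rot = rot, tissue = "soft")
  )
  th0 <- rot * pi / 180
  on_rim <- function(rho, phi) {
    # point at elliptical radius rho, polar angle phi, in body coordinates
    u <- rho * a * cos(phi); v <- rho * b * sin(phi)
    ctr + c(u * cos(th0) - v * sin(th0), u * sin(th0) + v * cos(th0))
  }
  if (thorax) {
    for (s in c(-1, 1)) {
      ell[[length(ell) + 1]] <- list(
        center = ctr + c(s * stats::runif(1, 0.38, 0.45) * a,
                         stats::runif(1, -8, 8)),
        axes = c(stats::runif(1, 0.30, 0.38) * a, stats::runif(1, 0.42, 0.55) * b),
        rot = rot + s * stats::runif(1, 5, 15), tissue = "lung")
    }
    # spine
    ell[[length(ell) + 1]] <- list(
      center = ctr + c(0, -0.62 * b), axes = c(16, 14),
      rot = 0, tissue = "bone")
    # rib-like bones along the body rim: peripheral skeletal anatomy that a
    # truncated scan loses and the kV prior still shows; lateral periphery
    # (the part a symmetric cut removes first) carries the densest share,
    # as in the chest wall
    for (k in seq_len(sample(8:12, 1))) {
      phi <- if (k %% 2 == 0) {
        sample(c(0, pi), 1) + stats::runif(1, -0.8, 0.8)
      } else {
        stats::runif(1, 0, 2 * pi)
      }
      ell[[length(ell) + 1]] <- list(
        center = on_rim(stats::runif(1, 0.82, 0.93), phi),
        axes = c(stats::runif(1, 10, 16), stats::runif(1, 5, 8)),
        rot = phi * 180 / pi + 90 + stats::runif(1, -15, 15),
        tissue = "bone")
    }
    # scapula-like lateral bones
    for (s in c(-1, 1)) {
      ell[[length(ell) + 1]] <- list(
        center = on_rim(stats::runif(1, 0.80, 0.88),
                        (s < 0) * pi + stats::runif(1, -0.5, 0.5)),
        axes = c(stats::runif(1, 12, 20), stats::runif(1, 7, 11)),
        rot = 90 * (s < 0) + stats::runif(1, -25, 25), tissue = "bone")
    }
  } else {
    # pelvis: two iliac wings reaching the lateral body periphery + sacrum
    for (s in c(-1, 1)) {
      ell[[length(ell) + 1]] <- list(
        center = ctr + c(s * stats::runif(1, 0.62, 0.72) * a,
                         stats::runif(1, -10, 5)),
        axes = c(stats::runif(1, 26, 34), stats::runif(1, 42, 55)),
        rot = s * stats::runif(1, 20, 35), tissue = "bone")
    }
    ell[[length(ell) + 1]] <- list(
      center = ctr + c(0, -0.45 * b), axes = c(20, 16), rot = 0,
      tissue = "bone")
  }
  # soft-tissue lesions anywhere in the body, periphery included
  n_lesions <- sample(3:5, 1)
  for (i in seq_len(n_lesions)) {
    ell[[length(ell) + 1]] <- list(
      center = on_rim(stats::runif(1, 0.15, 0.85), stats::runif(1, 0, 2 * pi)),
      axes = stats::runif(2, 8, 20), rot = stats::runif(1, 0, 180),
      tissue = "lesion")
  }
  phantom_spec(canvas_size, pixel_spacing, ell, tt,
               noise_sd = noise_sd, seed = as.integer(seed))
}

#' Body mask by thresholding
#'
#' Thresholds an HU image, keeps the largest connected component and fills
#' its holes (so low-density interior structures such as lungs stay inside
#' the mask while satellite objects like a treatment table are removed).
#'
#' @param img an [image_grid] in HU.
#' @param hu_threshold threshold in HU (pixels `>= hu_threshold` are body
#'   candidates).
#' @return An [image_grid] with modality `"mask"` and 0/1 values.
#' @export
body_mask_from_threshold <- function(img, hu_threshold = -300) {
  stopifnot(inherits(img, "image_grid"), img$unit == "HU")
  cand <- img$values >= hu_threshold
  if (!any(cand)) stop("no body found")
  lab <- EBImage::bwlabel(cand * 1)
  sizes <- tabulate(lab[lab > 0])
  keep <- which.max(sizes)
  mask <- EBImage::fillHull((lab == keep) * 1)
  image_grid(as.matrix(mask) * 1, img$spacing, modality = "mask")
}

#' Affine augmentation
#'
#' Applies one rigid-plus-scale transform (rotation about the image centre,
#' translation in mm, isotropic scale) jointly to an image or a list of
#' paired images/masks, resampling with bilinear interpolation. HU images
#' are filled with -1000 outside the source extent; masks are warped and
#' re-binarized at 0.5. When `params` gives ranges instead of values, one
#' transform is drawn with `seed` and applied to all inputs.
#'
#' @param img an [image_grid] or a list of them.
#' @param params either explicit
#'   `list(rotation = deg, translation = c(mm, mm), scale = s)` or ranges
#'   `list(rot_range = c(lo, hi), trans_range = c(lo, hi), scale_range = c(lo, hi))`.
#' @param seed seed used when sampling from ranges.
#' @return Same shape as `img` (single grid or list).
#' @export
affine_augment <- function(img, params = list(rotation = 0,
                                              translation = c(0, 0),
                                              scale = 1), seed = NULL) {
  single <- inherits(img, "image_grid")
  imgs <- if (single) list(img) else img
  stopifnot(all(vapply(imgs, inherits, TRUE, "image_grid")))
  if (!is.null(params$rot_range)) {
    if (!is.null(seed)) set.seed(as.integer(seed))
    params <- list(
      rotation = stats::runif(1, params$rot_range[1], params$rot_range[2]),
      translation = c(stats::runif(1, params$trans_range[1], params$trans_range[2]),
                      stats::runif(1, params$trans_range[1], params$trans_range[2])),
      scale = stats::runif(1, params$scale_range[1], params$scale_range[2]))
  }
  if (is.null(params$scale)) params$scale <- 1
  if (is.null(params$translation)) params$translation <- c(0, 0)
  if (is.null(params$rotation)) params$rotation <- 0
  if (params$scale <= 0) stop("scale must be positive")
  identity_tf <- params$rotation == 0 && all(params$translation == 0) &&
    params$scale == 1
  out <- lapply(imgs, function(im) {
    if (identity_tf) return(im)
    is_mask <- im$modality == "mask"
    fill <- if (is_mask) 0 else -1000
    w <- warp_rigid(im$values, im$spacing, params$rotation,
                    params$translation, params$scale, fill)
    if (is_mask) w <- (w >= 0.5) * 1
    res <- im
    res$values <- w
    res$body_mask <- NULL
    res
  })
  if (single) out[[1]] else out
}

# resample `values` under (rotation deg about centre, translation mm,
# isotropic scale); forward map p' = scale * R(theta) p + t, implemented by
# sampling the inverse map
warp_rigid <- function(values, spacing, rotation, translation, scale = 1,
                       fill = -1000) {
  n <- nrow(values); m <- ncol(values)
  th <- rotation * pi / 180
  xs <- grid_coords(m, spacing); ys <- grid_coords(n, spacing)
  X <- matrix(xs, n, m, byrow = TRUE); Y <- matrix(ys, n, m)
  xi <- (X - translation[1]); yi <- (Y - translation[2])
  xs0 <- (xi * cos(th) + yi * sin(th)) / scale
  ys0 <- (-xi * sin(th) + yi * cos(th)) / scale
  fi <- ys0 / spacing + (n + 1) / 2
  fj <- xs0 / spacing + (m + 1) / 2
  matrix(bilinear_sample(values, fi, fj, fill = fill), n, m)
}

#' Generate a phantom dataset on disk
#'
#' Draws `n_slices` phantoms from a spec family, writes paired kV/MV/mask
#' images as uncompressed NIfTI and a JSON manifest with paths, train/test
#' split tags and the per-slice generator seed. Deterministic given `seed`.
#'
#' @param n_slices number of phantoms (>= 1).
#' @param out_dir output directory (created if needed).
#' @param seed master seed; per-slice seeds are derived from it.
#' @param spec_family function `(seed) -> phantom_spec`, defaults to
#'   [random_phantom_spec].
#' @param train_frac fraction of slices tagged `train`.
#' @return The manifest (invisibly), also written to
#'   `file.path(out_dir, "manifest.json")`.
#' @export
make_dataset <- function(n_slices, out_dir, seed = 1L,
                         spec_family = random_phantom_spec,
                         train_frac = 0.8) {
  stopifnot(n_slices >= 1)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(out_dir, 2) != 0) stop("output directory not writable")
  n_train <- round(n_slices * train_frac)
  entries <- vector("list", n_slices)
  for (i in seq_len(n_slices)) {
    slice_seed <- (as.integer(seed) * 1009L + i * 7919L) %% 2147483647L
    spec <- spec_family(slice_seed)
    ph <- make_phantom(spec)
    base <- file.path(out_dir, sprintf("slice_%04d", i))
    write_image(ph$kv, paste0(base, "_kv.nii"))
    write_image(ph$mv, paste0(base, "_mv.nii"))
    write_image(ph$mask, paste0(base, "_mask.nii"))
    entries[[i]] <- list(
      id = i, seed = slice_seed,
      split = if (i <= n_train) "train" else "test",
      kv = paste0(base, "_kv.nii"), mv = paste0(base, "_mv.nii"),
      mask = paste0(base, "_mask.nii"),
      canvas_size = spec$canvas_size, pixel_spacing = spec$pixel_spacing)
  }
  manifest <- list(n_slices = n_slices, seed = as.integer(seed),
                   slices = entries)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
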
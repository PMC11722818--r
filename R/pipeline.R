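#' Pipeline run configuration
#'
#' One configuration object drives the whole synthetic study: phantom
#' family, scan geometry, truncation level, extrapolation method, network
#' training schedules and seeds. Every stage derives its own seed from the
#' master seed, so a run is fully reproducible from `(config, seed)`.
#'
#' @param seed master seed.
#' @param n_phantoms number of paired phantoms to generate.
#' @param train_frac fraction used for training (rest held out).
#' @param canvas_size,pixel_spacing phantom canvas.
#' @param geometry a [scan_geometry] for projection/reconstruction.
#' @param n_cut channels truncated per side.
#' @param mu_water water attenuation (mm^-1).
#' @param n_fit,feather water-cylinder extrapolation settings.
#' @param mask_threshold HU threshold for body masks of reconstructions.
#' @param transnet a [transnet_config].
#' @param fovnet a [swin_config].
#' @param n_triplets number of training triplets reconstructed for FOV-Net.
#' @param n_eval number of held-out phantoms used for evaluation.
#' @param ring_loss_weight training-loss weight of extended-FOV body pixels
#'   relative to in-FOV body pixels (background is excluded); upweighting
#'   the annulus concentrates the L1 gradient on the region being
#'   inpainted.
#' @param register_prior run rigid registration of the prior onto the
#'   pre-corrected image (the synthetic pipeline is aligned by
#'   construction; registration is kept in the loop for fidelity).
#' @param calibrate_prior affinely recalibrate the prior's intensities
#'   against the pre-corrected image over in-FOV body pixels, removing any
#'   residual global intensity error of the translator.
#' @param out_dir optional directory for artifacts (`NULL` = keep in memory).
#' @return A list of class `run_config`.
#' @export
run_config <- function(seed = 1L, n_phantoms = 200, train_frac = 0.8,
                       canvas_size = 96, pixel_spacing = 4,
                       geometry = scan_geometry("parallel", n_det = 144,
                                                det_spacing = 3.4,
                                                n_views = 120,
                                                ang_range = 180),
                       n_cut = 30, mu_water = 0.02, n_fit = 3, feather = 4,
                       mask_threshold = -500,
                       transnet = transnet_config("desk"),
                       fovnet = swin_config("desk"),
                       n_triplets = 80, n_eval = 16,
                       ring_loss_weight = 5,
                       register_prior = TRUE, calibrate_prior = TRUE,
                       out_dir = NULL) {
  stopifnot(inherits(geometry, "scan_geometry"),
            n_cut >= 0, n_cut < geometry$n_det / 2)
  structure(list(seed = as.integer(seed), n_phantoms = n_phantoms,
                 train_frac = train_frac, canvas_size = canvas_size,
                 pixel_spacing = pixel_spacing, geometry = geometry,
                 n_cut = n_cut, mu_water = mu_water, n_fit = n_fit,
                 feather = feather, mask_threshold = mask_threshold,
                 transnet = transnet, fovnet = fovnet,
                 n_triplets = n_triplets, n_eval = n_eval,
                 ring_loss_weight = ring_loss_weight,
                 register_prior = register_prior,
                 calibrate_prior = calibrate_prior, out_dir = out_dir,
                 schema_version = 1L),
            class = "run_config")
}

# deterministic per-stage seed derivation from the master seed
stage_seed <- function(seed, stage) {
  offs <- c(phantoms = 11L, transnet = 23L, triplets = 37L, fovnet = 41L,
            eval = 53L, sweep = 67L, ablation = 71L)
  (as.integer(seed) * 2557L + offs[[stage]] * 7919L) %% 2147483647L
}

#' Generate the phantom pool for a run
#'
#' @param cfg a [run_config].
#' @return `list(train, test)` of phantom lists (each `list(kv, mv, mask)`).
#' @export
pipeline_phantoms <- function(cfg) {
  base <- stage_seed(cfg$seed, "phantoms")
  phs <- lapply(seq_len(cfg$n_phantoms), function(i) {
    make_phantom(random_phantom_spec((base + i * 101L) %% 2147483647L,
                                     canvas_size = cfg$canvas_size,
                                     pixel_spacing = cfg$pixel_spacing))
  })
  n_train <- round(cfg$n_phantoms * cfg$train_frac)
  list(train = phs[seq_len(n_train)],
       test = phs[seq(n_train + 1, length(phs))])
}

# project the MV phantom, truncate, and reconstruct with the requested
# methods; returns HU image_grids plus the truncated sinogram
recon_methods <- function(ph, cfg, methods = c("none", "wce")) {
  mu <- hu_to_mu(ph$mv, cfg$mu_water)
  sino <- forward_project(mu, cfg$geometry)
  trunc <- truncate_sinogram(sino, cfg$n_cut)
  out <- list(truncated_sino = trunc)
  for (m in methods) {
    out[[m]] <- precorrect(trunc, m, out_size = cfg$canvas_size,
                           spacing = cfg$pixel_spacing,
                           mu_water = cfg$mu_water, n_fit = cfg$n_fit,
                           feather = cfg$feather,
                           mask_threshold = cfg$mask_threshold)
  }
  out
}

# training-loss weight map: body pixels weighted 1 inside the scan FOV and
# `ring_loss_weight` in the extended-FOV annulus; background excluded
loss_weights <- function(ph, cfg) {
  sfov <- sfov_disc(cfg)
  bm <- ph$mask$values > 0
  w <- bm * 1
  w[bm & !sfov] <- cfg$ring_loss_weight
  w
}

# 0/1 matrix of pixels inside the scan FOV disc
sfov_disc <- function(cfg) {
  xy <- grid_coords(cfg$canvas_size, cfg$pixel_spacing)
  (outer(xy^2, xy^2, `+`) <= sfov_radius(cfg$geometry, cfg$n_cut)^2) * 1
}

# Synthetic-MV prior for one phantom: translate the kV slice, rigidly
# register it to the pre-corrected image, and affinely recalibrate its
# intensities against the measured data. Inside the scan FOV both images
# are on the MV scale, so regressing I_prec on the prior over in-FOV body
# pixels estimates (and removes) any residual global intensity error of
# the translator using only information available at inference.
make_prior <- function(ph, i_prec, tn_model, cfg) {
  smv <- synthesize_mvct(ph$kv, tn_model)
  if (isTRUE(cfg$register_prior)) {
    reg <- rigid_register(smv, i_prec, max_trans = 10, max_rot = 5)
    smv <- reg$resampled
  }
  if (isTRUE(cfg$calibrate_prior)) {
    roi <- sfov_disc(cfg) > 0 & smv$values > -600 & i_prec$values > -600
    if (sum(roi) > 100) {
      fit <- try(hu_regression(i_prec$values[roi], smv$values[roi]),
                 silent = TRUE)
      if (!inherits(fit, "try-error") && fit$slope > 0.5 && fit$slope < 2) {
        smv$values <- fit$slope * smv$values + fit$intercept
        smv$values[smv$values < -1000] <- -1000
      }
    }
  }
  smv
}

#' Run the end-to-end pipeline
#'
#' Executes the full study on synthetic phantoms: generate paired kV/MV
#' slices; train the kV-to-MV translation GAN on unpaired training slices;
#' project + truncate + water-cylinder-extrapolate + reconstruct to build
#' (pre-corrected, prior, ground-truth) triplets; train the window-attention
#' inpainting network; and evaluate the truncated baseline, the
#' water-cylinder reconstruction and the network output on held-out
#' phantoms.
#'
#' @param cfg a [run_config].
#' @param verbose print stage progress.
#' @return A list with the trained models, per-phantom `metrics_report`s
#'   per method, and a `summary` data frame of mean metrics.
#' @export
run_pipeline <- function(cfg = run_config(), verbose = TRUE) {
  say <- function(...) if (verbose) message(sprintf(...))
  t_start <- Sys.time()
  say("[phantoms] generating %d phantoms", cfg$n_phantoms)
  pool <- pipeline_phantoms(cfg)

  say("[transnet] training translation GAN (%d steps)", cfg$transnet$n_steps)
  tn <- train_transnet(lapply(pool$train, function(p) p$kv$values),
                       lapply(pool$train, function(p) p$mv$values),
                       cfg$transnet, seed = stage_seed(cfg$seed, "transnet"),
                       verbose = verbose)

  say("[triplets] reconstructing %d training triplets", cfg$n_triplets)
  idx <- seq_len(min(cfg$n_triplets, length(pool$train)))
  triplets <- lapply(pool$train[idx], function(ph) {
    rec <- recon_methods(ph, cfg, "wce")
    smv <- make_prior(ph, rec$wce, tn, cfg)
    list(i_prec = rec$wce$values, i_smv = smv$values, gt = ph$mv$values,
         mask = loss_weights(ph, cfg), sfov = sfov_disc(cfg))
  })

  say("[fovnet] training inpainting network (%d steps)", cfg$fovnet$n_steps)
  fn <- train_fovnet(triplets, cfg$fovnet,
                     seed = stage_seed(cfg$seed, "fovnet"), verbose = verbose)

  say("[eval] evaluating %d held-out phantoms", cfg$n_eval)
  ev <- evaluate_pipeline(cfg, tn, fn, pool = pool)
  say("[done] %.1f min", as.numeric(difftime(Sys.time(), t_start, units = "mins")))
  out <- list(config = cfg, transnet = tn, fovnet = fn,
              reports = ev$reports, summary = ev$summary,
              slopes = ev$slopes, pool = pool)
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    save_checkpoint(tn, file.path(cfg$out_dir, "transnet.rds"))
    save_checkpoint(fn, file.path(cfg$out_dir, "fovnet.rds"))
    utils::write.csv(ev$summary, file.path(cfg$out_dir, "summary.csv"),
                     row.names = FALSE)
  }
  out
}

#' Evaluate trained models on held-out phantoms
#'
#' @param cfg a [run_config].
#' @param tn_model trained `transnet_model`.
#' @param fn_model trained `fovnet_model` (or a named list of them, e.g.
#'   `list(with_prior = ..., no_prior = ...)`).
#' @param pool phantom pool from [pipeline_phantoms] (regenerated if `NULL`).
#' @param n_cut optional override of the truncation level.
#' @return `list(reports, summary, slopes)`.
#' @export
evaluate_pipeline <- function(cfg, tn_model, fn_model, pool = NULL,
                              n_cut = NULL) {
  if (is.null(pool)) pool <- pipeline_phantoms(cfg)
  if (!is.null(n_cut)) cfg$n_cut <- n_cut
  if (inherits(fn_model, "fovnet_model")) {
    fn_model <- list(fovnet = fn_model)
  }
  sfov_r <- sfov_radius(cfg$geometry, cfg$n_cut)
  test <- pool$test[seq_len(min(cfg$n_eval, length(pool$test)))]
  methods <- c("none", "symmetric", "wce", names(fn_model))
  reports <- stats::setNames(
    lapply(methods, function(m) vector("list", length(test))), methods)
  slopes <- data.frame()
  for (i in seq_along(test)) {
    ph <- test[[i]]
    rec <- recon_methods(ph, cfg, c("none", "symmetric", "wce"))
    smv <- make_prior(ph, rec$wce, tn_model, cfg)
    preds <- list(none = rec$none, symmetric = rec$symmetric, wce = rec$wce)
    sfov_m <- sfov_disc(cfg)
    for (nm in names(fn_model)) {
      prior <- if (identical(attr(fn_model[[nm]], "prior_mode"), "none"))
        rec$wce else smv
      preds[[nm]] <- fovnet_forward(rec$wce, prior, fn_model[[nm]], sfov_m)
    }
    bm <- ph$mask$values
    for (m in names(preds)) {
      reports[[m]][[i]] <- evaluate_run(preds[[m]], ph$mv, bm, sfov_r)
    }
    b1 <- bm * 1
    r_kv <- hu_regression(ph$mv$values, ph$kv$values, b1)
    r_smv <- hu_regression(ph$mv$values, smv$values, b1)
    slopes <- rbind(slopes, data.frame(
      phantom = i, slope_kv = r_kv$slope, slope_smv = r_smv$slope,
      intercept_kv = r_kv$intercept, intercept_smv = r_smv$intercept))
  }
  summary <- do.call(rbind, lapply(names(preds), function(m) {
    g <- function(field, region) {
      mean(vapply(reports[[m]], function(r) r[[region]][[field]], 0))
    }
    data.frame(method = m,
               mae_body = g("mae", "body"), rmse_body = g("rmse", "body"),
               ssim_body = g("ssim", "body"),
               mae_efov = g("mae", "efov"), rmse_efov = g("rmse", "efov"),
               ssim_efov = g("ssim", "efov"))
  }))
  list(reports = reports, summary = summary, slopes = slopes)
}

#' Robustness sweep over truncation levels
#'
#' Re-evaluates trained models while varying the number of truncated
#' detector channels, returning one summary row per (level, method) plus a
#' monotonicity note (errors are expected to grow with the truncation
#' level).
#'
#' @param cfg a [run_config].
#' @param tn_model,fn_model trained models.
#' @param levels truncation levels (channels per side).
#' @param pool optional phantom pool to reuse.
#' @return `list(table, monotone_mae)`.
#' @export
robustness_sweep <- function(cfg, tn_model, fn_model,
                             levels = c(0, 15, 30, 45, 60), pool = NULL) {
  if (is.null(pool)) pool <- pipeline_phantoms(cfg)
  rows <- list()
  for (lv in levels) {
    ev <- evaluate_pipeline(cfg, tn_model, fn_model, pool = pool, n_cut = lv)
    s <- ev$summary
    s$n_cut <- lv
    rows[[length(rows) + 1]] <- s
  }
  tab <- do.call(rbind, rows)
  fov_tab <- tab[tab$method == "fovnet", ]
  fov_tab <- fov_tab[order(fov_tab$n_cut), ]
  list(table = tab,
       monotone_mae = all(diff(fov_tab$mae_body) > -1e-6 * pmax(fov_tab$mae_body[-1], 1)) ||
         !is.unsorted(fov_tab$mae_body, strictly = FALSE))
}

#' Prior ablation
#'
#' Trains two inpainting networks under identical seeds and data - one fed
#' the synthetic-MV prior, one fed the pre-corrected image twice (no
#' prior) - and evaluates both, mirroring the with/without-prior comparison.
#'
#' @param cfg a [run_config].
#' @param tn_model trained translation model.
#' @param pool optional phantom pool to reuse.
#' @param triplets optional precomputed with-prior triplets.
#' @param fn_with optional pretrained with-prior network (trained here when
#'   `NULL`).
#' @param verbose print progress.
#' @return `list(summary, reports, fn_with, fn_without)`; `summary` has one
#'   row per variant in the shape of an ablation table.
#' @export
ablation_run <- function(cfg, tn_model, pool = NULL, triplets = NULL,
                         fn_with = NULL, verbose = TRUE) {
  if (is.null(pool)) pool <- pipeline_phantoms(cfg)
  if (is.null(triplets)) {
    idx <- seq_len(min(cfg$n_triplets, length(pool$train)))
    triplets <- lapply(pool$train[idx], function(ph) {
      rec <- recon_methods(ph, cfg, "wce")
      smv <- make_prior(ph, rec$wce, tn_model, cfg)
      list(i_prec = rec$wce$values, i_smv = smv$values, gt = ph$mv$values,
           mask = loss_weights(ph, cfg), sfov = sfov_disc(cfg))
    })
  }
  seed_fn <- stage_seed(cfg$seed, "ablation")
  if (is.null(fn_with)) {
    fn_with <- train_fovnet(triplets, cfg$fovnet, seed = seed_fn,
                            verbose = verbose)
  }
  trip_np <- lapply(triplets, function(tr) {
    list(i_prec = tr$i_prec, i_smv = tr$i_prec, gt = tr$gt, mask = tr$mask,
         sfov = tr$sfov)
  })
  fn_without <- train_fovnet(trip_np, cfg$fovnet, seed = seed_fn,
                             verbose = verbose)
  attr(fn_without, "prior_mode") <- "none"
  ev <- evaluate_pipeline(cfg, tn_model,
                          list(with_prior = fn_with, no_prior = fn_without),
                          pool = pool)
  s <- ev$summary[ev$summary$method %in% c("with_prior", "no_prior"), ]
  ordering_ok <- s$mae_body[s$method == "with_prior"] <
    s$mae_body[s$method == "no_prior"]
  if (!ordering_ok) {
    message("note: with-prior variant did not improve on the no-prior variant")
  }
  list(summary = s, reports = ev$reports, fn_with = fn_with,
       fn_without = fn_without, ordering_ok = ordering_ok)
}

#' Read / write a run configuration as YAML
#'
#' @param cfg a [run_config].
#' @param path YAML file path.
#' @export
write_run_config <- function(cfg, path) {
  obj <- unclass(cfg)
  obj$geometry <- unclass(obj$geometry)
  obj$transnet <- unclass(obj$transnet)
  obj$fovnet <- unclass(obj$fovnet)
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  obj <- yaml::read_yaml(path)
  geom <- do.call(scan_geometry, obj$geometry[c("beam", "n_det", "det_spacing",
                                                "n_views", "ang_range", "sad")])
  tn <- do.call(transnet_config,
                c(list(scale = obj$transnet$scale),
                  obj$transnet[setdiff(names(obj$transnet), "scale")]))
  fv <- do.call(swin_config,
                c(list(scale = obj$fovnet$scale),
                  obj$fovnet[setdiff(names(obj$fovnet), "scale")]))
  keep <- setdiff(names(obj), c("geometry", "transnet", "fovnet",
                                "schema_version"))
  do.call(run_config, c(obj[keep], list(geometry = geom, transnet = tn,
                                        fovnet = fv)))
}
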
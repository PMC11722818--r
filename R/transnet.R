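#' TransNet configuration
#'
#' Settings for the contrastive-learning GAN that translates kilovoltage CT
#' slices into synthetic megavoltage CT. The generator is a fully
#' convolutional encoder (stride-2 downsampling) / residual-bottleneck /
#' decoder (nearest-neighbour upsampling) network with instance
#' normalisation and a tanh output over a fixed HU window; the
#' discriminator is a patch-level least-squares GAN critic by default, with
#' the classical log-loss form available as `gan_flavor = "vanilla"`.
#'
#' The `"desk"` scale is sized to train on a CPU in minutes (96x96
#' phantoms, 64x64 training crops); `"clinical"` mirrors a full-size
#' configuration (512x512 slices, 400 epochs at batch 1, learning rate
#' 2e-4 constant for the first half and linearly decayed to zero over the
#' second half).
#'
#' @param scale `"desk"` or `"clinical"`.
#' @param ... overrides for any listed field.
#' @return A list of class `transnet_config`.
#' @export
transnet_config <- function(scale = c("desk", "clinical"), ...) {
  scale <- match.arg(scale)
  cfg <- if (scale == "desk") {
    list(base_channels = 12, n_downsample = 2, n_resnet_blocks = 3,
         crop_size = 64, n_steps = 800, batch_size = 1,
         lr = 1e-3, beta1 = 0.5, beta2 = 0.999,
         hu_window = c(-1024, 1500),
         nce = list(tau = 0.07, n_positions = 64, n_negatives = 63,
                    selected_layers = c(0, 1, 2, 3, 4), mlp_dim = 64),
         gan_flavor = "lsgan", lambda_gan = 1, lambda_nce = 1,
         lambda_idt = 1)
  } else {
    list(base_channels = 64, n_downsample = 2, n_resnet_blocks = 6,
         crop_size = 512, n_steps = 400 * 912, batch_size = 1,
         lr = 2e-4, beta1 = 0.5, beta2 = 0.999,
         hu_window = c(-1024, 1500),
         nce = list(tau = 0.07, n_positions = 256, n_negatives = 255,
                    selected_layers = c(0, 1, 2, 3, 4), mlp_dim = 256),
         gan_flavor = "lsgan", lambda_gan = 1, lambda_nce = 1,
         lambda_idt = 1)
  }
  ov <- list(...)
  cfg[names(ov)] <- ov
  cfg$scale <- scale
  structure(cfg, class = "transnet_config")
}

hu_norm <- function(v, win = c(-1024, 1500)) {
  2 * (pmin(pmax(v, win[1]), win[2]) - win[1]) / (win[2] - win[1]) - 1
}

hu_denorm <- function(v, win = c(-1024, 1500)) {
  (v + 1) / 2 * (win[2] - win[1]) + win[1]
}

# channel width of each encoder feature tap (tap 0 = the input image)
transnet_tap_channels <- function(cfg) {
  C <- cfg$base_channels
  c(1, C, 2 * C, 4 * C, 4 * C)
}

#' Initialise a TransNet model
#'
#' Creates generator, discriminator and the per-layer two-layer projection
#' heads used by the PatchNCE loss, with seeded random weights.
#'
#' @param cfg a [transnet_config].
#' @param seed integer seed.
#' @return A `transnet_model` list.
#' @export
transnet_init <- function(cfg = transnet_config(), seed = 1L) {
  set.seed(as.integer(seed))
  C <- cfg$base_channels
  G <- list(
    enc1 = c(init_conv(7, 1, C), init_norm(C)),
    enc2 = c(init_conv(3, C, 2 * C), init_norm(2 * C)),
    enc3 = c(init_conv(3, 2 * C, 4 * C), init_norm(4 * C)),
    res = lapply(seq_len(cfg$n_resnet_blocks), function(i) {
      list(c1 = c(init_conv(3, 4 * C, 4 * C), init_norm(4 * C)),
           c2 = c(init_conv(3, 4 * C, 4 * C), init_norm(4 * C)))
    }),
    dec1 = c(init_conv(3, 4 * C, 2 * C), init_norm(2 * C)),
    dec2 = c(init_conv(3, 2 * C, C), init_norm(C)),
    out = init_conv(3, C, 1, gain = 0.5)
  )
  Dn <- list(
    d1 = init_conv(4, 1, C),
    d2 = c(init_conv(4, C, 2 * C), init_norm(2 * C)),
    d3 = c(init_conv(4, 2 * C, 4 * C), init_norm(4 * C)),
    d4 = init_conv(4, 4 * C, 1)
  )
  taps <- transnet_tap_channels(cfg)
  H <- lapply(cfg$nce$selected_layers, function(l) {
    din <- taps[l + 1]
    list(l1 = init_linear(din, cfg$nce$mlp_dim),
         l2 = init_linear(cfg$nce$mlp_dim, cfg$nce$mlp_dim))
  })
  names(H) <- paste0("tap", cfg$nce$selected_layers)
  structure(list(cfg = cfg, G = G, D = Dn, H = H, trained = FALSE,
                 step = 0L, loss_log = NULL),
            class = "transnet_model")
}

conv_in_relu <- function(x, ly, k, stride = 1) {
  y <- conv2d(x, ly, k, stride)
  ad_relu(ad_instnorm(y, ly$gamma, ly$beta))
}

# encoder part; returns bottleneck node and the feature taps
g_encode <- function(x, G, cfg) {
  taps <- list(`0` = x)
  e1 <- conv_in_relu(x, G$enc1, 7); taps$`1` <- e1
  e2 <- conv_in_relu(e1, G$enc2, 3, stride = 2); taps$`2` <- e2
  e3 <- conv_in_relu(e2, G$enc3, 3, stride = 2); taps$`3` <- e3
  h <- e3
  mid <- max(1L, ceiling(cfg$n_resnet_blocks / 2))
  for (i in seq_len(cfg$n_resnet_blocks)) {
    r <- conv_in_relu(h, G$res[[i]]$c1, 3)
    r <- conv2d(r, G$res[[i]]$c2, 3)
    r <- ad_instnorm(r, G$res[[i]]$c2$gamma, G$res[[i]]$c2$beta)
    h <- ad_add(h, r)
    if (i == mid) taps$`4` <- h
  }
  list(h = h, taps = taps)
}

g_decode <- function(h, G) {
  d1 <- conv_in_relu(upsample_nn2(h), G$dec1, 3)
  d2 <- conv_in_relu(upsample_nn2(d1), G$dec2, 3)
  y <- conv2d(d2, G$out, 3)
  ad_tanh(y)
}

# full generator on a normalized (H, W, 1) node
g_forward_node <- function(x, G, cfg) {
  enc <- g_encode(x, G, cfg)
  list(y = g_decode(enc$h, G), taps = enc$taps)
}

d_forward_node <- function(x, D) {
  h <- ad_lrelu(conv2d(x, D$d1, 4, stride = 2), 0.2)
  h <- conv2d(h, D$d2, 4, stride = 2)
  h <- ad_lrelu(ad_instnorm(h, D$d2$gamma, D$d2$beta), 0.2)
  h <- conv2d(h, D$d3, 4, stride = 1)
  h <- ad_lrelu(ad_instnorm(h, D$d3$gamma, D$d3$beta), 0.2)
  conv2d(h, D$d4, 4, stride = 1)
}

#' Generator forward pass
#'
#' Runs the generator on a kV (or MV) image and returns the translated
#' image in HU. Deterministic: the network has no stochastic layers.
#'
#' @param img an [image_grid] in HU, sides divisible by
#'   `2^n_downsample` (4 for the provided configurations).
#' @param model a `transnet_model`.
#' @return An [image_grid] with modality `"sMV"`.
#' @export
generator_forward <- function(img, model) {
  stopifnot(inherits(model, "transnet_model"), inherits(img, "image_grid"))
  d <- dim(img$values)
  if (any(d %% 2^model$cfg$n_downsample != 0)) {
    stop("image sides must be divisible by ", 2^model$cfg$n_downsample)
  }
  x <- array(hu_norm(img$values, model$cfg$hu_window), c(d, 1L))
  out <- g_forward_node(as_ad(x), model$G, model$cfg)
  v <- hu_denorm(matrix(ad_value(out$y), d[1], d[2]), model$cfg$hu_window)
  image_grid(v, img$spacing, modality = "sMV", unit = "HU")
}

#' Encoder feature stack
#'
#' Returns the selected encoder feature maps (pre-projection) for an image:
#' one `(H_l, W_l, C_l)` array per selected layer. Tap 0 is the input image
#' itself; deeper taps shrink by the encoder's stride-2 stages.
#'
#' @param img an [image_grid] in HU.
#' @param model a `transnet_model`.
#' @param selected_layers tap ids (subset of 0:4); defaults to the
#'   configured NCE layers.
#' @return Named list of arrays.
#' @export
encoder_features <- function(img, model, selected_layers = NULL) {
  stopifnot(inherits(model, "transnet_model"))
  if (is.null(selected_layers)) selected_layers <- model$cfg$nce$selected_layers
  bad <- setdiff(selected_layers, 0:4)
  if (length(bad)) stop("invalid layer id(s): ", paste(bad, collapse = ", "))
  d <- dim(img$values)
  x <- array(hu_norm(img$values, model$cfg$hu_window), c(d, 1L))
  enc <- g_encode(as_ad(x), model$G, model$cfg)
  out <- lapply(as.character(selected_layers), function(l) ad_value(enc$taps[[l]]))
  names(out) <- paste0("tap", selected_layers)
  out
}

# flatten an (H, W, C) feature map to (H*W, C)
flat_positions <- function(a) {
  d <- dim(a)
  matrix(a, d[1] * d[2], d[3])
}

#' Sample query/positive/negative NCE vectors
#'
#' Draws `n_positions` spatial positions per layer (without replacement).
#' The query vector comes from the output-image stack, the positive from
#' the input-image stack at the identical position, and the `N` negatives
#' from the input stack at distinct other positions. When projection
#' `heads` are supplied, all vectors are passed through the two-layer MLP;
#' they are always L2-normalised to the unit sphere.
#'
#' @param stack_in,stack_out named lists of feature arrays (same layers,
#'   same spatial grids), as returned by [encoder_features].
#' @param nce_cfg list with `n_positions`, `n_negatives`, `tau`.
#' @param seed integer seed for the position sampling.
#' @param heads optional projection heads (from a `transnet_model`).
#' @return Per layer: `list(v, v_pos, v_negs)` where `v`, `v_pos` are
#'   `n_positions x K` matrices and `v_negs` is
#'   `n_positions x N x K`.
#' @export
sample_nce_vectors <- function(stack_in, stack_out, nce_cfg, seed = 1L,
                               heads = NULL) {
  stopifnot(identical(names(stack_in), names(stack_out)))
  set.seed(as.integer(seed))
  out <- list()
  for (nm in names(stack_in)) {
    fin <- flat_positions(stack_in[[nm]])
    fout <- flat_positions(stack_out[[nm]])
    stopifnot(identical(dim(fin)[1], dim(fout)[1]))
    S_avail <- nrow(fin)
    S <- min(nce_cfg$n_positions, S_avail)
    N <- nce_cfg$n_negatives
    if (N + 1 > S_avail) stop("n_negatives + 1 exceeds available positions")
    pos <- sample.int(S_avail, S)
    proj <- function(M) {
      if (!is.null(heads)) {
        hd <- heads[[nm]]
        M <- ad_value(linear(ad_relu(linear(as_ad(M), hd$l1)), hd$l2))
      }
      M / (sqrt(rowSums(M^2)) + 1e-10)
    }
    q <- proj(fout[pos, , drop = FALSE])
    k <- proj(fin[pos, , drop = FALSE])
    negs <- array(0, c(S, N, ncol(k)))
    if (N > 0) {
      all_in <- proj(fin)
      for (si in seq_len(S)) {
        cand <- setdiff(seq_len(S_avail), pos[si])
        take <- sample(cand, N)
        negs[si, , ] <- all_in[take, , drop = FALSE]
      }
    }
    out[[nm]] <- list(v = q, v_pos = k, v_negs = negs)
  }
  out
}

#' PatchNCE cross-entropy term
#'
#' The (N+1)-way classification loss for one query: logits are the scaled
#' dot products of the query with its positive and the N negatives,
#' `l = -log( exp(v.v+ / tau) / (exp(v.v+ / tau) + sum_n exp(v.v_n- / tau)) )`.
#' With `N = 0` the loss is identically zero (single-class softmax).
#'
#' @param v query vector (unit norm).
#' @param v_pos positive vector (unit norm).
#' @param v_negs `N x K` matrix of negatives (may have 0 rows).
#' @param tau temperature (> 0).
#' @return Non-negative scalar.
#' @export
patch_nce_term <- function(v, v_pos, v_negs = NULL, tau = 0.07) {
  if (tau <= 0) stop("tau must be positive")
  lp <- sum(v * v_pos) / tau
  ln <- if (is.null(v_negs) || NROW(v_negs) == 0) numeric(0)
  else as.numeric(v_negs %*% v) / tau
  logits <- c(lp, ln)
  m <- max(logits)
  -(lp - (m + log(sum(exp(logits - m)))))
}

#' PatchNCE loss over layers and positions
#'
#' Mean of [patch_nce_term] over all selected layers and sampled positions:
#' queries from the translated image's encoder features, positives and
#' negatives from the input image's features at matching/other locations.
#'
#' @param model a `transnet_model`.
#' @param img input-domain image ([image_grid], HU).
#' @param seed seed for position sampling.
#' @param out_img optional translated image; computed by the generator when
#'   `NULL`.
#' @return Non-negative scalar.
#' @export
patch_nce_loss <- function(model, img, seed = 1L, out_img = NULL) {
  if (is.null(out_img)) out_img <- generator_forward(img, model)
  st_in <- encoder_features(img, model)
  st_out <- encoder_features(out_img, model)
  vs <- sample_nce_vectors(st_in, st_out, model$cfg$nce, seed, heads = model$H)
  terms <- unlist(lapply(vs, function(layer) {
    nk <- dim(layer$v_negs)[2:3]
    vapply(seq_len(nrow(layer$v)), function(s) {
      patch_nce_term(layer$v[s, ], layer$v_pos[s, ],
                     array(layer$v_negs[s, , ], dim = nk), model$cfg$nce$tau)
    }, 0)
  }))
  mean(terms)
}

#' Identity PatchNCE loss
#'
#' [patch_nce_loss] evaluated on a target-domain (MV) image: translating an
#' already-MV image should change nothing, so this acts as a learnable,
#' domain-specific identity loss.
#'
#' @inheritParams patch_nce_loss
#' @export
identity_nce_loss <- function(model, img, seed = 1L) {
  patch_nce_loss(model, img, seed)
}

#' Adversarial objective / losses
#'
#' Evaluates the adversarial objective from the discriminator outputs on a
#' real and a generated batch. `"vanilla"` uses the printed log form
#' `E[log D(y)] + E[log(1 - D(G(x)))]` (discriminator outputs are
#' probabilities; the generator term is the non-saturating variant), while
#' `"lsgan"` uses least-squares targets 1/0 on raw scores.
#'
#' @param d_real,d_fake discriminator outputs on real and generated images
#'   (any numeric shape).
#' @param flavor `"vanilla"` or `"lsgan"`.
#' @return `list(objective, loss_d, loss_g)`. For `"vanilla"`, `objective`
#'   is the value of the printed minimax objective; `loss_d = -objective`.
#' @export
adversarial_loss <- function(d_real, d_fake, flavor = c("lsgan", "vanilla")) {
  flavor <- match.arg(flavor)
  if (flavor == "vanilla") {
    obj <- mean(log(pmax(d_real, 1e-12))) + mean(log(pmax(1 - d_fake, 1e-12)))
    list(objective = obj, loss_d = -obj,
         loss_g = -mean(log(pmax(d_fake, 1e-12))))
  } else {
    list(objective = NA_real_,
         loss_d = 0.5 * mean((d_real - 1)^2) + 0.5 * mean(d_fake^2),
         loss_g = mean((d_fake - 1)^2))
  }
}

#' Total TransNet loss
#'
#' `L = lambda_gan * L_GAN + lambda_nce * L_PatchNCE(X) +
#' lambda_idt * L_PatchNCE(Y)`, with unit weights by default.
#'
#' @param gan_g generator-side adversarial loss.
#' @param nce_x PatchNCE loss on the source domain.
#' @param nce_y identity PatchNCE loss on the target domain.
#' @param weights numeric length-3 vector `(gan, nce, idt)`.
#' @return Scalar.
#' @export
transnet_total_loss <- function(gan_g, nce_x, nce_y, weights = c(1, 1, 1)) {
  weights[1] * gan_g + weights[2] * nce_x + weights[3] * nce_y
}

# autodiff PatchNCE for one layer during training: queries q and keys k are
# (S, C) feature nodes (pre-projection); negatives are the other S-1 sampled
# keys, i.e. the loss is an S-way classification with the diagonal as target
nce_layer_loss_node <- function(q_feats, k_feats, head, tau) {
  proj <- function(M) ad_l2norm_rows(linear(ad_relu(linear(M, head$l1)), head$l2))
  q <- proj(q_feats)
  k <- proj(k_feats)
  S <- nrow(ad_value(q_feats))
  logits <- ad_scale(ad_matmul(q, ad_aperm(k, c(2, 1))), 1 / tau)
  ls <- ad_logsoftmax_rows(logits)
  diag_idx <- as.integer(seq_len(S) + (seq_len(S) - 1L) * S)
  ad_scale(ad_mean(ad_gather(ls, diag_idx, S)), -1)
}

# gather sampled positions from tap nodes -> list of (S, C) nodes per layer
sample_tap_positions <- function(taps, selected, n_positions) {
  out <- list()
  for (l in selected) {
    node <- taps[[as.character(l)]]
    d <- dim(ad_value(node))
    S_avail <- d[1] * d[2]
    S <- min(n_positions, S_avail)
    pos <- sample.int(S_avail, S)
    idx <- as.integer(outer(pos, (seq_len(d[3]) - 1L) * S_avail, `+`))
    out[[as.character(l)]] <- ad_gather(node, idx, c(S, d[3]))
  }
  out
}

norm_crop <- function(values, crop, win) {
  d <- dim(values)
  i0 <- if (d[1] > crop) sample.int(d[1] - crop + 1L, 1L) else 1L
  j0 <- if (d[2] > crop) sample.int(d[2] - crop + 1L, 1L) else 1L
  v <- values[i0:(i0 + crop - 1L), j0:(j0 + crop - 1L)]
  array(hu_norm(v, win), c(crop, crop, 1L))
}

#' Train TransNet
#'
#' Adversarial + PatchNCE training on unpaired kV and MV slices (batch
#' size 1, Adam). The learning rate is constant for the first half of the
#' steps and decays linearly to zero over the second half. Deterministic
#' given `seed`.
#'
#' @param kv_images,mv_images lists of [image_grid]s (or matrices, HU). The
#'   two lists are sampled independently - no pixel pairing is used.
#' @param cfg a [transnet_config].
#' @param seed integer seed.
#' @param model optional model to resume from.
#' @param n_steps override of `cfg$n_steps`.
#' @param verbose print progress every 100 steps.
#' @return A trained `transnet_model` with a `loss_log` data frame.
#' @export
train_transnet <- function(kv_images, mv_images, cfg = transnet_config(),
                           seed = 1L, model = NULL, n_steps = NULL,
                           verbose = FALSE) {
  if (!length(kv_images) || !length(mv_images)) stop("empty dataset")
  if (is.null(model)) model <- transnet_init(cfg, seed = seed)
  cfg <- model$cfg
  if (is.null(n_steps)) n_steps <- cfg$n_steps
  as_mat <- function(x) if (inherits(x, "image_grid")) x$values else x
  kv_images <- lapply(kv_images, as_mat)
  mv_images <- lapply(mv_images, as_mat)
  g_params <- c(collect_params(model$G), collect_params(model$H))
  d_params <- collect_params(model$D)
  set.seed(as.integer(seed) + model$step)
  log_rows <- vector("list", n_steps)
  total_planned <- model$step + n_steps
  for (it in seq_len(n_steps)) {
    gstep <- model$step + it
    frac <- gstep / total_planned
    lr <- if (frac <= 0.5) cfg$lr else cfg$lr * 2 * (1 - frac)
    lr <- max(lr, cfg$lr * 1e-3)
    x <- norm_crop(kv_images[[sample.int(length(kv_images), 1)]],
                   cfg$crop_size, cfg$hu_window)
    y <- norm_crop(mv_images[[sample.int(length(mv_images), 1)]],
                   cfg$crop_size, cfg$hu_window)
    # generator forward on x (keeps encoder taps for NCE)
    gx <- g_forward_node(as_ad(x), model$G, cfg)
    fake_val <- ad_value(gx$y)
    # --- discriminator step (generated image detached) ---
    sr <- d_forward_node(as_ad(y), model$D)
    sf <- d_forward_node(as_ad(fake_val), model$D)
    loss_d <- if (cfg$gan_flavor == "lsgan") {
      ad_add(ad_scale(ad_mean(ad_square(ad_sub(sr, 1))), 0.5),
             ad_scale(ad_mean(ad_square(sf)), 0.5))
    } else {
      ad_scale(ad_add(ad_mean(ad_log(ad_sigmoid(sr))),
                      ad_mean(ad_log(ad_sub(1, ad_sigmoid(sf))))), -1)
    }
    ad_backward(loss_d)
    adam_step(d_params, lr, cfg$beta1, cfg$beta2)
    ad_zero_grad(d_params)
    # --- generator + heads step ---
    sf2 <- d_forward_node(gx$y, model$D)
    gan_g <- if (cfg$gan_flavor == "lsgan") {
      ad_mean(ad_square(ad_sub(sf2, 1)))
    } else {
      ad_scale(ad_mean(ad_log(ad_sigmoid(sf2))), -1)
    }
    sel <- cfg$nce$selected_layers
    # NCE(X): encoder features of x (from gx) vs encoder re-run on G(x)
    enc_fake <- g_encode(gx$y, model$G, cfg)
    seed_pos <- sample.int(1e6, 1)
    set.seed(seed_pos)
    q_x <- sample_tap_positions(enc_fake$taps, sel, cfg$nce$n_positions)
    set.seed(seed_pos)  # identical positions in the input stack
    k_x <- sample_tap_positions(gx$taps, sel, cfg$nce$n_positions)
    nce_x <- NULL
    for (l in as.character(sel)) {
      t_l <- nce_layer_loss_node(q_x[[l]], k_x[[l]],
                                 model$H[[paste0("tap", l)]], cfg$nce$tau)
      nce_x <- if (is.null(nce_x)) t_l else ad_add(nce_x, t_l)
    }
    nce_x <- ad_scale(nce_x, 1 / length(sel))
    # NCE(Y): identity pass
    gy <- g_forward_node(as_ad(y), model$G, cfg)
    enc_idt <- g_encode(gy$y, model$G, cfg)
    seed_pos2 <- sample.int(1e6, 1)
    set.seed(seed_pos2)
    q_y <- sample_tap_positions(enc_idt$taps, sel, cfg$nce$n_positions)
    set.seed(seed_pos2)
    k_y <- sample_tap_positions(gy$taps, sel, cfg$nce$n_positions)
    nce_y <- NULL
    for (l in as.character(sel)) {
      t_l <- nce_layer_loss_node(q_y[[l]], k_y[[l]],
                                 model$H[[paste0("tap", l)]], cfg$nce$tau)
      nce_y <- if (is.null(nce_y)) t_l else ad_add(nce_y, t_l)
    }
    nce_y <- ad_scale(nce_y, 1 / length(sel))
    loss_g <- ad_add(ad_scale(gan_g, cfg$lambda_gan),
                     ad_add(ad_scale(nce_x, cfg$lambda_nce),
                            ad_scale(nce_y, cfg$lambda_idt)))
    ad_backward(loss_g)
    adam_step(g_params, lr, cfg$beta1, cfg$beta2)
    ad_zero_grad(c(g_params, d_params))
    log_rows[[it]] <- data.frame(step = gstep, lr = lr,
                                 loss_d = ad_value(loss_d),
                                 loss_g = ad_value(loss_g),
                                 gan_g = ad_value(gan_g),
                                 nce_x = ad_value(nce_x),
                                 nce_y = ad_value(nce_y))
    if (verbose && it %% 100 == 0) {
      message(sprintf("transnet step %d/%d  D %.3f  G %.3f", gstep,
                      total_planned, ad_value(loss_d), ad_value(loss_g)))
    }
  }
  model$step <- model$step + n_steps
  model$trained <- TRUE
  new_log <- do.call(rbind, log_rows)
  model$loss_log <- rbind(model$loss_log, new_log)
  model
}

#' Translate a kV image to synthetic MV
#'
#' @param kv an [image_grid] (KV, HU).
#' @param model a trained `transnet_model`.
#' @return An [image_grid] with modality `"sMV"`.
#' @export
synthesize_mvct <- function(kv, model) {
  stopifnot(inherits(model, "transnet_model"))
  if (!isTRUE(model$trained)) {
    warning("model has not been trained; output is the raw initialisation")
  }
  generator_forward(kv, model)
}

#' Save / load a model checkpoint
#'
#' Checkpoints carry the config, all parameter values and the training
#' step / loss log, so training can resume deterministically.
#'
#' @param model a `transnet_model` or `fovnet_model`.
#' @param path output `.rds` path.
#' @export
save_checkpoint <- function(model, path) {
  obj <- list(class = class(model), cfg = model$cfg,
              step = model$step, trained = model$trained,
              loss_log = model$loss_log)
  # store the full parameter state of every trainable component present
  comp <- intersect(names(model), c("G", "D", "H", "net"))
  obj$state <- lapply(model[comp], params_state)
  obj$components <- comp
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @param init_fn the matching initialiser ([transnet_init] or
#'   [fovnet_init]); when `NULL` it is inferred from the checkpoint class.
#' @export
load_checkpoint <- function(path, init_fn = NULL) {
  obj <- readRDS(path)
  if (is.null(init_fn)) {
    init_fn <- if ("transnet_model" %in% obj$class) transnet_init else fovnet_init
  }
  model <- init_fn(obj$cfg, seed = 1L)
  for (comp in obj$components) {
    restore_params(model[[comp]], obj$state[[comp]])
  }
  model$step <- obj$step
  model$trained <- obj$trained
  model$loss_log <- obj$loss_log
  model
}
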
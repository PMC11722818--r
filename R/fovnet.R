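#' Swin FOV-Net configuration
#'
#' Configuration of the window-attention U-shaped inpainting network that
#' fuses the pre-corrected reconstruction and the synthetic-MV prior into
#' an extended-FOV image. Token grids are produced by non-overlapping
#' `patch_size` x `patch_size` patch embedding; each resolution level runs
#' an even number of Swin blocks (alternating W-MSA / SW-MSA with shift
#' `window/2`); levels are linked by patch-merging (down) and
#' patch-expanding (up) layers with skip connections, and the input is
#' additionally skip-fed to the final linear layer.
#'
#' `"desk"`: 96x96 inputs, patch 4, embed 24, window 4, two resolution
#' levels (24^2 and 12^2 tokens). `"full"`: 512x512 inputs, patch 4,
#' embed 48, window 8, four levels (128^2 ... 16^2), mirroring the
#' published layout (the 512x512x2 input embeds to 128x128x48 tokens).
#'
#' @param scale `"desk"` or `"full"`.
#' @param ... field overrides.
#' @return A list of class `swin_config`.
#' @export
swin_config <- function(scale = c("desk", "full"), ...) {
  scale <- match.arg(scale)
  cfg <- if (scale == "desk") {
    list(img_size = 96, patch_size = 4, embed_dim = 24, window = 4,
         depths = c(2, 2), heads = c(3, 6), mlp_ratio = 2,
         in_channels = 2, out_channels = 1,
         final_channels = 6, hu_window = c(-1024, 1500),
         fov_aware_head = TRUE,
         n_steps = 1200, batch_size = 1, lr = 5e-3,
         masked_loss = TRUE, beta1 = 0.9, beta2 = 0.999)
  } else {
    list(img_size = 512, patch_size = 4, embed_dim = 48, window = 8,
         depths = c(2, 2, 2, 2), heads = c(3, 6, 12, 24), mlp_ratio = 4,
         in_channels = 2, out_channels = 1,
         final_channels = 12, hu_window = c(-1024, 1500),
         fov_aware_head = TRUE,
         n_steps = 100 * 912, batch_size = 8, lr = 2e-4,
         masked_loss = TRUE, beta1 = 0.9, beta2 = 0.999)
  }
  ov <- list(...)
  cfg[names(ov)] <- ov
  cfg$scale <- scale
  grid <- cfg$img_size / cfg$patch_size
  n_lv <- length(cfg$depths)
  stopifnot(cfg$img_size %% cfg$patch_size == 0,
            all(cfg$depths %% 2 == 0),
            length(cfg$heads) == n_lv,
            grid %% (cfg$window * 2^(n_lv - 1)) == 0)
  structure(cfg, class = "swin_config")
}

# per-level channel widths
swin_channels <- function(cfg) cfg$embed_dim * 2^(seq_along(cfg$depths) - 1)

init_swin_block <- function(C, heads, M) {
  list(ln1 = init_norm(C),
       wq = init_linear(C, C), wk = init_linear(C, C), wv = init_linear(C, C),
       proj = init_linear(C, C),
       bias_table = ad_param(matrix(stats::rnorm((2 * M - 1)^2 * heads, 0, 0.02),
                                    (2 * M - 1)^2, heads)),
       ln2 = init_norm(C),
       fc1 = NULL, fc2 = NULL)
}

#' Initialise a FOV-Net model
#'
#' @param cfg a [swin_config].
#' @param seed integer seed.
#' @return A `fovnet_model` list. The output head starts near zero, so an
#'   untrained network approximately reproduces its pre-corrected input
#'   (exactly, if the head is explicitly zeroed).
#' @export
fovnet_init <- function(cfg = swin_config(), seed = 1L) {
  set.seed(as.integer(seed))
  Cs <- swin_channels(cfg)
  M <- cfg$window
  mk_blocks <- function(C, heads, n) {
    lapply(seq_len(n), function(i) {
      b <- init_swin_block(C, heads, M)
      b$fc1 <- init_linear(C, cfg$mlp_ratio * C)
      b$fc2 <- init_linear(cfg$mlp_ratio * C, C)
      b
    })
  }
  n_lv <- length(cfg$depths)
  grid <- cfg$img_size %/% cfg$patch_size
  net <- list(
    embed = init_conv(cfg$patch_size, cfg$in_channels, cfg$embed_dim),
    embed_ln = init_norm(cfg$embed_dim),
    # learnable absolute positional embedding: the scan-FOV boundary is a
    # fixed spatial structure, and relative-position bias alone gives
    # windows no absolute anchor to locate it
    ape = ad_param(array(stats::rnorm(grid^2 * cfg$embed_dim, 0, 0.02),
                         c(grid, grid, cfg$embed_dim))),
    enc = lapply(seq_len(n_lv), function(s) {
      mk_blocks(Cs[s], cfg$heads[s], cfg$depths[s])
    }),
    merge = lapply(seq_len(n_lv - 1), function(s) init_linear(4 * Cs[s], 2 * Cs[s])),
    expand = lapply(seq_len(n_lv - 1), function(s) init_linear(Cs[s + 1], 2 * Cs[s + 1])),
    fuse = lapply(seq_len(n_lv - 1), function(s) init_linear(2 * Cs[s], Cs[s])),
    dec = lapply(seq_len(n_lv - 1), function(s) {
      mk_blocks(Cs[s], cfg$heads[s], cfg$depths[s])
    }),
    final_expand = init_linear(Cs[1], cfg$patch_size^2 * cfg$final_channels),
    out = init_linear(cfg$final_channels + cfg$in_channels +
                        (if (isTRUE(cfg$fov_aware_head)) 3L else 0L),
                      cfg$out_channels, gain = 0.05)
  )
  # near-zero output head: the network starts close to the identity on its
  # pre-corrected input and learns a correction on top of it, while the
  # small non-zero weights let gradients reach the transformer stages
  structure(list(cfg = cfg, net = net, trained = FALSE, step = 0L,
                 loss_log = NULL),
            class = "fovnet_model")
}

# ---- exported token-space operations ----------------------------------------

#' Patch embedding
#'
#' Splits a 2-channel image into non-overlapping `patch_size` patches and
#' linearly maps each to an `embed_dim`-vector (a 512x512x2 input under the
#' full-scale configuration becomes a 128x128x48 token grid).
#'
#' @param img_pair `(H, W, in_channels)` array (normalised intensities).
#' @param model a `fovnet_model`.
#' @return `(H/p, W/p, embed_dim)` token array.
#' @export
patch_embed <- function(img_pair, model) {
  cfg <- model$cfg
  d <- dim(img_pair)
  if (any(d[1:2] %% cfg$patch_size != 0)) {
    stop("image sides must be divisible by patch_size")
  }
  stopifnot(d[3] == cfg$in_channels)
  ad_value(patch_embed_node(as_ad(img_pair), model$net, cfg))
}

patch_embed_node <- function(x, net, cfg, ape = FALSE) {
  t0 <- conv2d(x, net$embed, cfg$patch_size, stride = cfg$patch_size, pad = 0)
  tok <- ad_layernorm(t0, net$embed_ln$gamma, net$embed_ln$beta)
  if (ape && !is.null(net$ape)) tok <- ad_add(tok, net$ape)
  tok
}

#' Window partition / reverse
#'
#' Splits an `(H, W, C)` token grid into non-overlapping `M x M` windows
#' (`(nW, M^2, C)`) and merges them back; the two are exact bijections.
#'
#' @param tokens `(H, W, C)` array.
#' @param M window size (must divide H and W).
#' @return `window_partition`: `(nW, M^2, C)` array; `window_reverse`: the
#'   `(H, W, C)` grid.
#' @export
window_partition <- function(tokens, M) {
  d <- dim(tokens)
  wp <- window_partition_idx(d[1], d[2], d[3], M)
  array(tokens[wp$idx], wp$dim)
}

#' @rdname window_partition
#' @param windows `(nW, M^2, C)` array produced by `window_partition`.
#' @param H,W token-grid dimensions.
#' @export
window_reverse <- function(windows, M, H, W) {
  C <- dim(windows)[3]
  wp <- window_partition_idx(H, W, C, M)
  array(as.numeric(windows)[wp$inv], c(H, W, C))
}

#' Cyclic (toroidal) shift of a token grid
#'
#' Rolls the grid by `offset` rows and columns (negative offsets for the
#' SW-MSA shift); `cyclic_shift(cyclic_shift(x, k), -k)` is the identity.
#'
#' @param tokens `(H, W, C)` array.
#' @param offset integer shift applied to both axes.
#' @return Shifted array of the same shape.
#' @export
cyclic_shift <- function(tokens, offset) {
  if (offset %% dim(tokens)[1] == 0 && offset %% dim(tokens)[2] == 0) {
    return(tokens)
  }
  d <- dim(tokens)
  plan <- cyclic_shift_idx(d[1], d[2], d[3], offset, offset)
  array(c(tokens, 0)[plan$idx_safe], d)
}

#' Scaled dot-product window attention
#'
#' `Attention(Q, K, V) = softmax(Q K^T / sqrt(d) + B) V` for one window and
#' one head; every softmax row sums to one.
#'
#' @param Q,K,V `M^2 x d` matrices.
#' @param B optional `M^2 x M^2` additive bias (relative-position bias plus
#'   any shift mask).
#' @return `list(output, attention)`.
#' @export
window_attention <- function(Q, K, V, B = NULL) {
  stopifnot(identical(dim(Q), dim(K)), nrow(K) == nrow(V))
  d <- ncol(Q)
  S <- Q %*% t(K) / sqrt(d)
  if (!is.null(B)) S <- S + B
  S <- S - apply(S, 1, max)
  A <- exp(S); A <- A / rowSums(A)
  list(output = A %*% V, attention = A)
}

# ---- internal attention / block forward -------------------------------------

# bias gather plan: (h, M^2, M^2) from the ((2M-1)^2, h) table
bias_plan <- function(M, h) {
  key <- paste("biasplan", M, h, sep = "_")
  cache_get(key, function() {
    rel <- relpos_index(M)          # (M^2, M^2), values 1..(2M-1)^2
    n_off <- (2 * M - 1)^2
    M2 <- M * M
    idx <- integer(h * M2 * M2)
    pos <- 0L
    for (j in seq_len(M2)) {
      for (i in seq_len(M2)) {
        idx[pos + seq_len(h)] <- rel[i, j] + (seq_len(h) - 1L) * n_off
        pos <- pos + h
      }
    }
    gather_plan(idx, n_off * h, c(h, M2, M2))
  })
}

# shift mask replicated over heads: (nW*h, M^2, M^2) constant array
sw_mask_full <- function(H, W, M, shift, h) {
  key <- paste("swmaskfull", H, W, M, shift, h, sep = "_")
  cache_get(key, function() {
    mask <- sw_attn_mask(H, W, M, shift)
    nW <- dim(mask)[1]; M2 <- M * M
    arr <- array(0, c(nW, h, M2, M2))
    for (hh in seq_len(h)) arr[, hh, , ] <- mask
    dim(arr) <- c(nW * h, M2, M2)
    arr
  })
}

# one Swin block on (H, W, C) tokens; shift > 0 selects SW-MSA
swin_block_node <- function(x, blk, heads, M, shift, cfg) {
  d <- dim(ad_value(x))
  H <- d[1]; W <- d[2]; C <- d[3]
  dh <- C / heads
  xm <- ad_reshape(x, c(H * W, C))
  h1 <- ad_layernorm(xm, blk$ln1$gamma, blk$ln1$beta)
  hg <- ad_reshape(h1, c(H, W, C))
  if (shift > 0) {
    plan <- cyclic_shift_idx(H, W, C, -shift, -shift)
    hg <- ad_gather(hg, plan)
  }
  wp <- window_partition_idx(H, W, C, M)
  win <- ad_gather(hg, wp$plan)                   # (nW, M^2, C)
  nW <- wp$nW; M2 <- M * M
  wm <- ad_reshape(win, c(nW * M2, C))
  to_heads <- function(z) {
    z <- ad_reshape(z, c(nW, M2, heads, dh))
    z <- ad_aperm(z, c(1, 3, 2, 4))
    ad_reshape(z, c(nW * heads, M2, dh))
  }
  q <- to_heads(linear(wm, blk$wq))
  k <- to_heads(linear(wm, blk$wk))
  v <- to_heads(linear(wm, blk$wv))
  scores <- ad_scale(ad_bmm(q, ad_aperm(k, c(1, 3, 2))), 1 / sqrt(dh))
  bias <- ad_gather(blk$bias_table, bias_plan(M, heads))
  scores <- ad_add(scores, ad_reshape(ad_rep_lead(bias, nW),
                                      c(nW * heads, M2, M2)))
  if (shift > 0) {
    scores <- ad_add(scores, sw_mask_full(H, W, M, shift, heads))
  }
  attn <- ad_softmax_last(scores)
  out <- ad_bmm(attn, v)                          # (nW*heads, M2, dh)
  out <- ad_reshape(out, c(nW, heads, M2, dh))
  out <- ad_aperm(out, c(1, 3, 2, 4))
  out <- ad_reshape(out, c(nW * M2, C))
  out <- linear(out, blk$proj)
  out <- ad_reshape(out, c(nW, M2, C))
  og <- ad_gather(out, wp$inv_plan)               # back to (H, W, C)
  if (shift > 0) {
    plan_b <- cyclic_shift_idx(H, W, C, shift, shift)
    og <- ad_gather(og, plan_b)
  }
  x1 <- ad_add(x, og)                             # attention residual
  x1m <- ad_reshape(x1, c(H * W, C))
  h2 <- ad_layernorm(x1m, blk$ln2$gamma, blk$ln2$beta)
  mlp <- linear(ad_gelu(linear(h2, blk$fc1)), blk$fc2)
  ad_reshape(ad_add(x1m, mlp), c(H, W, C))
}

#' Paired Swin blocks (W-MSA then SW-MSA)
#'
#' Applies two consecutive Swin blocks to a token grid: the first with
#' regular window attention, the second with the shifted-window variant
#' (shift `window/2`, masked so tokens do not mix across the toroidal
#' seam). Shape-preserving.
#'
#' @param tokens `(H, W, C)` token array.
#' @param model a `fovnet_model`.
#' @param level resolution level (1-based).
#' @param pair which block pair of the level (1-based).
#' @param branch `"enc"` or `"dec"`.
#' @return Token array of the same shape.
#' @export
swin_block_pair <- function(tokens, model, level = 1, pair = 1,
                            branch = "enc") {
  cfg <- model$cfg
  blocks <- model$net[[branch]][[level]]
  i <- 2 * (pair - 1) + 1
  stopifnot(i + 1 <= length(blocks))
  x <- as_ad(tokens)
  x <- swin_block_node(x, blocks[[i]], cfg$heads[level], cfg$window, 0, cfg)
  x <- swin_block_node(x, blocks[[i + 1]], cfg$heads[level], cfg$window,
                       cfg$window %/% 2, cfg)
  ad_value(x)
}

# pixel shuffle gather plan: (H, W, r^2*c) -> (rH, rW, c)
pixel_shuffle_plan <- function(H, W, c_out, r) {
  key <- paste("pshuf", H, W, c_out, r, sep = "_")
  cache_get(key, function() {
    oH <- r * H; oW <- r * W
    oi <- rep(seq_len(oH), times = oW)
    oj <- rep(seq_len(oW), each = oH)
    a <- (oi - 1L) %% r; b <- (oj - 1L) %% r
    ii <- (oi - 1L) %/% r + 1L; jj <- (oj - 1L) %/% r + 1L
    base <- ii + (jj - 1L) * H
    idx <- integer(oH * oW * c_out)
    pos <- 0L
    for (cc in seq_len(c_out)) {
      ch <- (cc - 1L) + c_out * (a + r * b)       # source channel
      idx[pos + seq_len(oH * oW)] <- base + ch * H * W
      pos <- pos + oH * oW
    }
    gather_plan(idx, H * W * r^2 * c_out, c(oH, oW, c_out))
  })
}

patch_merge_node <- function(x, layer) {
  d <- dim(ad_value(x))
  H <- d[1]; W <- d[2]; C <- d[3]
  stopifnot(H %% 2 == 0, W %% 2 == 0)
  key <- paste("pmerge", H, W, C, sep = "_")
  plan <- cache_get(key, function() {
    oH <- H %/% 2L; oW <- W %/% 2L
    oi <- rep(seq_len(oH), times = oW)
    oj <- rep(seq_len(oW), each = oH)
    idx <- integer(oH * oW * 4L * C)
    pos <- 0L
    for (cc in seq_len(C)) {
      for (b in 0:1) for (a in 0:1) {
        ii <- 2L * (oi - 1L) + a + 1L
        jj <- 2L * (oj - 1L) + b + 1L
        idx[pos + seq_len(oH * oW)] <- ii + (jj - 1L) * H + (cc - 1L) * H * W
        pos <- pos + oH * oW
      }
    }
    # column order: (a, b) neighbours fastest, then channel
    gather_plan(idx, H * W * C, c(oH * oW, 4L * C))
  })
  cols <- ad_gather(x, plan)
  y <- linear(cols, layer)
  ad_reshape(y, c(H %/% 2L, W %/% 2L, 2L * C))
}

patch_expand_node <- function(x, layer) {
  d <- dim(ad_value(x))
  y <- linear(ad_reshape(x, c(d[1] * d[2], d[3])), layer)
  c2 <- ncol(ad_value(layer$w))
  y <- ad_reshape(y, c(d[1], d[2], c2))
  ad_gather(y, pixel_shuffle_plan(d[1], d[2], c2 %/% 4L, 2L))
}

#' Patch merging / expansion
#'
#' `patch_merge` concatenates each 2x2 token neighbourhood and applies a
#' linear reduction (`(H, W, C) -> (H/2, W/2, 2C)`); `patch_expand`
#' linearly doubles the channels and redistributes them spatially
#' (`(H, W, C) -> (2H, 2W, C/2)`), inverting the merge's shape transform.
#'
#' @param tokens `(H, W, C)` token array.
#' @param model a `fovnet_model`.
#' @param level encoder level of the merge/expand layer (1-based).
#' @return Token array with the stated shape.
#' @export
patch_merge <- function(tokens, model, level = 1) {
  ad_value(patch_merge_node(as_ad(tokens), model$net$merge[[level]]))
}

#' @rdname patch_merge
#' @export
patch_expand <- function(tokens, model, level = 1) {
  ad_value(patch_expand_node(as_ad(tokens), model$net$expand[[level]]))
}

# full forward pass on a (H, W, 2) normalised input; `head_aux` is an
# optional constant (H, W, k) array appended to the final head (the
# FOV-aware ring indicator and its products with the inputs). Returns the
# output in normalised units.
fovnet_forward_node <- function(x, iprec_norm, net, cfg, head_aux = NULL) {
  n_lv <- length(cfg$depths)
  M <- cfg$window
  tok <- patch_embed_node(x, net, cfg, ape = TRUE)
  skips <- vector("list", n_lv - 1)
  for (s in seq_len(n_lv)) {
    blocks <- net$enc[[s]]
    for (i in seq(1, length(blocks), by = 2)) {
      tok <- swin_block_node(tok, blocks[[i]], cfg$heads[s], M, 0, cfg)
      tok <- swin_block_node(tok, blocks[[i + 1]], cfg$heads[s], M,
                             M %/% 2, cfg)
    }
    if (s < n_lv) {
      skips[[s]] <- tok
      tok <- patch_merge_node(tok, net$merge[[s]])
    }
  }
  for (s in seq(n_lv - 1, 1)) {
    tok <- patch_expand_node(tok, net$expand[[s]])
    d <- dim(ad_value(tok))
    cat2 <- ad_concat_last(tok, skips[[s]])
    fused <- linear(ad_reshape(cat2, c(d[1] * d[2], 2L * d[3])), net$fuse[[s]])
    tok <- ad_reshape(fused, c(d[1], d[2], d[3]))
    blocks <- net$dec[[s]]
    for (i in seq(1, length(blocks), by = 2)) {
      tok <- swin_block_node(tok, blocks[[i]], cfg$heads[s], M, 0, cfg)
      tok <- swin_block_node(tok, blocks[[i + 1]], cfg$heads[s], M,
                             M %/% 2, cfg)
    }
  }
  d <- dim(ad_value(tok))
  y <- linear(ad_reshape(tok, c(d[1] * d[2], d[3])), net$final_expand)
  y <- ad_reshape(y, c(d[1], d[2], cfg$patch_size^2 * cfg$final_channels))
  feat <- ad_gather(y, pixel_shuffle_plan(d[1], d[2], cfg$final_channels,
                                          cfg$patch_size))
  # skip-feed the full input pair to the final linear layer; the output is
  # a residual on the pre-corrected channel
  withskip <- ad_concat_last(feat, x)
  if (!is.null(head_aux)) withskip <- ad_concat_last(withskip, head_aux)
  dd <- dim(ad_value(withskip))
  o <- linear(ad_reshape(withskip, c(dd[1] * dd[2], dd[3])), net$out)
  o <- ad_reshape(o, c(dd[1], dd[2], 1L))
  ad_add(o, iprec_norm)
}

# ring indicator (1 outside the scan FOV) and its products with the two
# normalised input channels; zeros when the scan FOV is unknown
fov_head_aux <- function(cfg, d, p_n, s_n, sfov_mask) {
  if (!isTRUE(cfg$fov_aware_head)) return(NULL)
  r <- if (is.null(sfov_mask)) matrix(0, d[1], d[2]) else 1 - (sfov_mask > 0)
  array(c(r, r * p_n, r * s_n), c(d, 3L))
}

#' FOV-Net forward pass
#'
#' Produces the extended-FOV image from the pre-corrected reconstruction
#' and the (registered) synthetic-MV prior. Deterministic in evaluation.
#'
#' @param i_prec pre-corrected MVCT ([image_grid], HU).
#' @param i_smv synthetic-MV prior of identical geometry (pass `i_prec`
#'   again to run the no-prior ablation).
#' @param model a `fovnet_model`.
#' @param sfov_mask optional 0/1 matrix marking pixels inside the scan FOV.
#'   The scan geometry is known at inference time, and the FOV-aware head
#'   receives the ring indicator (and its products with the inputs) so the
#'   in-FOV/extended-FOV blend is directly expressible; `NULL` feeds zeros.
#' @return An [image_grid] in HU.
#' @export
fovnet_forward <- function(i_prec, i_smv, model, sfov_mask = NULL) {
  stopifnot(inherits(model, "fovnet_model"),
            identical(dim(i_prec$values), dim(i_smv$values)))
  cfg <- model$cfg
  d <- dim(i_prec$values)
  p_n <- hu_norm(i_prec$values, cfg$hu_window)
  s_n <- hu_norm(i_smv$values, cfg$hu_window)
  x <- array(c(p_n, s_n), c(d, 2L))
  aux <- fov_head_aux(cfg, d, p_n, s_n, sfov_mask)
  out <- fovnet_forward_node(as_ad(x), array(p_n, c(d, 1L)), model$net, cfg,
                             head_aux = aux)
  v <- hu_denorm(matrix(ad_value(out), d[1], d[2]), cfg$hu_window)
  image_grid(v, i_prec$spacing, modality = "MV", unit = "HU")
}

#' L1 reconstruction loss
#'
#' Mean absolute difference between the network output and the ground
#' truth; identical to the whole-image MAE.
#'
#' @param pred,gt images or matrices of identical shape.
#' @return Non-negative scalar.
#' @export
reconstruction_loss <- function(pred, gt) {
  pv <- if (inherits(pred, "image_grid")) pred$values else as.matrix(pred)
  gv <- if (inherits(gt, "image_grid")) gt$values else as.matrix(gt)
  stopifnot(identical(dim(pv), dim(gv)))
  mean(abs(pv - gv))
}

#' Number of trainable parameters
#'
#' @param model a `fovnet_model` or `transnet_model` (or a [swin_config] /
#'   [transnet_config], which is instantiated first).
#' @return Integer count of scalar parameters.
#' @export
model_param_count <- function(model) {
  if (inherits(model, "swin_config")) model <- fovnet_init(model, seed = 1L)
  if (inherits(model, "transnet_config")) model <- transnet_init(model, seed = 1L)
  comp <- intersect(names(model), c("G", "D", "H", "net"))
  sum(vapply(model[comp], count_params, 0))
}

#' Train FOV-Net
#'
#' Supervised L1 training on (pre-corrected, prior, ground-truth) triplets
#' with Adam; the learning rate is constant for the first 80% of steps and
#' decays linearly to zero afterwards. Losses are computed on the
#' normalised intensity scale. Deterministic given `seed`.
#'
#' @param triplets list of `list(i_prec, i_smv, gt)` ([image_grid]s or HU
#'   matrices), optionally with a non-negative weight matrix `mask` (when
#'   `masked_loss` is set the L1 loss is weighted by it, matching the
#'   background-removed training data the method is designed for) and a
#'   0/1 `sfov` matrix feeding the FOV-aware head. For the no-prior
#'   ablation pass `i_prec` as `i_smv`.
#' @param cfg a [swin_config].
#' @param seed integer seed.
#' @param model optional model to resume from.
#' @param n_steps override of `cfg$n_steps`.
#' @param verbose print progress every 100 steps.
#' @return A trained `fovnet_model`.
#' @export
train_fovnet <- function(triplets, cfg = swin_config(), seed = 1L,
                         model = NULL, n_steps = NULL, verbose = FALSE) {
  if (!length(triplets)) stop("empty dataset")
  if (is.null(model)) model <- fovnet_init(cfg, seed = seed)
  cfg <- model$cfg
  if (is.null(n_steps)) n_steps <- cfg$n_steps
  as_mat <- function(x) if (inherits(x, "image_grid")) x$values else x
  params <- collect_params(model$net)
  set.seed(as.integer(seed) + model$step)
  total_planned <- model$step + n_steps
  log_rows <- vector("list", n_steps)
  for (it in seq_len(n_steps)) {
    gstep <- model$step + it
    frac <- gstep / total_planned
    lr <- if (frac <= 0.8) cfg$lr else cfg$lr * 5 * (1 - frac)
    lr <- max(lr, cfg$lr * 1e-3)
    loss_acc <- 0
    for (bi in seq_len(cfg$batch_size)) {
      tr <- triplets[[sample.int(length(triplets), 1)]]
      d <- dim(as_mat(tr$i_prec))
      p_n <- hu_norm(as_mat(tr$i_prec), cfg$hu_window)
      s_n <- hu_norm(as_mat(tr$i_smv), cfg$hu_window)
      g_n <- hu_norm(as_mat(tr$gt), cfg$hu_window)
      x <- array(c(p_n, s_n), c(d, 2L))
      aux <- fov_head_aux(cfg, d, p_n, s_n, tr$sfov)
      out <- fovnet_forward_node(as_ad(x), array(p_n, c(d, 1L)),
                                 model$net, cfg, head_aux = aux)
      resid <- ad_abs(ad_sub(out, array(g_n, c(d, 1L))))
      loss <- if (isTRUE(cfg$masked_loss) && !is.null(tr$mask)) {
        w <- array(as_mat(tr$mask), c(d, 1L))
        ad_scale(ad_sum(ad_mul(resid, w)), 1 / (sum(w) * cfg$batch_size))
      } else {
        ad_scale(ad_mean(resid), 1 / cfg$batch_size)
      }
      ad_backward(loss)
      loss_acc <- loss_acc + ad_value(loss)
    }
    adam_step(params, lr, cfg$beta1, cfg$beta2)
    ad_zero_grad(params)
    log_rows[[it]] <- data.frame(step = gstep, lr = lr, loss_l1 = loss_acc)
    if (verbose && it %% 100 == 0) {
      message(sprintf("fovnet step %d/%d  L1 %.4f", gstep, total_planned,
                      loss_acc))
    }
  }
  model$step <- model$step + n_steps
  model$trained <- TRUE
  model$loss_log <- rbind(model$loss_log, do.call(rbind, log_rows))
  model
}
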
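# Neural-network layers built on the autodiff primitives. Feature maps are
# (H, W, C) arrays for convolutional parts and (N, C) matrices / token
# arrays for transformer parts; batch size is 1 image per forward pass.

.idx_cache <- new.env(parent = emptyenv())

cache_get <- function(key, builder) {
  if (is.null(.idx_cache[[key]])) .idx_cache[[key]] <- builder()
  .idx_cache[[key]]
}

# im2col index map: linear indices into an (H, W, Cin) array for every
# (out-position, patch-element) pair; 0 marks zero padding. Column order is
# (di, dj, c) to match the (k, k, Cin, Cout) weight layout.
im2col_idx <- function(H, W, Cin, k, stride, pad) {
  key <- paste("im2col", H, W, Cin, k, stride, pad, sep = "_")
  cache_get(key, function() {
    Ho <- (H + 2 * pad - k) %/% stride + 1
    Wo <- (W + 2 * pad - k) %/% stride + 1
    io <- rep(seq_len(Ho), times = Wo)          # out rows vary fastest
    jo <- rep(seq_len(Wo), each = Ho)
    i0 <- (io - 1) * stride - pad               # top-left corner (0-based)
    j0 <- (jo - 1) * stride - pad
    n_out <- Ho * Wo
    idx <- matrix(0L, n_out, k * k * Cin)
    col <- 0L
    for (c in seq_len(Cin)) {
      for (dj in 0:(k - 1)) {
        for (di in 0:(k - 1)) {
          col <- col + 1L
          ii <- i0 + di + 1L
          jj <- j0 + dj + 1L
          ok <- ii >= 1L & ii <= H & jj >= 1L & jj <= W
          v <- integer(n_out)
          v[ok] <- ii[ok] + (jj[ok] - 1L) * H + (c - 1L) * H * W
          idx[, col] <- v
        }
      }
    }
    list(plan = gather_plan(idx, H * W * Cin, c(n_out, k * k * Cin)),
         Ho = Ho, Wo = Wo)
  })
}

# He-style initialisation for a conv weight matrix (k*k*Cin, Cout)
init_conv <- function(k, Cin, Cout, gain = 1) {
  fan_in <- k * k * Cin
  w <- matrix(stats::rnorm(fan_in * Cout, 0, gain * sqrt(2 / fan_in)),
              fan_in, Cout)
  list(w = ad_param(w), b = ad_param(numeric(Cout)))
}

init_linear <- function(Cin, Cout, gain = 1) {
  w <- matrix(stats::rnorm(Cin * Cout, 0, gain * sqrt(2 / Cin)), Cin, Cout)
  list(w = ad_param(w), b = ad_param(numeric(Cout)))
}

init_norm <- function(C) {
  list(gamma = ad_param(rep(1, C)), beta = ad_param(numeric(C)))
}

# 2D convolution of an (H, W, Cin) node with layer = list(w, b)
conv2d <- function(x, layer, k, stride = 1, pad = (k - 1) %/% 2) {
  d <- dim_or_len(ad_value(x))
  Cin <- if (length(d) == 3) d[3] else 1L
  if (length(d) == 2) x <- ad_reshape(x, c(d[1], d[2], 1L))
  ic <- im2col_idx(d[1], d[2], Cin, k, stride, pad)
  cols <- ad_gather(x, ic$plan)
  y <- ad_add_bias(ad_matmul(cols, layer$w), layer$b)
  ad_reshape(y, c(ic$Ho, ic$Wo, ncol(ad_value(layer$w))))
}

linear <- function(x, layer) {
  ad_add_bias(ad_matmul(x, layer$w), layer$b)
}

# nearest-neighbour x2 upsampling of (H, W, C) via a gather
upsample_nn2 <- function(x) {
  d <- dim(ad_value(x))
  key <- paste("up2", d[1], d[2], d[3], sep = "_")
  ic <- cache_get(key, function() {
    H <- d[1]; W <- d[2]; C <- d[3]
    io <- rep(seq_len(2 * H), times = 2 * W)
    jo <- rep(seq_len(2 * W), each = 2 * H)
    ii <- (io + 1L) %/% 2L; jj <- (jo + 1L) %/% 2L
    base <- ii + (jj - 1L) * H
    idx <- as.integer(outer(base, (seq_len(C) - 1L) * H * W, `+`))
    gather_plan(idx, H * W * C, c(2L * H, 2L * W, C))
  })
  ad_gather(x, ic)
}

# ---- window utilities for the Swin blocks ----------------------------------

# (H, W, C) tokens -> (nW, M^2, C) windows; exact bijection via gather
window_partition_idx <- function(H, W, C, M) {
  key <- paste("wpart", H, W, C, M, sep = "_")
  cache_get(key, function() {
    stopifnot(H %% M == 0, W %% M == 0)
    nWh <- H %/% M; nWw <- W %/% M
    nW <- nWh * nWw
    # output order: window index fastest? dims (nW, M^2, C): element (w, p, c)
    w_i <- rep(seq_len(nWh), times = nWw)   # window grid row
    w_j <- rep(seq_len(nWw), each = nWh)
    p_i <- rep(seq_len(M), times = M)       # in-window row
    p_j <- rep(seq_len(M), each = M)
    idx <- integer(nW * M * M * C)
    pos <- 0L
    for (c in seq_len(C)) {
      off_c <- (c - 1L) * H * W
      for (p in seq_len(M * M)) {
        ii <- (w_i - 1L) * M + p_i[p]
        jj <- (w_j - 1L) * M + p_j[p]
        idx[pos + seq_len(nW)] <- ii + (jj - 1L) * H + off_c
        pos <- pos + nW
      }
    }
    inv <- integer(length(idx))
    inv[idx] <- seq_along(idx)
    n <- H * W * C
    list(idx = idx, inv = inv, dim = c(nW, M * M, C), nW = nW,
         plan = gather_plan(idx, n, c(nW, M * M, C)),
         inv_plan = gather_plan(inv, n, c(H, W, C)))
  })
}

# toroidal roll of (H, W, C) tokens by (dy, dx); gather-based
cyclic_shift_idx <- function(H, W, C, dy, dx) {
  key <- paste("roll", H, W, C, dy, dx, sep = "_")
  cache_get(key, function() {
    io <- rep(seq_len(H), times = W)
    jo <- rep(seq_len(W), each = H)
    ii <- ((io - 1L - dy) %% H) + 1L
    jj <- ((jo - 1L - dx) %% W) + 1L
    base <- ii + (jj - 1L) * H
    idx <- as.integer(outer(base, (seq_len(C) - 1L) * H * W, `+`))
    gather_plan(idx, H * W * C, c(H, W, C))
  })
}

# relative-position index (M^2 x M^2) into the (2M-1)^2 bias table
relpos_index <- function(M) {
  key <- paste("relpos", M, sep = "_")
  cache_get(key, function() {
    ii <- rep(seq_len(M), times = M)
    jj <- rep(seq_len(M), each = M)
    di <- outer(ii, ii, `-`) + (M - 1L)   # 0 .. 2M-2
    dj <- outer(jj, jj, `-`) + (M - 1L)
    di * (2L * M - 1L) + dj + 1L          # 1 .. (2M-1)^2
  })
}

# additive attention mask for shifted windows: -inf (large negative) where
# a window mixes tokens from different toroidal regions
sw_attn_mask <- function(H, W, M, shift) {
  key <- paste("swmask", H, W, M, shift, sep = "_")
  cache_get(key, function() {
    # region labels in shifted coordinates: the seam introduced by the
    # toroidal roll splits the last window row/column into two groups that
    # must not attend to each other
    hs <- c(rep(1L, H - M), rep(2L, M - shift), rep(3L, shift))
    ws <- c(rep(1L, W - M), rep(2L, M - shift), rep(3L, shift))
    region <- outer(hs, ws, function(a, b) a * 4L + b)
    wp <- window_partition_idx(H, W, 1L, M)
    regw <- array(region[wp$idx], dim = wp$dim)  # (nW, M^2, 1)
    nW <- wp$nW; M2 <- M * M
    mask <- array(0, c(nW, M2, M2))
    for (w in seq_len(nW)) {
      r <- regw[w, , 1]
      mask[w, , ] <- ifelse(outer(r, r, `!=`), -1e4, 0)
    }
    mask
  })
}
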
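# Reverse-mode automatic differentiation on plain numeric arrays.
#
# Every operation builds an `ad_node` (an environment holding the forward
# value, its parents and a backward closure). `ad_backward()` topologically
# sorts the graph reachable from a scalar loss and accumulates gradients
# into the leaves. Parameters are leaves created with `ad_param()`; plain
# arrays passed to ops are treated as constants and receive no gradient.
# The graph is rebuilt on every forward pass (define-by-run), which is what
# the training loops below rely on.

.ad_env <- new.env(parent = emptyenv())
.ad_env$pass <- 0L

new_ad_node <- function(value, parents = list(), backward = NULL) {
  n <- new.env(parent = emptyenv())
  n$value <- value
  n$parents <- parents
  n$backward <- backward
  n$grad <- NULL
  n$requires_grad <- any(vapply(parents, function(p) p$requires_grad, TRUE))
  class(n) <- "ad_node"
  n
}

ad_param <- function(value) {
  n <- new_ad_node(value)
  n$requires_grad <- TRUE
  n$is_param <- TRUE
  n
}

as_ad <- function(x) {
  if (inherits(x, "ad_node")) return(x)
  n <- new_ad_node(x)
  n$requires_grad <- FALSE
  n
}

ad_value <- function(x) if (inherits(x, "ad_node")) x$value else x

# gradients of `loss` (scalar node) w.r.t. all reachable parameters
ad_backward <- function(loss) {
  topo <- vector("list", 256L); k <- 0L
  .ad_env$pass <- .ad_env$pass + 1L
  mark <- .ad_env$pass
  stack <- list(list(node = loss, stage = 1L))
  # iterative DFS post-order
  while (length(stack)) {
    top <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    nd <- top$node
    if (top$stage == 1L) {
      if (identical(nd$.visit, mark) || !nd$requires_grad) next
      nd$.visit <- mark
      stack[[length(stack) + 1L]] <- list(node = nd, stage = 2L)
      for (p in nd$parents) {
        if (p$requires_grad && !identical(p$.visit, mark)) {
          stack[[length(stack) + 1L]] <- list(node = p, stage = 1L)
        }
      }
    } else {
      k <- k + 1L
      if (k > length(topo)) topo <- c(topo, vector("list", length(topo)))
      topo[[k]] <- nd
    }
  }
  loss$grad <- array(1, dim = dim_or_len(loss$value))
  for (i in seq(k, 1L)) {
    nd <- topo[[i]]
    if (is.null(nd$backward) || is.null(nd$grad)) next
    gs <- nd$backward(nd$grad)
    for (j in seq_along(nd$parents)) {
      p <- nd$parents[[j]]
      if (!p$requires_grad || is.null(gs[[j]])) next
      p$grad <- if (is.null(p$grad)) gs[[j]] else p$grad + gs[[j]]
    }
    nd$grad <- NULL  # free intermediate gradients eagerly
  }
  invisible(loss)
}

dim_or_len <- function(x) if (is.null(dim(x))) length(x) else dim(x)

ad_zero_grad <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(params)
}

# ---- primitive ops ---------------------------------------------------------

ad_add <- function(a, b) {
  a <- as_ad(a); b <- as_ad(b)
  new_ad_node(a$value + b$value, list(a, b),
              function(g) list(g, g))
}

ad_sub <- function(a, b) {
  a <- as_ad(a); b <- as_ad(b)
  new_ad_node(a$value - b$value, list(a, b),
              function(g) list(g, -g))
}

ad_mul <- function(a, b) {
  a <- as_ad(a); b <- as_ad(b)
  av <- a$value; bv <- b$value
  new_ad_node(av * bv, list(a, b),
              function(g) list(g * bv, g * av))
}

ad_scale <- function(a, s) {
  a <- as_ad(a)
  new_ad_node(a$value * s, list(a), function(g) list(g * s))
}

ad_matmul <- function(a, b) {
  a <- as_ad(a); b <- as_ad(b)
  av <- a$value; bv <- b$value
  new_ad_node(av %*% bv, list(a, b),
              function(g) list(g %*% t(bv), crossprod(av, g)))
}

# add a bias vector over the last dimension (columns of a matrix)
ad_add_bias <- function(a, b) {
  a <- as_ad(a); b <- as_ad(b)
  av <- a$value
  stopifnot(length(dim(av)) == 2, length(b$value) == ncol(av))
  new_ad_node(sweep(av, 2, b$value, `+`), list(a, b),
              function(g) list(g, colSums(g)))
}

ad_relu <- function(a) {
  a <- as_ad(a)
  keep <- a$value > 0
  new_ad_node(a$value * keep, list(a), function(g) list(g * keep))
}

ad_lrelu <- function(a, slope = 0.2) {
  a <- as_ad(a)
  pos <- a$value > 0
  fac <- ifelse(pos, 1, slope)
  new_ad_node(a$value * fac, list(a), function(g) list(g * fac))
}

ad_tanh <- function(a) {
  a <- as_ad(a)
  y <- tanh(a$value)
  new_ad_node(y, list(a), function(g) list(g * (1 - y^2)))
}

ad_sigmoid <- function(a) {
  a <- as_ad(a)
  y <- 1 / (1 + exp(-a$value))
  new_ad_node(y, list(a), function(g) list(g * y * (1 - y)))
}

# tanh-approximation GELU
ad_gelu <- function(a) {
  a <- as_ad(a)
  x <- a$value
  c0 <- sqrt(2 / pi)
  inner <- c0 * (x + 0.044715 * x^3)
  t <- tanh(inner)
  y <- 0.5 * x * (1 + t)
  new_ad_node(y, list(a), function(g) {
    dt <- (1 - t^2) * c0 * (1 + 3 * 0.044715 * x^2)
    list(g * (0.5 * (1 + t) + 0.5 * x * dt))
  })
}

ad_log <- function(a, eps = 1e-12) {
  a <- as_ad(a)
  v <- pmax(a$value, eps)
  new_ad_node(log(v), list(a), function(g) list(g / v))
}

ad_square <- function(a) {
  a <- as_ad(a)
  new_ad_node(a$value^2, list(a), function(g) list(2 * g * a$value))
}

ad_abs <- function(a) {
  a <- as_ad(a)
  s <- sign(a$value)
  new_ad_node(abs(a$value), list(a), function(g) list(g * s))
}

ad_mean <- function(a) {
  a <- as_ad(a)
  n <- length(a$value)
  d <- dim_or_len(a$value)
  new_ad_node(mean(a$value), list(a),
              function(g) list(array(as.numeric(g) / n, d)))
}

ad_sum <- function(a) {
  a <- as_ad(a)
  d <- dim_or_len(a$value)
  new_ad_node(sum(a$value), list(a),
              function(g) list(array(as.numeric(g), d)))
}

ad_reshape <- function(a, new_dim) {
  a <- as_ad(a)
  old <- dim_or_len(a$value)
  v <- a$value; dim(v) <- new_dim
  new_ad_node(v, list(a), function(g) { dim(g) <- old; list(g) })
}

ad_aperm <- function(a, perm) {
  a <- as_ad(a)
  inv <- order(perm)
  new_ad_node(aperm(a$value, perm), list(a),
              function(g) list(aperm(g, inv)))
}

# Precomputed index plan for ad_gather: a flat index vector (0 = zero
# padding) plus the sorted scatter groups that make the backward pass a
# single cumsum-diff. Plans are built once per layer shape and cached.
gather_plan <- function(idx, n_in, out_dim) {
  idx <- as.integer(idx)
  idx_safe <- idx
  idx_safe[idx == 0L] <- n_in + 1L  # extra slot holding 0
  ord <- order(idx_safe)
  sorted <- idx_safe[ord]
  ends <- c(which(diff(sorted) != 0L), length(sorted))
  structure(list(idx_safe = idx_safe, n_in = as.integer(n_in),
                 out_dim = out_dim, ord = ord, ends = ends,
                 groups = sorted[ends]),
            class = "gather_plan")
}

# gather elements of `a` (as a flat vector) into an array; `plan` is a
# gather_plan (or a raw integer index vector with `out_dim` given, built on
# the fly). Backward scatter-adds. This is the single primitive behind
# im2col, window partition/reverse, cyclic shifts, upsampling and pixel
# shuffles.
ad_gather <- function(a, plan, out_dim = NULL) {
  a <- as_ad(a)
  av <- a$value
  if (!inherits(plan, "gather_plan")) {
    plan <- gather_plan(plan, length(av), out_dim)
  }
  in_dim <- dim_or_len(av)
  v <- c(av, 0)[plan$idx_safe]
  dim(v) <- plan$out_dim
  new_ad_node(v, list(a), function(g) {
    gs <- as.numeric(g)[plan$ord]
    cs <- cumsum(gs)
    sums <- cs[plan$ends] - c(0, cs[plan$ends[-length(plan$ends)]])
    gr <- numeric(plan$n_in + 1L)
    gr[plan$groups] <- sums
    gr <- gr[seq_len(plan$n_in)]
    dim(gr) <- in_dim
    list(gr)
  })
}

# concatenate two arrays along the last dimension
ad_concat_last <- function(a, b) {
  a <- as_ad(a); b <- as_ad(b)
  da <- dim(a$value); db <- dim(b$value)
  stopifnot(identical(da[-length(da)], db[-length(db)]))
  nd <- length(da)
  v <- array(0, c(da[-nd], da[nd] + db[nd]))
  lead <- prod(da[-nd])
  v[seq_len(lead * da[nd])] <- a$value
  v[lead * da[nd] + seq_len(lead * db[nd])] <- b$value
  new_ad_node(v, list(a, b), function(g) {
    ga <- g[seq_len(lead * da[nd])]; dim(ga) <- da
    gb <- g[lead * da[nd] + seq_len(lead * db[nd])]; dim(gb) <- db
    list(ga, gb)
  })
}

# softmax over the last dimension of a 2D or 3D array
ad_softmax_last <- function(a) {
  a <- as_ad(a)
  d <- dim_or_len(a$value)
  nlast <- d[length(d)]
  M <- matrix(a$value, ncol = nlast)
  mx <- M[cbind(seq_len(nrow(M)), max.col(M, ties.method = "first"))]
  E <- exp(M - mx)
  P <- E / rowSums(E)
  y <- array(P, d)
  new_ad_node(y, list(a), function(g) {
    G <- matrix(g, ncol = nlast)
    gx <- P * (G - rowSums(G * P))
    dim(gx) <- d
    list(gx)
  })
}

# log-softmax over rows of a matrix
ad_logsoftmax_rows <- function(a) {
  a <- as_ad(a)
  M <- a$value
  mx <- M[cbind(seq_len(nrow(M)), max.col(M, ties.method = "first"))]
  E <- exp(M - mx)
  S <- rowSums(E)
  y <- (M - mx) - log(S)
  P <- E / S
  new_ad_node(y, list(a), function(g) list(g - rowSums(g) * P))
}

# layer normalisation over the last dimension, with learnable gain/offset
ad_layernorm <- function(a, gamma, beta, eps = 1e-5) {
  a <- as_ad(a); gamma <- as_ad(gamma); beta <- as_ad(beta)
  d <- dim_or_len(a$value)
  C <- d[length(d)]
  M <- matrix(a$value, ncol = C)
  mu <- rowMeans(M)
  xc <- M - mu
  va <- rowMeans(xc^2)
  inv <- 1 / sqrt(va + eps)
  xhat <- xc * inv
  y <- sweep(sweep(xhat, 2, gamma$value, `*`), 2, beta$value, `+`)
  new_ad_node(array(y, d), list(a, gamma, beta), function(g) {
    G <- matrix(g, ncol = C)
    gy <- sweep(G, 2, gamma$value, `*`)
    gx <- inv * (gy - rowMeans(gy) - xhat * rowMeans(gy * xhat))
    dim(gx) <- d
    list(gx, colSums(G * xhat), colSums(G))
  })
}

# instance normalisation of an (H, W, C) feature map: each channel is
# normalised over its spatial extent
ad_instnorm <- function(a, gamma, beta, eps = 1e-5) {
  a <- as_ad(a); gamma <- as_ad(gamma); beta <- as_ad(beta)
  d <- dim(a$value)
  HW <- d[1] * d[2]; C <- d[3]
  M <- matrix(a$value, nrow = HW)         # columns are channels
  mu <- colMeans(M)
  xc <- sweep(M, 2, mu)
  va <- colMeans(xc^2)
  inv <- 1 / sqrt(va + eps)
  xhat <- sweep(xc, 2, inv, `*`)
  y <- sweep(sweep(xhat, 2, gamma$value, `*`), 2, beta$value, `+`)
  new_ad_node(array(y, d), list(a, gamma, beta), function(g) {
    G <- matrix(g, nrow = HW)
    gy <- sweep(G, 2, gamma$value, `*`)
    gx <- sweep(gy - matrix(colMeans(gy), HW, C, byrow = TRUE) -
                  xhat * matrix(colMeans(gy * xhat), HW, C, byrow = TRUE),
                2, inv, `*`)
    dim(gx) <- d
    list(gx, colSums(G * xhat), colSums(G))
  })
}

# L2-normalise rows of a matrix to the unit sphere
ad_l2norm_rows <- function(a, eps = 1e-10) {
  a <- as_ad(a)
  M <- a$value
  nrm <- sqrt(rowSums(M^2)) + eps
  y <- M / nrm
  new_ad_node(y, list(a), function(g) {
    list((g - y * rowSums(g * y)) / nrm)
  })
}

# batched matrix multiply: (B, m, k) x (B, k, n) -> (B, m, n), vectorised
# over the batch by looping over the small contraction/output dims only
bmm_raw <- function(av, bv) {
  da <- dim(av); db <- dim(bv)
  B <- da[1]; m <- da[2]; K <- da[3]; n <- db[3]
  v <- array(0, c(B, m, n))
  for (j in seq_len(n)) {
    acc <- matrix(0, B, m)
    for (k in seq_len(K)) acc <- acc + av[, , k] * bv[, k, j]
    v[, , j] <- acc
  }
  v
}

ad_bmm <- function(a, b) {
  a <- as_ad(a); b <- as_ad(b)
  av <- a$value; bv <- b$value
  da <- dim(av); db <- dim(bv)
  stopifnot(length(da) == 3, length(db) == 3, da[1] == db[1], da[3] == db[2])
  new_ad_node(bmm_raw(av, bv), list(a, b), function(g) {
    m <- da[2]; K <- da[3]; n <- db[3]; B <- da[1]
    # dA[b,i,k] = sum_j G[b,i,j] B[b,k,j]; dB[b,k,j] = sum_i A[b,i,k] G[b,i,j]
    ga <- array(0, da); gb <- array(0, db)
    for (k in seq_len(K)) {
      acc <- matrix(0, B, m)
      for (j in seq_len(n)) acc <- acc + g[, , j] * bv[, k, j]
      ga[, , k] <- acc
      Ak <- av[, , k, drop = FALSE]; dim(Ak) <- c(B, m)
      for (j in seq_len(n)) gb[, k, j] <- rowSums(Ak * g[, , j])
    }
    list(ga, gb)
  })
}

# replicate an array along a new leading dimension (entries vary slowest):
# used to broadcast the relative-position bias over windows
ad_rep_lead <- function(a, times) {
  a <- as_ad(a)
  d <- dim_or_len(a$value)
  v <- rep(as.numeric(a$value), each = times)
  dim(v) <- c(times, d)
  new_ad_node(v, list(a), function(g) {
    gm <- matrix(g, nrow = times)
    gs <- colSums(gm)
    dim(gs) <- d
    list(gs)
  })
}

# ---- optimiser -------------------------------------------------------------

# Adam update over a list of ad_param nodes; state is kept on the nodes
adam_step <- function(params, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (p in params) {
    if (is.null(p$grad)) next
    if (is.null(p$adam_m)) {
      p$adam_m <- p$grad * 0
      p$adam_v <- p$grad * 0
      p$adam_t <- 0L
    }
    p$adam_t <- p$adam_t + 1L
    p$adam_m <- beta1 * p$adam_m + (1 - beta1) * p$grad
    p$adam_v <- beta2 * p$adam_v + (1 - beta2) * p$grad^2
    mhat <- p$adam_m / (1 - beta1^p$adam_t)
    vhat <- p$adam_v / (1 - beta2^p$adam_t)
    p$value <- p$value - lr * mhat / (sqrt(vhat) + eps)
  }
  invisible(params)
}

# flat list of ad_param nodes from a nested parameter structure
collect_params <- function(x) {
  if (inherits(x, "ad_node")) return(if (isTRUE(x$is_param)) list(x) else list())
  if (is.list(x)) return(do.call(c, lapply(x, collect_params)))
  list()
}

# total number of scalar parameters
count_params <- function(x) {
  sum(vapply(collect_params(x), function(p) length(p$value), 0))
}

# snapshot / restore parameter values (checkpointing)
params_state <- function(x) lapply(collect_params(x), function(p) p$value)

restore_params <- function(x, state) {
  ps <- collect_params(x)
  stopifnot(length(ps) == length(state))
  for (i in seq_along(ps)) ps[[i]]$value <- state[[i]]
  invisible(x)
}
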
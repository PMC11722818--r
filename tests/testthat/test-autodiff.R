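# finite-difference verification of the reverse-mode engine

num_grad <- function(f, x, eps = 1e-5) {
  g <- x * 0
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

expect_gradient <- function(make_loss, x0, tol = 1e-5) {
  p <- priorfov:::ad_param(x0)
  loss <- make_loss(p)
  priorfov:::ad_backward(loss)
  ga <- p$grad
  gn <- num_grad(function(x) {
    priorfov:::ad_value(make_loss(priorfov:::ad_param(x)))
  }, x0)
  expect_lt(max(abs(ga - gn)) / max(1e-8, max(abs(gn))), tol)
}

test_that("gradients of dense, activation and loss ops match finite differences", {
  pf <- asNamespace("priorfov")
  set.seed(1)
  m1 <- matrix(rnorm(12), 3, 4)
  m2 <- matrix(rnorm(20), 4, 5)
  b5 <- rnorm(5)
  expect_gradient(function(p) {
    pf$ad_mean(pf$ad_relu(pf$ad_add_bias(pf$ad_matmul(p, m2), b5)))
  }, m1)
  expect_gradient(function(p) pf$ad_mean(pf$ad_square(pf$ad_tanh(p))), m1)
  expect_gradient(function(p) pf$ad_mean(pf$ad_gelu(p)), m1)
  expect_gradient(function(p) pf$ad_mean(pf$ad_log(pf$ad_sigmoid(p))), m1)
  expect_gradient(function(p) pf$ad_mean(pf$ad_abs(p)), m1 + 0.3)
  cs <- matrix(runif(12), 3, 4)
  expect_gradient(function(p) {
    pf$ad_mean(pf$ad_mul(pf$ad_logsoftmax_rows(p), cs))
  }, m1)
  cs3 <- array(rnorm(12) + 2, c(2, 2, 3))
  expect_gradient(function(p) {
    pf$ad_mean(pf$ad_mul(pf$ad_softmax_last(pf$ad_reshape(p, c(2, 2, 3))), cs3))
  }, array(rnorm(12), c(2, 2, 3)))
  csn <- matrix(rnorm(12), 3, 4)
  expect_gradient(function(p) pf$ad_mean(pf$ad_mul(pf$ad_l2norm_rows(p), csn)), m1)
})

test_that("gradients of normalisation, attention and structural ops match", {
  pf <- asNamespace("priorfov")
  set.seed(2)
  m1 <- matrix(rnorm(12), 3, 4)
  g0 <- rnorm(4); b0 <- rnorm(4)
  expect_gradient(function(p) pf$ad_mean(pf$ad_square(pf$ad_layernorm(p, g0, b0))), m1)
  expect_gradient(function(p) pf$ad_mean(pf$ad_square(pf$ad_layernorm(m1, p, b0))), g0)
  x3 <- array(rnorm(24), c(2, 3, 4))
  expect_gradient(function(p) pf$ad_mean(pf$ad_square(pf$ad_instnorm(p, g0, b0))), x3,
                  tol = 1e-4)
  a3 <- array(rnorm(24), c(2, 3, 4)); b3 <- array(rnorm(40), c(2, 4, 5))
  expect_gradient(function(p) pf$ad_mean(pf$ad_square(pf$ad_bmm(p, b3))), a3)
  expect_gradient(function(p) pf$ad_mean(pf$ad_square(pf$ad_bmm(a3, p))), b3)
  rl <- array(rnorm(18), c(3, 2, 3))
  expect_gradient(function(p) pf$ad_mean(pf$ad_mul(pf$ad_rep_lead(p, 3), rl)),
                  matrix(rnorm(6), 2, 3))
  cc <- array(rnorm(6), c(3, 2))
  expect_gradient(function(p) pf$ad_mean(pf$ad_square(pf$ad_concat_last(p, cc))),
                  matrix(rnorm(9), 3, 3))
})

test_that("convolution and upsampling gradients match finite differences", {
  pf <- asNamespace("priorfov")
  set.seed(3)
  x <- array(rnorm(6 * 6 * 2), c(6, 6, 2))
  ly <- pf$init_conv(3, 2, 4)
  expect_gradient(function(p) {
    pf$ad_mean(pf$ad_square(pf$conv2d(p, ly, 3, stride = 2, pad = 1)))
  }, x)
  w0 <- pf$ad_value(ly$w)
  expect_gradient(function(p) {
    l2 <- list(w = p, b = ly$b)
    pf$ad_mean(pf$ad_square(pf$conv2d(pf$as_ad(x), l2, 3, stride = 2, pad = 1)))
  }, w0)
  expect_gradient(function(p) pf$ad_mean(pf$ad_square(pf$upsample_nn2(p))), x)
})

test_that("Adam descends a quadratic and training state round-trips", {
  pf <- asNamespace("priorfov")
  set.seed(4)
  target <- matrix(rnorm(6), 2, 3)
  p <- pf$ad_param(matrix(0, 2, 3))
  for (i in 1:400) {
    loss <- pf$ad_mean(pf$ad_square(pf$ad_sub(p, target)))
    pf$ad_backward(loss)
    pf$adam_step(list(p), 0.05)
    pf$ad_zero_grad(list(p))
  }
  expect_lt(max(abs(p$value - target)), 0.02)
  st <- pf$params_state(list(p))
  p$value[] <- 0
  pf$restore_params(list(p), st)
  expect_equal(p$value, st[[1]])
})
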
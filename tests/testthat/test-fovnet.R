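test_that("patch embedding produces the stated token grids", {
  m <- fovnet_init(swin_config("desk"), seed = 2)
  tok <- patch_embed(array(rnorm(96 * 96 * 2), c(96, 96, 2)), m)
  expect_equal(dim(tok), c(24, 24, 24))
  expect_error(patch_embed(array(0, c(94, 94, 2)), m), "divisible")
  # zero input: every token is the embedding bias (after the layer norm all
  # tokens are identical)
  tok0 <- patch_embed(array(0, c(96, 96, 2)), m)
  expect_lt(max(abs(sweep(matrix(tok0, 576, 24), 2,
                          matrix(tok0, 576, 24)[1, ]))), 1e-9)
  # full-scale config: 512 x 512 x 2 -> 128 x 128 x 48
  mF <- fovnet_init(swin_config("full"), seed = 2)
  tokF <- patch_embed(array(rnorm(512 * 512 * 2), c(512, 512, 2)), mF)
  expect_equal(dim(tokF), c(128, 128, 48))
})

test_that("window partition / reverse and cyclic shifts are exact bijections", {
  set.seed(3)
  tok <- array(rnorm(24 * 24 * 5), c(24, 24, 5))
  w <- window_partition(tok, 4)
  expect_equal(dim(w), c(36, 16, 5))
  expect_identical(window_reverse(w, 4, 24, 24), tok)
  # one window when the grid equals the window
  tok8 <- array(rnorm(8 * 8 * 3), c(8, 8, 3))
  expect_equal(dim(window_partition(tok8, 8))[1], 1)
  # 128 grid with window 8 -> 256 windows
  big <- array(0, c(128, 128, 1))
  expect_equal(dim(window_partition(big, 8))[1], 256)
  expect_identical(cyclic_shift(cyclic_shift(tok, -2), 2), tok)
  expect_identical(cyclic_shift(tok, 0), tok)
  # shift moves content toroidally
  expect_equal(cyclic_shift(tok, 3)[4, 4, ], tok[1, 1, ])
})

test_that("window attention is row-stochastic with the right limits", {
  set.seed(5)
  Q <- matrix(rnorm(16 * 8), 16); K <- matrix(rnorm(16 * 8), 16)
  V <- matrix(rnorm(16 * 8), 16); B <- matrix(rnorm(256), 16, 16)
  at <- window_attention(Q, K, V, B)
  expect_true(all(abs(rowSums(at$attention) - 1) < 1e-6))
  # zero queries and bias -> uniform attention, rows average V
  u <- window_attention(matrix(0, 16, 8), K, V)
  expect_equal(u$output[3, ], colMeans(V), tolerance = 1e-9)
  # a dominant logit makes the output copy the corresponding value row
  B1 <- matrix(0, 16, 16); B1[, 7] <- 60
  dom <- window_attention(matrix(0, 16, 8), K, V, B1)
  expect_equal(dom$output[1, ], V[7, ], tolerance = 1e-9)
  expect_error(window_attention(Q, K[1:8, ], V))
})

test_that("Swin block pairs preserve shape and reduce to the identity", {
  cfg <- swin_config("desk")
  m <- fovnet_init(cfg, seed = 4)
  tok <- array(rnorm(24 * 24 * 24), c(24, 24, 24))
  out <- swin_block_pair(tok, m, level = 1, pair = 1)
  expect_equal(dim(out), dim(tok))
  expect_true(all(is.finite(out)))
  # zeroing the attention projection and MLP second layer leaves the
  # residual path only: the pair becomes the identity
  m0 <- fovnet_init(cfg, seed = 4)
  for (b in m0$net$enc[[1]]) {
    b$proj$w$value[] <- 0; b$proj$b$value[] <- 0
    b$fc2$w$value[] <- 0; b$fc2$b$value[] <- 0
  }
  out0 <- swin_block_pair(tok, m0, level = 1, pair = 1)
  expect_equal(out0, tok, tolerance = 1e-12)
})

test_that("masked shifted-window attention equals plain attention on constants", {
  pf <- asNamespace("priorfov")
  cfg <- swin_config("desk")
  m <- fovnet_init(cfg, seed = 6)
  tok <- array(0.777, c(24, 24, 24))
  blk <- m$net$enc[[1]][[1]]
  y_w <- pf$ad_value(pf$swin_block_node(pf$as_ad(tok), blk, 3, 4, 0, cfg))
  y_sw <- pf$ad_value(pf$swin_block_node(pf$as_ad(tok), blk, 3, 4, 2, cfg))
  expect_lt(max(abs(y_w - y_sw)), 1e-5)
})

test_that("patch merge and expand perform the stated shape transforms", {
  m <- fovnet_init(swin_config("desk"), seed = 2)
  tok <- array(rnorm(24 * 24 * 24), c(24, 24, 24))
  mg <- patch_merge(tok, m, 1)
  expect_equal(dim(mg), c(12, 12, 48))
  ex <- patch_expand(array(rnorm(12 * 12 * 48), c(12, 12, 48)), m, 1)
  expect_equal(dim(ex), c(24, 24, 24))
  mF <- fovnet_init(swin_config("full"), seed = 2)
  tokF <- array(rnorm(128 * 128 * 48), c(128, 128, 48))
  expect_equal(dim(patch_merge(tokF, mF, 1)), c(64, 64, 96))
})

test_that("the forward pass is shape-preserving, deterministic, and the
          zero-initialised head reproduces the pre-corrected input", {
  m <- fovnet_init(swin_config("desk"), seed = 8)
  ph <- small_phantom(17)
  prior <- ph$kv
  out <- fovnet_forward(ph$mv, prior, m)
  expect_identical(dim(out$values), dim(ph$mv$values))
  out2 <- fovnet_forward(ph$mv, prior, m)
  expect_identical(out$values, out2$values)
  # architectural probe: zeroing the final linear layer makes the network
  # the identity on its skip-fed pre-corrected input
  m0 <- fovnet_init(swin_config("desk"), seed = 8)
  m0$net$out$w$value[] <- 0
  m0$net$out$b$value[] <- 0
  probe <- fovnet_forward(ph$mv, prior, m0)
  expect_lt(max(abs(probe$values - ph$mv$values)), 1e-9)
  expect_error(fovnet_forward(ph$mv, image_grid(matrix(0, 48, 48), 4), m))
})

test_that("reconstruction loss is the mean absolute difference", {
  x <- matrix(c(1, 2, 3, 4), 2)
  expect_equal(reconstruction_loss(x, x), 0)
  expect_equal(reconstruction_loss(x + 7, x), 7)
  set.seed(2)
  a <- matrix(rnorm(36), 6); b <- matrix(rnorm(36), 6)
  expect_equal(reconstruction_loss(a, b), mae(a, b))
})

test_that("short supervised training reduces the L1 loss and can resume", {
  set.seed(3)
  cfg <- swin_config("desk", n_steps = 30)
  phs <- lapply(1:4, function(i) make_phantom(random_phantom_spec(i)))
  trips <- lapply(phs, function(ph) {
    noisy <- ph$mv$values + matrix(rnorm(96 * 96, 0, 150), 96)
    list(i_prec = noisy, i_smv = ph$mv$values, gt = ph$mv$values)
  })
  expect_error(train_fovnet(list(), cfg), "empty")
  m <- train_fovnet(trips, cfg, seed = 4)
  expect_true(m$trained)
  first <- mean(m$loss_log$loss_l1[1:8])
  last <- mean(m$loss_log$loss_l1[23:30])
  expect_lt(last, first)
  # checkpoint round trip reproduces predictions
  p <- tempfile(fileext = ".rds")
  save_checkpoint(m, p)
  m2 <- load_checkpoint(p)
  pr <- image_grid(trips[[1]]$i_prec, 4)
  sm <- image_grid(trips[[1]]$i_smv, 4, modality = "sMV")
  expect_equal(fovnet_forward(pr, sm, m2)$values,
               fovnet_forward(pr, sm, m)$values, tolerance = 1e-12)
  unlink(p)
})

test_that("parameter counts scale with the configuration", {
  n_desk <- model_param_count(swin_config("desk"))
  expect_gt(n_desk, 1e4)
  n_tn <- model_param_count(transnet_config("desk"))
  expect_gt(n_tn, n_desk / 100)
})
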
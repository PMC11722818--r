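test_that("generator preserves shape, is deterministic and finite", {
  m <- transnet_init(transnet_config("desk"), seed = 3)
  ph <- small_phantom(4)
  out1 <- generator_forward(ph$kv, m)
  out2 <- generator_forward(ph$kv, m)
  expect_identical(dim(out1$values), dim(ph$kv$values))
  expect_identical(out1$values, out2$values)
  expect_true(all(is.finite(out1$values)))
  zero <- generator_forward(image_grid(matrix(0, 32, 32), 4), m)
  expect_true(all(is.finite(zero$values)))
  expect_error(generator_forward(image_grid(matrix(0, 33, 33), 4), m),
               "divisible")
})

test_that("encoder feature stacks have the declared layers and scales", {
  m <- transnet_init(transnet_config("desk"), seed = 3)
  ph <- small_phantom(4)
  fe <- encoder_features(ph$kv, m)
  expect_named(fe, paste0("tap", c(0, 1, 2, 3, 4)))
  dims <- vapply(fe, function(a) dim(a)[1], 0)
  expect_equal(unname(dims), c(96, 96, 48, 24, 24))
  fe2 <- encoder_features(ph$kv, m)
  expect_identical(fe, fe2)
  expect_error(encoder_features(ph$kv, m, selected_layers = 9), "invalid layer")
})

test_that("NCE sampling returns unit vectors at aligned positions", {
  m <- transnet_init(transnet_config("desk"), seed = 3)
  ph <- small_phantom(4)
  st_in <- encoder_features(ph$kv, m)
  st_out <- encoder_features(generator_forward(ph$kv, m), m)
  ncfg <- list(n_positions = 16, n_negatives = 8, tau = 0.07)
  vs <- sample_nce_vectors(st_in, st_out, ncfg, seed = 5, heads = m$H)
  for (layer in vs) {
    expect_equal(dim(layer$v), c(16, 64))
    expect_equal(dim(layer$v_negs), c(16, 8, 64))
    expect_true(all(abs(rowSums(layer$v^2) - 1) < 1e-6))
    expect_true(all(abs(rowSums(layer$v_pos^2) - 1) < 1e-6))
    expect_true(all(abs(apply(layer$v_negs, 1:2, function(z) sum(z^2)) - 1) < 1e-6))
  }
  vs2 <- sample_nce_vectors(st_in, st_out, ncfg, seed = 5, heads = m$H)
  expect_identical(vs, vs2)
  # when the input equals itself, positives are identical to queries
  vs_id <- sample_nce_vectors(st_in, st_in, ncfg, seed = 5, heads = m$H)
  expect_equal(vs_id$tap0$v, vs_id$tap0$v_pos)
  expect_error(sample_nce_vectors(st_in, st_out,
                                  list(n_positions = 4, n_negatives = 1e6),
                                  1, m$H),
               "exceeds")
})

test_that("the contrastive term matches its closed-form special cases", {
  v <- c(1, 0, 0)
  expect_equal(patch_nce_term(v, v, NULL, tau = 1), 0)
  # uniform logits over N+1 classes -> log(N+1)
  negs <- matrix(rep(v, 3), 3, byrow = TRUE)
  expect_equal(patch_nce_term(v, v, negs, tau = 1), log(4), tolerance = 1e-12)
  # one orthogonal negative at tau = 1
  expect_equal(patch_nce_term(c(1, 0, 0), c(1, 0, 0), matrix(c(0, 1, 0), 1),
                              tau = 1),
               -log(exp(1) / (exp(1) + 1)), tolerance = 1e-12)
  expect_error(patch_nce_term(v, v, NULL, tau = 0), "positive")
})

test_that("the term matches a brute-force softmax cross-entropy on random vectors", {
  set.seed(9)
  for (i in 1:25) {
    K <- sample(4:16, 1); N <- sample(1:8, 1); tau <- runif(1, 0.05, 1)
    unit <- function(z) z / sqrt(sum(z^2))
    v <- unit(rnorm(K)); vp <- unit(rnorm(K))
    vn <- t(apply(matrix(rnorm(N * K), N), 1, unit))
    logits <- c(sum(v * vp), as.numeric(vn %*% v)) / tau
    brute <- -log(exp(logits[1]) / sum(exp(logits)))
    expect_equal(patch_nce_term(v, vp, vn, tau), brute, tolerance = 1e-6)
  }
})

test_that("the batched training NCE agrees with the per-term evaluation", {
  pf <- asNamespace("priorfov")
  set.seed(12)
  S <- 6; C <- 5; tau <- 0.07
  q <- matrix(rnorm(S * C), S); k <- matrix(rnorm(S * C), S)
  head <- list(l1 = pf$init_linear(C, 8), l2 = pf$init_linear(8, 8))
  node <- pf$nce_layer_loss_node(pf$as_ad(q), pf$as_ad(k), head, tau)
  # reference: project + normalise each row, then average patch_nce_term
  proj <- function(M) {
    M1 <- pmax(M %*% pf$ad_value(head$l1$w) +
                 matrix(pf$ad_value(head$l1$b), S, 8, byrow = TRUE), 0)
    M2 <- M1 %*% pf$ad_value(head$l2$w) +
      matrix(pf$ad_value(head$l2$b), S, 8, byrow = TRUE)
    M2 / sqrt(rowSums(M2^2))
  }
  qn <- proj(q); kn <- proj(k)
  terms <- vapply(seq_len(S), function(s) {
    patch_nce_term(qn[s, ], kn[s, ], kn[-s, , drop = FALSE], tau)
  }, 0)
  expect_equal(pf$ad_value(node), mean(terms), tolerance = 1e-8)
})

test_that("PatchNCE losses aggregate terms and stay non-negative", {
  m <- transnet_init(transnet_config("desk",
                                     nce = list(tau = 0.07, n_positions = 8,
                                                n_negatives = 7,
                                                selected_layers = c(0, 2),
                                                mlp_dim = 16)),
                     seed = 3)
  ph <- small_phantom(4)
  l_x <- patch_nce_loss(m, ph$kv, seed = 2)
  l_y <- identity_nce_loss(m, ph$mv, seed = 2)
  expect_gte(l_x, 0); expect_gte(l_y, 0)
})

test_that("adversarial objective reproduces printed values", {
  # D == 0.5 everywhere: objective = log .5 + log .5
  half <- matrix(0.5, 3, 3)
  v <- adversarial_loss(half, half, "vanilla")
  expect_equal(v$objective, 2 * log(0.5), tolerance = 1e-12)
  # perfect discriminator: objective -> 0 from below
  p <- adversarial_loss(matrix(1, 2, 2), matrix(0, 2, 2), "vanilla")
  expect_gt(p$objective, -1e-6)
  expect_lte(p$objective, 0)
  # lsgan at D == 0.5: each squared term is 0.25
  l <- adversarial_loss(half, half, "lsgan")
  expect_equal(l$loss_d, 0.25)
  expect_equal(l$loss_g, 0.25)
  expect_error(adversarial_loss(half, half, "wgan"))
})

test_that("the total loss is the unit-weighted sum with linear overrides", {
  expect_equal(transnet_total_loss(0, 0, 0), 0)
  expect_equal(transnet_total_loss(1.5, 2.5, 3.5), 7.5)
  expect_equal(transnet_total_loss(1.5, 2.5, 3.5, weights = c(2, 1, 0)), 5.5)
})

test_that("a short training run reduces losses and round-trips checkpoints", {
  set.seed(1)
  phs <- lapply(1:6, function(i) make_phantom(random_phantom_spec(i)))
  kv <- lapply(phs, function(p) p$kv$values)
  mv <- lapply(phs, function(p) p$mv$values)
  cfg <- transnet_config("desk", base_channels = 8, n_resnet_blocks = 2,
                         crop_size = 48, n_steps = 40,
                         nce = list(tau = 0.07, n_positions = 32,
                                    n_negatives = 31,
                                    selected_layers = c(0, 2, 3),
                                    mlp_dim = 32))
  m <- train_transnet(kv, mv, cfg, seed = 5)
  expect_true(m$trained)
  expect_equal(nrow(m$loss_log), 40)
  first <- mean(m$loss_log$loss_g[1:10])
  last <- mean(m$loss_log$loss_g[31:40])
  expect_lt(last, first)
  p <- tempfile(fileext = ".rds")
  save_checkpoint(m, p)
  m2 <- load_checkpoint(p)
  ph <- small_phantom(30)
  expect_equal(synthesize_mvct(ph$kv, m2)$values,
               synthesize_mvct(ph$kv, m)$values, tolerance = 1e-12)
  expect_equal(m2$step, m$step)
  unlink(p)
  expect_warning(synthesize_mvct(ph$kv, transnet_init(cfg, 1)), "not been trained")
})
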
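make_config <- function(n = 4, scales = c(0.5, 1.5), layers = 1) {
  aghn_config(scales = scales, n_layers = layers, n_regions = n)
}

test_that("GraphHeat layer composes weight, kernel and tanh", {
  k <- diag(3)
  expect_equal(ghn_forward(k, matrix(0, 3, 3)), matrix(0, 3, 3))
  expect_equal(ghn_forward(diag(3), diag(3), diag(3)),
               diag(tanh(1), 3))

  set.seed(4)
  w <- matrix(rnorm(16), 4, 4)
  h <- heat_kernel(spectral_decompose(build_laplacian(random_sc(4, seed = 8))), 1)
  x <- matrix(rnorm(16), 4, 4)
  expect_equal(ghn_forward(h, w, x),
               tanh(matmul_oracle(w, matmul_oracle(h, x))),
               tolerance = 1e-12)
  expect_error(ghn_forward(h, matrix(0, 3, 3)), "match")
})

test_that("attention scores are vec dot-products with softmax normalization", {
  psi <- list(matrix(1:4 / 10, 2), matrix(4:1 / 10, 2))
  zero <- compute_attention(psi, rep(0, 4))
  expect_equal(zero$raw_alpha, c(0, 0))
  expect_equal(zero$attention_probs, c(0.5, 0.5))

  one <- compute_attention(psi[1], runif(4))
  expect_equal(one$attention_probs, 1)

  same <- compute_attention(list(psi[[1]], psi[[1]], psi[[1]]), rnorm(4))
  expect_equal(same$attention_probs, rep(1 / 3, 3), tolerance = 1e-12)

  # raw scores (ln 3, 0) give probabilities (0.75, 0.25)
  psi2 <- list(matrix(c(log(3), 0, 0, 0), 2), matrix(0, 2, 2))
  att <- compute_attention(psi2, c(1, 0, 0, 0))
  expect_equal(att$attention_probs, c(0.75, 0.25), tolerance = 1e-12)

  expect_error(compute_attention(psi, rep(0, 5)), "length")
})

test_that("attention flattening is row-major", {
  # an asymmetric Psi paired with a one-hot weight vector distinguishes
  # row-major from column-major flattening
  psi <- matrix(c(0, 10, 20, 0), 2)   # column-major: psi[2,1]=10, psi[1,2]=20
  w <- c(0, 1, 0, 0)                  # selects position 2 of the flattening
  att <- compute_attention(list(psi, matrix(0, 2, 2)), w)
  expect_equal(att$raw_alpha[1], psi[1, 2])   # row-major picks row 1, col 2
})

test_that("fusion is a symmetrized convex combination", {
  s <- matrix(c(0.1, 0.4, 0.2, 0.3), 2)
  expect_equal(fuse_outputs(list(s, s), c(0.3, 0.7)), (s + t(s)) / 2)
  a <- matrix(runif(9), 3)
  b <- matrix(runif(9), 3)
  expect_equal(fuse_outputs(list(a, b), c(1, 0)), (a + t(a)) / 2)

  mix <- 0.3 * a + 0.7 * b
  expect_equal(fuse_outputs(list(a, b), c(0.3, 0.7)),
               (mix + t(mix)) / 2, tolerance = 1e-14)
  expect_error(fuse_outputs(list(a, b), c(0.6, 0.6)), "sum to 1")
})

test_that("forward pass yields symmetric bounded predictions with simplex attention", {
  cfg <- make_config(6, c(0.6, 2, 6))
  sc <- random_sc(6, seed = 31)
  params <- aghn_init(cfg, seed = 2)
  pred <- aghn_forward(sc, params, cfg)
  expect_s3_class(pred, "aghn_prediction")
  expect_equal(pred$fc_pred, t(pred$fc_pred))
  expect_true(all(abs(pred$fc_pred) < 1))
  expect_equal(sum(pred$attention_probs), 1, tolerance = 1e-10)
  expect_true(all(pred$attention_probs > 0 & pred$attention_probs < 1))
  expect_equal(pred$attention_probs, softmax_ref(pred$raw_alpha))

  zero_params <- params
  zero_params$scale_weights <- lapply(zero_params$scale_weights, function(l) {
    lapply(l, function(w) w * 0)
  })
  pz <- aghn_forward(sc, zero_params, cfg)
  expect_equal(pz$fc_pred, matrix(0, 6, 6))
  expect_equal(pz$attention_probs, rep(1 / 3, 3))
})

test_that("forward pass is deterministic outside training mode", {
  cfg <- make_config(5, c(0.8, 2))
  sc <- random_sc(5, seed = 44)
  params <- aghn_init(cfg, seed = 9)
  p1 <- aghn_forward(sc, params, cfg)
  p2 <- aghn_forward(sc, params, cfg)
  expect_identical(p1$fc_pred, p2$fc_pred)
  expect_identical(p1$attention_probs, p2$attention_probs)
})

test_that("M-GHN fuses uniformly and ignores the attention weights", {
  cfg <- make_config(5, c(0.8, 2, 5))
  sc <- random_sc(5, seed = 3)
  params <- aghn_init(cfg, seed = 1)
  p1 <- aghn_forward(sc, params, cfg, variant = "m_ghn")
  expect_equal(p1$attention_probs, rep(1 / 3, 3))
  params2 <- params
  set.seed(99)
  params2$attention_weights <- rnorm(25)
  p2 <- aghn_forward(sc, params2, cfg, variant = "m_ghn")
  expect_identical(p1$fc_pred, p2$fc_pred)
})

test_that("model is equivariant to node relabeling", {
  for (seed in 1:3) {
    n <- 5
    cfg <- make_config(n, c(0.7, 3), layers = 2)
    sc <- random_sc(n, seed = 200 + seed)
    params <- aghn_init(cfg, seed = seed)
    perm <- sample(n)
    p <- diag(n)[perm, ]
    sc_p <- p %*% sc %*% t(p)
    params_p <- params
    params_p$scale_weights <- lapply(params$scale_weights, function(l) {
      lapply(l, function(w) p %*% w %*% t(p))
    })
    wmat <- matrix(params$attention_weights, n, n, byrow = TRUE)
    params_p$attention_weights <- as.vector(t(p %*% wmat %*% t(p)))
    pred <- aghn_forward(sc, params, cfg)
    pred_p <- aghn_forward(sc_p, params_p, cfg)
    expect_equal(pred_p$fc_pred, p %*% pred$fc_pred %*% t(p),
                 tolerance = 1e-10)
    expect_equal(pred_p$attention_probs, pred$attention_probs,
                 tolerance = 1e-10)
  }
})

test_that("parameter count matches the formula and the instantiated model", {
  expect_identical(count_parameters(aghn_config(n_regions = 87)), 60552L)
  expect_identical(count_parameters(aghn_config(scales = 1, n_regions = 2)), 8L)
  expect_equal(count_parameters(aghn_config(n_regions = 86)),
               7 * 86^2 + 86^2)

  set.seed(77)
  for (i in 1:10) {
    cfg <- aghn_config(scales = sort(runif(sample(1:5, 1), 0.1, 9)),
                       n_layers = sample(1:4, 1),
                       n_regions = sample(2:12, 1))
    params <- aghn_init(cfg)
    flat_len <- length(unlist(params$scale_weights)) +
      length(params$attention_weights)
    expect_identical(count_parameters(cfg), as.integer(flat_len))
  }
})

test_that("checkpoints round-trip bitwise", {
  cfg <- make_config(4)
  params <- aghn_init(cfg, seed = 5)
  path <- tempfile(fileext = ".rds")
  save_checkpoint(params, cfg, path, seed = 5L)
  ck <- load_checkpoint(path)
  expect_identical(ck$params, params)
  expect_identical(ck$config, cfg)
  expect_identical(ck$seed, 5L)
  expect_error(load_checkpoint({
    p2 <- tempfile(fileext = ".rds"); saveRDS(list(a = 1), p2); p2
  }), "checkpoint")
})
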
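# Small cohorts used across training tests.
tiny_cohort <- function(n = 6, subjects = 8, seed = 1, fc_maker = NULL) {
  set.seed(seed)
  pairs <- lapply(seq_len(subjects), function(k) {
    sc <- connectivity_matrix(random_sc(n, seed = seed * 100 + k), "structural")
    fc <- if (is.null(fc_maker)) {
      f <- matrix(runif(n * n, -0.3, 0.3), n, n)
      f <- (f + t(f)) / 2
      diag(f) <- 1
      connectivity_matrix(f, "functional")
    } else {
      fc_maker(sc, k)
    }
    list(sc = sc, fc = fc, id = sprintf("sub-%03d", k))
  })
  make_cohort(pairs, rep(c("train", "val", "test"), c(subjects - 3, 1, 2)))
}

test_that("loss is the per-entry squared Frobenius difference", {
  a <- matrix(runif(9), 3)
  expect_equal(aghn_loss(a, a), 0)
  expect_equal(aghn_loss(matrix(1, 2, 2), matrix(0, 2, 2)), 1)

  b <- matrix(runif(9), 3)
  manual <- 0
  for (i in 1:3) for (j in 1:3) manual <- manual + (a[i, j] - b[i, j])^2
  expect_equal(aghn_loss(a, b), manual / 9, tolerance = 1e-12)
  expect_error(aghn_loss(a, matrix(0, 2, 2)), "mismatch")
})

test_that("analytic gradients agree with finite differences", {
  n <- 4
  sc <- random_sc(n, seed = 61)
  fc <- matrix(runif(n * n, -0.5, 0.5), n, n)
  fc <- (fc + t(fc)) / 2
  diag(fc) <- 1
  for (case in list(list(v = "aghn", layers = 1, excl = FALSE),
                    list(v = "aghn", layers = 2, excl = TRUE),
                    list(v = "m_ghn", layers = 1, excl = FALSE))) {
    cfg <- aghn_config(scales = c(0.5, 1.5), n_layers = case$layers,
                       n_regions = n)
    bank <- build_kernel_bank(sc, cfg$scales)
    params <- aghn_init(cfg, seed = 3)
    fp <- aghn:::.forward_pass(bank, params, cfg, case$v)
    bp <- aghn:::.backward_pass(fp, fc, bank, params, cfg, case$v,
                                exclude_diagonal = case$excl)
    theta <- aghn:::flatten_params(params)
    denom <- if (case$excl) n * n - n else n * n
    lossf <- function(t) {
      p <- aghn:::unflatten_params(t, cfg)
      f <- aghn:::.forward_pass(bank, p, cfg, case$v)
      r <- f$fc_pred - fc
      if (case$excl) diag(r) <- 0
      sum(r * r) / denom
    }
    eps <- 1e-6
    probe <- seq(1, length(theta), length.out = 25)
    for (j in round(probe)) {
      tp <- theta; tp[j] <- tp[j] + eps
      tm <- theta; tm[j] <- tm[j] - eps
      expect_equal(bp$grad[j], (lossf(tp) - lossf(tm)) / (2 * eps),
                   tolerance = 1e-6)
    }
  }
})

test_that("training on zero-FC targets drives the loss down", {
  cohort <- tiny_cohort(fc_maker = function(sc, k) {
    z <- diag(nrow(sc))
    connectivity_matrix(z, "functional")
  })
  cfg <- aghn_config(scales = c(0.8, 2), n_regions = 6)
  tc <- train_config(max_epochs = 30, patience = 30, dropout_keep = 1,
                     exclude_diagonal = TRUE, seed = 2)
  rep <- aghn_train(cohort, cfg, tc)
  h <- rep$history
  expect_lt(h$train_loss[nrow(h)], h$train_loss[1])
  # epoch-1 loss never exceeds the initialization loss
  for (s in 1:5) {
    tc2 <- train_config(max_epochs = 2, patience = 2, dropout_keep = 1,
                        exclude_diagonal = TRUE, seed = s)
    r2 <- aghn_train(cohort, cfg, tc2)
    expect_lte(r2$history$train_loss[2], r2$history$train_loss[1] + 1e-8)
  }
  # predictions after training are near zero on the training split
  preds <- predict_cohort(rep$final_params, cohort, cfg, split = "train")
  losses <- vapply(seq_along(preds), function(k) {
    i <- attr(preds, "subject_indices")[k]
    p <- preds[[k]]$fc_pred
    diag(p) <- 1   # compare off-diagonal structure only
    mean((p - unclass(cohort$pairs[[i]]$fc))^2)
  }, numeric(1))
  expect_lt(max(losses), 1e-3)
})

test_that("training is bitwise reproducible under one master seed", {
  cohort <- tiny_cohort(seed = 5)
  cfg <- aghn_config(scales = c(0.8, 2), n_regions = 6)
  tc <- train_config(max_epochs = 8, patience = 8, seed = 11)  # dropout on
  r1 <- aghn_train(cohort, cfg, tc)
  r2 <- aghn_train(cohort, cfg, tc)
  expect_identical(r1$history, r2$history)
  expect_identical(r1$final_params, r2$final_params)
  # repeat prediction of the same subject is identical
  p1 <- predict_cohort(r1$final_params, cohort, cfg, split = "test")
  p2 <- predict_cohort(r1$final_params, cohort, cfg, split = "test")
  expect_identical(p1[[1]]$fc_pred, p2[[1]]$fc_pred)
})

test_that("early stopping halts after a patience-long validation plateau", {
  cohort <- tiny_cohort(seed = 9)
  cfg <- aghn_config(scales = c(0.8, 2), n_regions = 6)
  # learning rate zero: nothing improves, so the monitor plateaus from
  # epoch 2 onward and training must stop at epoch 1 + patience
  tc <- train_config(learning_rate = 0, weight_decay = 0, max_epochs = 50,
                     patience = 5, dropout_keep = 1, seed = 4)
  rep <- aghn_train(cohort, cfg, tc)
  expect_lte(rep$stopped_epoch, 1 + 5)
  expect_equal(rep$best_epoch, 1)
})

test_that("with zero learning rate parameter norms do not grow", {
  cohort <- tiny_cohort(seed = 13)
  cfg <- aghn_config(scales = c(0.8, 2), n_regions = 6)
  tc <- train_config(learning_rate = 0, weight_decay = 1e-3, max_epochs = 5,
                     patience = 5, dropout_keep = 1, seed = 6)
  rep <- aghn_train(cohort, cfg, tc)
  init <- aghn_init(cfg, seed = 6)
  expect_lte(sqrt(sum(aghn:::flatten_params(rep$final_params)^2)),
             sqrt(sum(aghn:::flatten_params(init)^2)) + 1e-12)
})

test_that("random_aghn freezes the scale weights but trains attention", {
  cohort <- tiny_cohort(seed = 21)
  cfg <- aghn_config(scales = c(0.8, 2), n_regions = 6)
  tc <- train_config(max_epochs = 5, patience = 5, dropout_keep = 1, seed = 8)
  rep <- aghn_train(cohort, cfg, tc, variant = "random_aghn")
  init <- aghn_init(cfg, seed = 8)
  expect_identical(rep$final_params$scale_weights, init$scale_weights)
  expect_false(identical(rep$final_params$attention_weights,
                         init$attention_weights))
})

test_that("degenerate training inputs raise configuration errors", {
  cohort <- tiny_cohort(seed = 2)
  cohort$split <- rep("test", length(cohort$pairs))
  cfg <- aghn_config(scales = c(0.8, 2), n_regions = 6)
  expect_error(aghn_train(cohort, cfg, train_config()), "empty training split")
  expect_error(train_config(dropout_keep = 0), "dropout_keep")
  expect_error(train_config(patience = 20, max_epochs = 10), "patience")
})
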
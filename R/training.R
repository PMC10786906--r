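#' Training hyper-parameters
#'
#' Defaults follow the published regimen: Adam with initial learning rate
#' 0.001, L2 weight decay 5e-4, dropout keep-probability 0.5, at most 100
#' epochs, and early stopping when the validation loss has not decreased
#' for 10 consecutive epochs.
#'
#' @param learning_rate Adam step size.
#' @param weight_decay L2 penalty coefficient added to the gradient.
#' @param dropout_keep Keep-probability in (0, 1]; 1 disables dropout.
#' @param max_epochs Maximum number of passes over the training split.
#' @param patience Consecutive non-improving validation epochs tolerated
#'   before stopping (any decrease counts as an improvement).
#' @param batch_size Subjects per optimizer step.
#' @param seed Master seed; initialization, shuffling and dropout streams
#'   are derived from it.
#' @param exclude_diagonal Logical; when `TRUE` the optimized objective
#'   averages squared residuals over off-diagonal entries only. The
#'   empirical-FC diagonal is identically 1 by construction and carries no
#'   information about the mapping, so recovery experiments set this.
#' @return An `aghn_train_config` object.
#' @export
train_config <- function(learning_rate = 0.001, weight_decay = 5e-4,
                         dropout_keep = 0.5, max_epochs = 100L,
                         patience = 10L, batch_size = 16L, seed = 1L,
                         exclude_diagonal = FALSE) {
  if (dropout_keep <= 0 || dropout_keep > 1) {
    stop("dropout_keep must be in (0, 1]", call. = FALSE)
  }
  if (patience > max_epochs) {
    stop("patience must not exceed max_epochs", call. = FALSE)
  }
  structure(list(learning_rate = learning_rate, weight_decay = weight_decay,
                 dropout_keep = dropout_keep,
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed),
                 exclude_diagonal = isTRUE(exclude_diagonal)),
            class = "aghn_train_config")
}

#' Prediction loss between two FC matrices
#'
#' Per-entry mean squared error: the squared Frobenius norm of the
#' difference divided by N^2. This is a monotonic rescaling of the summed
#' squared-Frobenius objective (identical minimizer) that keeps
#' hyper-parameters comparable across parcellation sizes.
#'
#' @param pred_fc,emp_fc N x N matrices.
#' @return Non-negative scalar, 0 iff the matrices are equal.
#' @export
aghn_loss <- function(pred_fc, emp_fc) {
  if (!all(dim(pred_fc) == dim(emp_fc))) {
    stop(sprintf("shape mismatch: %d x %d vs %d x %d",
                 nrow(pred_fc), ncol(pred_fc), nrow(emp_fc), ncol(emp_fc)),
         call. = FALSE)
  }
  d <- pred_fc - emp_fc
  sum(d * d) / length(d)
}

# ---- parameter flattening -------------------------------------------------

flatten_params <- function(params) {
  c(unlist(params$scale_weights, use.names = FALSE), params$attention_weights)
}

unflatten_params <- function(flat, config) {
  n <- config$n_regions
  n2 <- n * n
  w <- vector("list", config$n_layers)
  pos <- 0L
  for (l in seq_len(config$n_layers)) {
    w[[l]] <- vector("list", config$m)
    for (i in seq_len(config$m)) {
      w[[l]][[i]] <- matrix(flat[(pos + 1L):(pos + n2)], n, n)
      pos <- pos + n2
    }
  }
  alpha <- flat[(pos + 1L):(pos + n2)]
  structure(list(scale_weights = w, attention_weights = alpha),
            class = "aghn_params")
}

# ---- loss + gradient for one subject --------------------------------------

# Analytic back-propagation through fuse -> attention -> dropout -> stacked
# tanh layers. Returns the subject loss and gradients in the flattened
# parameter layout. `fp` is the cache from .forward_pass().
.backward_pass <- function(fp, fc, bank, params, config, variant,
                           dropout_keep = 1, exclude_diagonal = FALSE) {
  n <- config$n_regions
  m <- config$m
  r <- fp$fc_pred - fc
  if (exclude_diagonal) diag(r) <- 0
  denom <- if (exclude_diagonal) n * n - n else n * n
  loss <- sum(r * r) / denom
  g <- (2 / denom) * r                      # symmetric; d loss / d fused

  if (variant == "m_ghn") {
    d_psi_used <- lapply(seq_len(m), function(i) g / m)
    g_alpha <- numeric(n * n)
  } else {
    scores <- vapply(fp$psi_used, function(p) sum(g * p), numeric(1))
    p <- fp$attention_probs
    d_alpha <- p * (scores - sum(p * scores))   # softmax Jacobian
    wmat <- mat_rowmajor(params$attention_weights, n)
    d_psi_used <- lapply(seq_len(m), function(i) p[i] * g + d_alpha[i] * wmat)
    g_alpha <- numeric(n * n)
    for (i in seq_len(m)) {
      g_alpha <- g_alpha + d_alpha[i] * vec_rowmajor(fp$psi_used[[i]])
    }
  }

  g_w <- NULL
  if (variant != "random_aghn") {
    g_w <- lapply(seq_len(config$n_layers), function(l) vector("list", m))
    for (i in seq_len(m)) {
      d_psi <- d_psi_used[[i]]
      if (!is.null(fp$masks)) d_psi <- d_psi * fp$masks[[i]] / dropout_keep
      for (l in rev(seq_len(config$n_layers))) {
        psi_l <- fp$psi_layers[[i]][[l]]
        dz <- d_psi * (1 - psi_l * psi_l)
        g_w[[l]][[i]] <- dz %*% t(fp$hpsi[[i]][[l]])
        if (l > 1L) {
          d_psi <- bank$kernels[[i]] %*%
            (t(params$scale_weights[[l]][[i]]) %*% dz)
        }
      }
    }
  }

  flat_gw <- if (is.null(g_w)) {
    numeric(config$n_layers * m * n * n)
  } else {
    unlist(g_w, use.names = FALSE)
  }
  list(loss = loss, grad = c(flat_gw, g_alpha))
}

# ---- training loop --------------------------------------------------------

#' Train an A-GHN on a cohort
#'
#' Minimizes the mean per-subject FC prediction error over the training
#' split with Adam, evaluating the validation split after every epoch
#' (dropout off) and stopping early when validation loss fails to improve
#' for `patience` consecutive epochs. The returned parameters are those of
#' the best validation epoch. All parameters are shared across subjects;
#' only the heat-kernel bank is subject-specific.
#'
#' @param cohort An [make_cohort()] cohort.
#' @param scale_config An [aghn_config()] matching the cohort's N.
#' @param config An [train_config()].
#' @param variant Model variant: `"aghn"` (attention fusion), `"m_ghn"`
#'   (uniform fusion, no attention), or `"random_aghn"` (scale weights
#'   frozen at initialization; only the attention weights train).
#' @param features Optional node feature matrix X (default identity).
#' @param verbose Print a progress line every `verbose` epochs (0 = quiet).
#' @return An `aghn_train_report`: list with `history` (data frame of
#'   per-epoch `train_loss`, `val_loss` and the summed-Frobenius
#'   convention `train_frob`), `stopped_epoch`, `best_epoch`,
#'   `final_params`, plus the configurations used.
#' @export
aghn_train <- function(cohort, scale_config, config = train_config(),
                       variant = c("aghn", "m_ghn", "random_aghn"),
                       features = NULL, verbose = 0L) {
  variant <- match.arg(variant)
  idx_train <- split_indices(cohort, "train")
  idx_val <- split_indices(cohort, "val")
  if (length(idx_train) == 0) stop("empty training split", call. = FALSE)
  if (cohort$n_regions != scale_config$n_regions) {
    stop("scale_config n_regions does not match the cohort", call. = FALSE)
  }

  banks <- lapply(cohort$pairs,
                  function(p) build_kernel_bank(p$sc, scale_config$scales))
  fcs <- lapply(cohort$pairs, function(p) unclass_matrix(p$fc))

  params <- aghn_init(scale_config, seed = config$seed)
  theta <- flatten_params(params)
  n2 <- scale_config$n_regions^2
  n_w <- length(theta) - n2
  trainable <- rep(TRUE, length(theta))
  if (variant == "random_aghn") trainable[seq_len(n_w)] <- FALSE

  # Adam state
  mo <- numeric(length(theta))
  vo <- numeric(length(theta))
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  step <- 0L

  subject_loss <- function(i, par, train_mode) {
    fp <- .forward_pass(banks[[i]], par, scale_config, variant,
                        training = train_mode,
                        dropout_keep = config$dropout_keep,
                        features = features)
    r <- fp$fc_pred - fcs[[i]]
    if (config$exclude_diagonal) diag(r) <- 0
    denom <- if (config$exclude_diagonal) n2 - scale_config$n_regions else n2
    sum(r * r) / denom
  }

  set.seed(derive_seed(config$seed, 20L))   # shuffle + dropout stream
  history <- vector("list", config$max_epochs)
  best_val <- Inf
  best_theta <- theta
  best_epoch <- 0L
  wait <- 0L
  stopped_epoch <- config$max_epochs

  for (epoch in seq_len(config$max_epochs)) {
    order_idx <- sample(idx_train)
    batches <- split(order_idx,
                     ceiling(seq_along(order_idx) / config$batch_size))
    epoch_losses <- numeric(0)
    for (batch in batches) {
      params <- unflatten_params(theta, scale_config)
      grad <- numeric(length(theta))
      bloss <- 0
      for (i in batch) {
        fp <- .forward_pass(banks[[i]], params, scale_config, variant,
                            training = TRUE,
                            dropout_keep = config$dropout_keep,
                            features = features)
        bp <- .backward_pass(fp, fcs[[i]], banks[[i]], params, scale_config,
                             variant, dropout_keep = config$dropout_keep,
                             exclude_diagonal = config$exclude_diagonal)
        grad <- grad + bp$grad
        bloss <- bloss + bp$loss
      }
      grad <- grad / length(batch)
      bloss <- bloss / length(batch)
      if (!is.finite(bloss)) {
        stop(sprintf("non-finite training loss at epoch %d", epoch),
             call. = FALSE)
      }
      epoch_losses <- c(epoch_losses, bloss)
      grad <- grad + config$weight_decay * theta
      grad[!trainable] <- 0
      step <- step + 1L
      mo <- b1 * mo + (1 - b1) * grad
      vo <- b2 * vo + (1 - b2) * grad * grad
      mhat <- mo / (1 - b1^step)
      vhat <- vo / (1 - b2^step)
      theta <- theta - config$learning_rate * mhat / (sqrt(vhat) + eps)
    }

    params <- unflatten_params(theta, scale_config)
    val_loss <- if (length(idx_val)) {
      mean(vapply(idx_val, subject_loss, numeric(1),
                  par = params, train_mode = FALSE))
    } else NA_real_
    train_loss <- mean(epoch_losses)
    denom <- if (config$exclude_diagonal) n2 - scale_config$n_regions else n2
    history[[epoch]] <- data.frame(epoch = epoch, train_loss = train_loss,
                                   val_loss = val_loss,
                                   train_frob = train_loss * denom,
                                   lr = config$learning_rate)
    if (verbose > 0 && epoch %% verbose == 0) {
      message(sprintf("epoch %4d  train %.6f  val %.6f",
                      epoch, train_loss, val_loss))
    }

    monitor <- if (is.na(val_loss)) train_loss else val_loss
    if (monitor < best_val) {
      best_val <- monitor
      best_theta <- theta
      best_epoch <- epoch
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= config$patience) {
        stopped_epoch <- epoch
        break
      }
    }
    stopped_epoch <- epoch
  }

  structure(list(history = do.call(rbind, history[!vapply(history, is.null, logical(1))]),
                 stopped_epoch = stopped_epoch,
                 best_epoch = best_epoch,
                 best_val_loss = best_val,
                 final_params = unflatten_params(best_theta, scale_config),
                 scale_config = scale_config,
                 train_config = config,
                 variant = variant),
            class = "aghn_train_report")
}

#' @export
print.aghn_train_report <- function(x, ...) {
  cat(sprintf("<aghn_train_report> variant=%s, stopped at epoch %d (best epoch %d, val loss %.6g)\n",
              x$variant, x$stopped_epoch, x$best_epoch, x$best_val_loss))
  invisible(x)
}

#' Predict FC for every subject of a cohort split
#'
#' Runs the forward pass with the trained (fixed) parameters and dropout
#' off for each subject in the requested split.
#'
#' @param params Trained `aghn_params`.
#' @param cohort An `aghn_cohort`.
#' @param scale_config The [aghn_config()] used at training time.
#' @param variant Model variant (see [aghn_forward()]).
#' @param split Which split to predict: `"test"`, `"val"`, `"train"` or
#'   `"all"`.
#' @param features Optional node feature matrix X.
#' @return List of `aghn_prediction` objects with attribute
#'   `subject_indices` (positions in the cohort).
#' @export
predict_cohort <- function(params, cohort, scale_config,
                           variant = c("aghn", "m_ghn", "random_aghn"),
                           split = "test", features = NULL) {
  variant <- match.arg(variant)
  if (cohort$n_regions != scale_config$n_regions) {
    stop("scale_config n_regions does not match the cohort", call. = FALSE)
  }
  if (length(params$attention_weights) != scale_config$n_regions^2) {
    stop("params do not match scale_config dimensions", call. = FALSE)
  }
  idx <- if (identical(split, "all")) {
    seq_along(cohort$pairs)
  } else {
    split_indices(cohort, split)
  }
  preds <- lapply(idx, function(i) {
    aghn_forward(cohort$pairs[[i]]$sc, params, scale_config,
                 variant = variant, training = FALSE, features = features)
  })
  names(preds) <- vapply(cohort$pairs[idx],
                         function(p) p$id %||% NA_character_, character(1))
  attr(preds, "subject_indices") <- idx
  preds
}
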
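#' Model configuration for an A-GHN
#'
#' Fixes the diffusion scales, the number of stacked GraphHeat layers per
#' sub-model, and the number of brain regions N. The default scale set
#' `c(0.6, 0.8, 1, 2, 4, 6, 8)` spans local (small gamma) to global (large
#' gamma) diffusion.
#'
#' @param scales Strictly increasing positive diffusion scales (length m).
#' @param n_layers Number of stacked GraphHeat layers per sub-model
#'   (1, 2 or 4 are the studied variants; any positive integer is allowed).
#' @param n_regions Number of graph nodes N.
#' @return An `aghn_config` object.
#' @examples
#' cfg <- aghn_config(n_regions = 87)
#' count_parameters(cfg)
#' @export
aghn_config <- function(scales = c(0.6, 0.8, 1, 2, 4, 6, 8),
                        n_layers = 1L, n_regions) {
  if (any(diff(scales) <= 0) || any(scales <= 0)) {
    stop("scales must be strictly increasing and positive", call. = FALSE)
  }
  n_layers <- as.integer(n_layers)
  n_regions <- as.integer(n_regions)
  if (n_layers < 1) stop("n_layers must be >= 1", call. = FALSE)
  if (n_regions < 2) stop("n_regions must be >= 2", call. = FALSE)
  structure(list(scales = scales, m = length(scales),
                 n_layers = n_layers, n_regions = n_regions),
            class = "aghn_config")
}

#' Number of trainable parameters of an A-GHN
#'
#' One layer holds one N x N weight matrix per scale plus the length-N^2
#' attention weight vector: `n_layers * m * N^2 + N^2`. For the
#' Desikan-Killiany parcellation (N = 87) with m = 7 scales and one layer
#' this is 60,552.
#'
#' @param config An [aghn_config()].
#' @return Integer parameter count.
#' @export
count_parameters <- function(config) {
  n2 <- config$n_regions^2
  as.integer(config$n_layers * config$m * n2 + n2)
}

#' Initialize A-GHN parameters
#'
#' Per-scale weight matrices `W[[layer]][[scale]]` (each N x N) and the
#' attention weight vector `w_alpha` (length N^2) are drawn from a scaled
#' uniform distribution with bound 1/N, seeded for reproducibility.
#'
#' @param config An [aghn_config()].
#' @param seed Integer seed for the initialization stream.
#' @return An `aghn_params` object: list with `scale_weights` (list of
#'   `n_layers` lists of m matrices) and `attention_weights` (numeric
#'   vector of length N^2).
#' @export
aghn_init <- function(config, seed = 1L) {
  n <- config$n_regions
  bound <- 1 / n
  set.seed(derive_seed(seed, 10L))
  w <- lapply(seq_len(config$n_layers), function(l) {
    lapply(seq_len(config$m), function(i) {
      matrix(stats::runif(n * n, -bound, bound), n, n)
    })
  })
  alpha <- stats::runif(n * n, -bound, bound)
  structure(list(scale_weights = w, attention_weights = alpha),
            class = "aghn_params")
}

#' One GraphHeat sub-model layer
#'
#' The scale-specific GraphHeat convolution
#' \eqn{\Psi_\gamma = \tanh(W_\gamma H_\gamma X)} with the heat kernel
#' \eqn{H_\gamma = e^{-\gamma L}} as the diffusion filter. The node feature
#' matrix X defaults to the identity, in which case the product reduces to
#' \eqn{\tanh(W_\gamma H_\gamma)}.
#'
#' @param kernel Heat kernel matrix \eqn{H_\gamma} (N x N).
#' @param weight Trainable weight matrix \eqn{W_\gamma} (N x N).
#' @param features Node feature matrix X; `NULL` means the identity.
#' @return N x N matrix with entries in (-1, 1).
#' @export
ghn_forward <- function(kernel, weight, features = NULL) {
  stopifnot_square(kernel, "kernel")
  if (!is.matrix(weight) || any(dim(weight) != dim(kernel))) {
    stop(sprintf("weight must be %d x %d to match the kernel",
                 nrow(kernel), nrow(kernel)), call. = FALSE)
  }
  z <- if (is.null(features)) {
    weight %*% kernel
  } else {
    if (nrow(features) != ncol(kernel)) {
      stop("features rows must match kernel columns", call. = FALSE)
    }
    weight %*% (kernel %*% features)
  }
  tanh(z)
}

#' Attention scores over sub-model outputs
#'
#' Each sub-model output is flattened row-major and scored against a shared
#' weight vector, \eqn{\alpha_i = \mathrm{vec}(\Psi_{\gamma_i}) \cdot
#' W_\alpha}; a softmax converts the scores to convex fusion weights.
#'
#' @param sub_outputs List of m matrices (each N x N).
#' @param attention_weights Numeric vector of length N^2.
#' @return List with `raw_alpha` (length-m scores) and `attention_probs`
#'   (softmax of the scores; positive, summing to 1).
#' @export
compute_attention <- function(sub_outputs, attention_weights) {
  n2 <- length(sub_outputs[[1]])
  if (length(attention_weights) != n2) {
    stop(sprintf("attention_weights has length %d but sub-model outputs have %d entries",
                 length(attention_weights), n2), call. = FALSE)
  }
  raw <- vapply(sub_outputs,
                function(p) sum(vec_rowmajor(p) * attention_weights),
                numeric(1))
  list(raw_alpha = unname(raw), attention_probs = softmax(unname(raw)))
}

#' Fuse sub-model outputs into a predicted FC
#'
#' Convex combination of the scale-specific outputs followed by
#' symmetrization \eqn{(M + M^T)/2}, so the prediction is symmetric and
#' stays inside the tanh range (-1, 1) like an FC correlation matrix.
#'
#' @param sub_outputs List of m matrices (each N x N).
#' @param attention_probs Non-negative weights summing to 1.
#' @return Symmetric N x N matrix.
#' @export
fuse_outputs <- function(sub_outputs, attention_probs) {
  if (abs(sum(attention_probs) - 1) > 1e-8) {
    stop("attention_probs must sum to 1", call. = FALSE)
  }
  acc <- attention_probs[1] * sub_outputs[[1]]
  for (i in seq_along(sub_outputs)[-1]) {
    acc <- acc + attention_probs[i] * sub_outputs[[i]]
  }
  symmetrize(acc)
}

#' A-GHN forward pass
#'
#' Composes the full model for one subject: heat-kernel bank over the
#' configured scales, one GraphHeat sub-model per scale (stacked
#' `n_layers` deep, \eqn{\Psi^{(l+1)} = \tanh(W^{(l)} H \Psi^{(l)})} with
#' \eqn{\Psi^{(0)} = X}), attention over the final-layer outputs, and
#' symmetrized fusion into the predicted FC.
#'
#' Variants: `"aghn"` is the full model; `"m_ghn"` replaces attention by
#' uniform weights 1/m (ablation of the attention module); `"random_aghn"`
#' runs the same forward pass but its scale weights are frozen at
#' initialization during training (see [aghn_train()]).
#'
#' @param sc Structural connectivity matrix (or a precomputed
#'   `heat_kernel_bank` via `bank`).
#' @param params An `aghn_params` object.
#' @param config An [aghn_config()].
#' @param variant One of `"aghn"`, `"m_ghn"`, `"random_aghn"`.
#' @param training Logical; when `TRUE`, dropout with keep-probability
#'   `dropout_keep` is applied to each sub-model output (inverted scaling),
#'   drawing from the current RNG stream. Off at prediction time.
#' @param dropout_keep Keep-probability in (0, 1].
#' @param features Optional node feature matrix X (default identity).
#' @param bank Optional precomputed [build_kernel_bank()] result for `sc`
#'   (saves the eigendecomposition when predicting repeatedly).
#' @return An `aghn_prediction` object: list with `fc_pred`, `sub_outputs`,
#'   `attention_probs`, `raw_alpha`.
#' @export
aghn_forward <- function(sc, params, config,
                         variant = c("aghn", "m_ghn", "random_aghn"),
                         training = FALSE, dropout_keep = 1,
                         features = NULL, bank = NULL) {
  variant <- match.arg(variant)
  if (is.null(bank)) bank <- build_kernel_bank(sc, config$scales)
  if (bank$n_regions != config$n_regions) {
    stop(sprintf("config expects N = %d regions but input has N = %d",
                 config$n_regions, bank$n_regions), call. = FALSE)
  }
  fp <- .forward_pass(bank, params, config, variant,
                      training = training, dropout_keep = dropout_keep,
                      features = features)
  structure(list(fc_pred = fp$fc_pred,
                 sub_outputs = fp$psi_final,
                 attention_probs = fp$attention_probs,
                 raw_alpha = fp$raw_alpha),
            class = "aghn_prediction")
}

# Internal forward pass with cached intermediates for back-propagation.
# Returns per-scale layer outputs, the dropout masks actually used, the
# fused prediction and the attention state.
.forward_pass <- function(bank, params, config, variant,
                          training = FALSE, dropout_keep = 1,
                          features = NULL) {
  m <- config$m
  n_layers <- config$n_layers
  psi_layers <- vector("list", m)   # psi_layers[[i]][[l]]
  hpsi <- vector("list", m)         # cached H %*% Psi^{(l-1)}
  psi_final <- vector("list", m)
  for (i in seq_len(m)) {
    h <- bank$kernels[[i]]
    psi_prev <- features
    psi_layers[[i]] <- vector("list", n_layers)
    hpsi[[i]] <- vector("list", n_layers)
    for (l in seq_len(n_layers)) {
      hp <- if (is.null(psi_prev)) h else h %*% psi_prev
      hpsi[[i]][[l]] <- hp
      psi_prev <- tanh(params$scale_weights[[l]][[i]] %*% hp)
      psi_layers[[i]][[l]] <- psi_prev
    }
    psi_final[[i]] <- psi_prev
  }

  masks <- NULL
  psi_used <- psi_final
  if (training && dropout_keep < 1) {
    n <- config$n_regions
    masks <- lapply(seq_len(m), function(i) {
      matrix(stats::rbinom(n * n, 1L, dropout_keep), n, n)
    })
    psi_used <- lapply(seq_len(m), function(i) {
      psi_final[[i]] * masks[[i]] / dropout_keep
    })
  }

  if (variant == "m_ghn") {
    raw_alpha <- rep(0, m)
    probs <- rep(1 / m, m)
  } else {
    att <- compute_attention(psi_used, params$attention_weights)
    raw_alpha <- att$raw_alpha
    probs <- att$attention_probs
  }

  list(fc_pred = fuse_outputs(psi_used, probs),
       psi_layers = psi_layers, hpsi = hpsi,
       psi_final = psi_final, psi_used = psi_used, masks = masks,
       raw_alpha = raw_alpha, attention_probs = probs)
}

#' Save or load an A-GHN checkpoint
#'
#' A checkpoint archives the trained parameters together with the model
#' configuration and the master seed, and round-trips bitwise.
#'
#' @param params An `aghn_params` object.
#' @param config The matching [aghn_config()].
#' @param path File path for the checkpoint.
#' @param seed Master seed associated with the run (stored for provenance).
#' @return `save_checkpoint()` returns `path` invisibly; `load_checkpoint()`
#'   returns a list with `params`, `config` and `seed`.
#' @export
save_checkpoint <- function(params, config, path, seed = NA_integer_) {
  saveRDS(list(params = params, config = config, seed = seed,
               package_version = as.character(utils::packageVersion("aghn"))),
          path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  if (!all(c("params", "config") %in% names(ck))) {
    stop("not an A-GHN checkpoint: ", path, call. = FALSE)
  }
  ck
}
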
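#' Specification for a synthetic SC-FC cohort
#'
#' Describes a seeded generative cohort: sparse symmetric SC matrices with
#' power-law (Pareto) edge weights, and FC matrices produced from each
#' subject's SC by a known (planted) multi-scale heat-diffusion mixture
#' plus symmetric Gaussian noise. Because the generative family matches
#' the model's own forward equations, parameter and prediction recovery
#' are measurable quantities rather than hopes.
#'
#' @param n_regions Number of nodes N.
#' @param n_subjects Number of subjects (at least 3).
#' @param edge_density Probability that an off-diagonal edge is present.
#' @param powerlaw_exponent Pareto density exponent `a` of the nonzero
#'   weights, `p(x) ~ x^-a` for `x >= weight_min` (a > 1; heavier tails
#'   for smaller `a`).
#' @param weight_min Pareto lower bound before max-rescaling.
#' @param planted_scales Diffusion scales of the planted mixture.
#' @param planted_mixture Either a simplex weight vector shared by all
#'   subjects (same length as `planted_scales`), or the string
#'   `"subject"` for heterogeneous per-subject simplex weights drawn from
#'   a symmetric Dirichlet.
#' @param planted_weight_scale Half-width of the uniform distribution the
#'   shared planted weight matrices M_i are drawn from.
#' @param noise_sigma Standard deviation of the symmetric Gaussian noise
#'   added to the noiseless FC (0 disables noise).
#' @param split_sizes Optional integer vector `c(n_train, n_val, n_test)`;
#'   when `NULL` the 500/50/508 proportions are scaled to `n_subjects`
#'   (train and val rounded, val at least 1, test takes the remainder).
#' @param seed Master seed; every generated object is a deterministic
#'   function of (seed, subject index).
#' @return An `aghn_synthetic_spec` object.
#' @export
synthetic_spec <- function(n_regions = 30L, n_subjects = 100L,
                           edge_density = 0.4, powerlaw_exponent = 3,
                           weight_min = 0.01,
                           planted_scales = c(0.6, 2, 6),
                           planted_mixture = c(0.5, 0.3, 0.2),
                           planted_weight_scale = 2,
                           noise_sigma = 0.05,
                           split_sizes = NULL, seed = 1L) {
  if (n_subjects < 3) stop("n_subjects must be at least 3", call. = FALSE)
  if (edge_density <= 0 || edge_density > 1) {
    stop("edge_density must be in (0, 1]", call. = FALSE)
  }
  if (powerlaw_exponent <= 1) {
    stop("powerlaw_exponent must be > 1", call. = FALSE)
  }
  if (any(diff(planted_scales) <= 0) || any(planted_scales <= 0)) {
    stop("planted_scales must be strictly increasing and positive", call. = FALSE)
  }
  if (is.numeric(planted_mixture)) {
    if (length(planted_mixture) != length(planted_scales) ||
        any(planted_mixture < 0) ||
        abs(sum(planted_mixture) - 1) > 1e-8) {
      stop("planted_mixture must be simplex weights, one per planted scale",
           call. = FALSE)
    }
  } else if (!identical(planted_mixture, "subject")) {
    stop("planted_mixture must be a simplex vector or \"subject\"", call. = FALSE)
  }
  if (noise_sigma < 0) stop("noise_sigma must be non-negative", call. = FALSE)
  if (!is.null(split_sizes)) {
    split_sizes <- as.integer(split_sizes)
    if (length(split_sizes) != 3 || sum(split_sizes) != n_subjects ||
        split_sizes[1] < 1) {
      stop("split_sizes must be c(n_train, n_val, n_test) summing to n_subjects",
           call. = FALSE)
    }
  }
  structure(list(n_regions = as.integer(n_regions),
                 n_subjects = as.integer(n_subjects),
                 edge_density = edge_density,
                 powerlaw_exponent = powerlaw_exponent,
                 weight_min = weight_min,
                 planted_scales = planted_scales,
                 planted_mixture = planted_mixture,
                 planted_weight_scale = planted_weight_scale,
                 noise_sigma = noise_sigma,
                 split_sizes = split_sizes,
                 seed = as.integer(seed)),
            class = "aghn_synthetic_spec")
}

# Pareto sampler: density p(x) ~ x^-a for x >= xmin (inverse-CDF method).
rpareto <- function(n, exponent, xmin) {
  xmin * stats::runif(n)^(-1 / (exponent - 1))
}

#' Generate one synthetic structural connectivity matrix
#'
#' Off-diagonal support is drawn independently with probability
#' `edge_density`; nonzero weights are i.i.d. Pareto with the configured
#' density exponent, then rescaled so the largest weight is 1 (mirroring
#' normalized streamline counts). Deterministic in (seed, subject index).
#' A disconnected draw is permitted but reported via a message.
#'
#' @param spec An [synthetic_spec()].
#' @param subject_index Positive integer subject index.
#' @return Structural [connectivity_matrix].
#' @export
generate_sc <- function(spec, subject_index = 1L) {
  n <- spec$n_regions
  set.seed(derive_seed(spec$seed, 1L, subject_index))
  n_pairs <- n * (n - 1) / 2
  present <- stats::runif(n_pairs) < spec$edge_density
  w <- numeric(n_pairs)
  if (any(present)) {
    w[present] <- rpareto(sum(present), spec$powerlaw_exponent, spec$weight_min)
    w <- w / max(w)
  }
  a <- matrix(0, n, n)
  a[upper.tri(a)] <- w
  a <- a + t(a)
  comps <- igraph::components(
    igraph::graph_from_adjacency_matrix(a > 0, mode = "undirected"))
  if (comps$no > 1) {
    message(sprintf("generate_sc: subject %d SC graph has %d components",
                    subject_index, comps$no))
  }
  connectivity_matrix(a, "structural")
}

#' Planted generative parameters of a synthetic cohort
#'
#' The shared weight matrices `M_i` (one per planted scale, entries
#' uniform on +/- `planted_weight_scale`) are drawn once per cohort from
#' the seeded stream, mirroring population-shared model parameters.
#'
#' @param spec An [synthetic_spec()].
#' @return List with `M` (list of matrices) and `scales`.
#' @export
planted_parameters <- function(spec) {
  n <- spec$n_regions
  set.seed(derive_seed(spec$seed, 2L, 0L))
  M <- lapply(seq_along(spec$planted_scales), function(i) {
    matrix(stats::runif(n * n, -spec$planted_weight_scale,
                        spec$planted_weight_scale), n, n)
  })
  list(M = M, scales = spec$planted_scales)
}

# Per-subject mixture weights on the scale simplex.
planted_mixture_weights <- function(spec, subject_index) {
  if (is.numeric(spec$planted_mixture)) return(spec$planted_mixture)
  k <- length(spec$planted_scales)
  set.seed(derive_seed(spec$seed, 5L, subject_index))
  g <- stats::rgamma(k, shape = 2, rate = 1)   # symmetric Dirichlet(2)
  g / sum(g)
}

#' Generate a synthetic functional connectivity matrix
#'
#' The noiseless FC is the planted analogue of the model's fusion:
#' `symmetrize(sum_i beta_i * tanh(M_i %*% H_{gamma_i}))` with the
#' subject's own heat kernels, plus symmetric Gaussian noise on the
#' off-diagonal entries, clipped to \eqn{[-1, 1]} with the diagonal forced
#' to 1 as in an empirical correlation matrix.
#'
#' @param sc The subject's structural [connectivity_matrix].
#' @param spec An [synthetic_spec()].
#' @param subject_index Positive integer subject index.
#' @param planted Optional precomputed [planted_parameters()] (to avoid
#'   redrawing them per subject).
#' @return Functional [connectivity_matrix].
#' @export
generate_fc <- function(sc, spec, subject_index = 1L, planted = NULL) {
  if (is.null(planted)) planted <- planted_parameters(spec)
  bank <- build_kernel_bank(sc, spec$planted_scales)
  beta <- planted_mixture_weights(spec, subject_index)
  sub <- lapply(seq_along(planted$M), function(i) {
    ghn_forward(bank$kernels[[i]], planted$M[[i]])
  })
  fc <- fuse_outputs(sub, beta)
  if (spec$noise_sigma > 0) {
    set.seed(derive_seed(spec$seed, 3L, subject_index))
    n <- spec$n_regions
    e <- matrix(0, n, n)
    e[upper.tri(e)] <- stats::rnorm(n * (n - 1) / 2, sd = spec$noise_sigma)
    fc <- fc + e + t(e)
  }
  fc <- pmin(pmax(fc, -1), 1)
  diag(fc) <- 1
  connectivity_matrix(fc, "functional")
}

# Split sizes mirroring the 500/50/508 proportions.
default_split_sizes <- function(n_subjects) {
  n_train <- round(n_subjects * 500 / 1058)
  n_val <- max(1L, round(n_subjects * 50 / 1058))
  c(n_train, n_val, n_subjects - n_train - n_val)
}

#' Generate a full synthetic cohort
#'
#' Assembles per-subject SC-FC pairs and split labels. Subjects are
#' generated independently given the seed, so the first `n_train` are the
#' training split, the next `n_val` the validation split and the rest the
#' test split.
#'
#' @param spec An [synthetic_spec()].
#' @return An `aghn_cohort`.
#' @examples
#' cohort <- generate_cohort(synthetic_spec(n_regions = 10, n_subjects = 10))
#' cohort
#' @export
generate_cohort <- function(spec) {
  sizes <- spec$split_sizes %||% default_split_sizes(spec$n_subjects)
  if (any(sizes < 0) || sum(sizes) != spec$n_subjects) {
    stop("split sizes are inconsistent with n_subjects", call. = FALSE)
  }
  planted <- planted_parameters(spec)
  pairs <- lapply(seq_len(spec$n_subjects), function(k) {
    sc <- generate_sc(spec, k)
    fc <- generate_fc(sc, spec, k, planted = planted)
    list(sc = sc, fc = fc, id = sprintf("sub-%03d", k))
  })
  split <- rep(c("train", "val", "test"), times = sizes)
  make_cohort(pairs, split)
}

#' Power-law perturbation of a test SC matrix
#'
#' Replaces the SC entirely by a fresh draw from the power-law edge-weight
#' generator (support and weights both resampled). The output therefore
#' carries no dependence on the input values beyond its dimension: this is
#' the regime in which a model that genuinely learned the SC-FC mapping
#' should fail, as opposed to one that memorized population-average FC.
#' Deterministic in (seed, replicate). The draw uses the spec's
#' `edge_density`; setting it to 1 in the perturbation spec reproduces the
#' dense protocol in which every off-diagonal element receives a fresh
#' power-law value.
#'
#' @param sc Structural [connectivity_matrix] (used only for its size
#'   check against the spec).
#' @param spec An [synthetic_spec()].
#' @param replicate Integer replicate index.
#' @return Structural [connectivity_matrix].
#' @export
perturb_sc <- function(sc, spec, replicate = 1L) {
  if (nrow(sc) != spec$n_regions) {
    stop("sc dimension does not match the spec", call. = FALSE)
  }
  n <- spec$n_regions
  set.seed(derive_seed(spec$seed, 4L, replicate))
  n_pairs <- n * (n - 1) / 2
  present <- stats::runif(n_pairs) < spec$edge_density
  w <- numeric(n_pairs)
  if (any(present)) {
    w[present] <- rpareto(sum(present), spec$powerlaw_exponent, spec$weight_min)
    w <- w / max(w)
  }
  a <- matrix(0, n, n)
  a[upper.tri(a)] <- w
  connectivity_matrix(a + t(a), "structural")
}
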
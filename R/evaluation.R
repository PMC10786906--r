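#' Pearson correlation between two FC matrices
#'
#' Correlates the vectorized strict upper triangles of the two symmetric
#' matrices. The diagonal is excluded: empirical FC has a constant unit
#' diagonal, and including a constant would spuriously inflate the
#' correlation.
#'
#' @param pred,emp Symmetric N x N matrices.
#' @return Correlation in \eqn{[-1, 1]}.
#' @export
pearson_fc <- function(pred, emp) {
  if (!all(dim(pred) == dim(emp))) {
    stop("matrices must have identical dimensions", call. = FALSE)
  }
  x <- upper_tri_values(pred)
  y <- upper_tri_values(emp)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined: zero variance in an upper triangle",
         call. = FALSE)
  }
  stats::cor(x, y)
}

#' Louvain community detection on an FC matrix
#'
#' Runs modularity-maximizing Louvain clustering on the weighted graph of
#' the FC matrix. Negative entries are clipped to zero first (classical
#' modularity assumes non-negative weights) and the diagonal is ignored.
#' The partition is deterministic given the seed.
#'
#' @param fc Symmetric N x N matrix.
#' @param resolution Louvain resolution parameter (1 = classical
#'   modularity; larger values favor more, smaller communities).
#' @param seed Integer seed for the algorithm's randomized sweep order.
#' @return An `aghn_partition` object: list with `assignment` (length-N
#'   integer labels, contiguous from 0) and `n_communities`.
#' @export
detect_communities <- function(fc, resolution = 1, seed = 1L) {
  stopifnot_square(fc, "FC matrix")
  w <- pmax(unclass_matrix(fc), 0)
  diag(w) <- 0
  if (all(w == 0)) {
    stop("degenerate partition: matrix has no positive off-diagonal weights",
         call. = FALSE)
  }
  g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                           weighted = TRUE)
  set.seed(derive_seed(seed, 30L))
  cl <- igraph::cluster_louvain(g, resolution = resolution)
  labels <- as.integer(igraph::membership(cl)) - 1L
  partition(labels)
}

#' @rdname detect_communities
#' @param assignment Integer community labels (any coding; relabeled to be
#'   contiguous from 0 in first-appearance order).
#' @export
partition <- function(assignment) {
  labels <- as.integer(factor(assignment, levels = unique(assignment))) - 1L
  structure(list(assignment = labels,
                 n_communities = length(unique(labels))),
            class = "aghn_partition")
}

partition_labels <- function(x) {
  if (inherits(x, "aghn_partition")) x$assignment else as.integer(x)
}

#' Mutual information between two node partitions
#'
#' The KL divergence between the joint label distribution and the product
#' of its marginals, computed from the contingency table of the two
#' assignments. Reported in bits by default (base-2 logarithm). Symmetric,
#' non-negative, and equal to the partition entropy when both arguments
#' coincide.
#'
#' @param x,y Partitions ([partition()] objects or integer label vectors)
#'   over the same N nodes.
#' @param base Logarithm base (2 = bits).
#' @return Non-negative scalar.
#' @export
mutual_information <- function(x, y, base = 2) {
  lx <- partition_labels(x)
  ly <- partition_labels(y)
  if (length(lx) != length(ly)) {
    stop("partitions must label the same number of nodes", call. = FALSE)
  }
  joint <- table(lx, ly) / length(lx)
  px <- rowSums(joint)
  py <- colSums(joint)
  outer_p <- outer(px, py)
  nz <- joint > 0
  sum(joint[nz] * log(joint[nz] / outer_p[nz], base = base))
}

#' @rdname mutual_information
#' @export
partition_entropy <- function(x, base = 2) {
  p <- table(partition_labels(x))
  p <- p / sum(p)
  -sum(p * log(p, base = base))
}

#' Evaluate cohort predictions against empirical FC
#'
#' Computes per-subject upper-triangle Pearson correlation and per-entry
#' MSE against the empirical FC of the subjects the predictions belong to,
#' plus cohort means. Optionally compares the Louvain community structure
#' of the mean predicted FC with that of the mean empirical FC via
#' partition mutual information (community detection on the split-mean
#' matrices, as in group-level connectomics).
#'
#' @param predictions Output of [predict_cohort()] (carries the subject
#'   indices it was computed for).
#' @param cohort The `aghn_cohort` the predictions refer to.
#' @param mi Logical; also compute the mean-FC community MI table.
#' @param resolution,seed Passed to [detect_communities()] when
#'   `mi = TRUE`.
#' @return An `aghn_eval_report`: list with `per_subject` (data frame of
#'   `id`, `pearson`, `mse`), `mean_pearson`, `mean_mse`, and optionally
#'   `mi_table` (data frame mirroring a "Model1 vs. Model2 / MI" layout)
#'   and the two partitions.
#' @export
evaluate_cohort <- function(predictions, cohort, mi = FALSE,
                            resolution = 1, seed = 1L) {
  idx <- attr(predictions, "subject_indices")
  if (is.null(idx)) idx <- seq_along(predictions)
  if (length(idx) == 0) stop("no predictions to evaluate", call. = FALSE)
  per <- data.frame(
    id = vapply(cohort$pairs[idx], function(p) p$id %||% NA_character_,
                character(1)),
    pearson = vapply(seq_along(idx), function(k) {
      pearson_fc(predictions[[k]]$fc_pred,
                 unclass_matrix(cohort$pairs[[idx[k]]]$fc))
    }, numeric(1)),
    mse = vapply(seq_along(idx), function(k) {
      aghn_loss(predictions[[k]]$fc_pred,
                unclass_matrix(cohort$pairs[[idx[k]]]$fc))
    }, numeric(1))
  )
  report <- list(per_subject = per,
                 mean_pearson = mean(per$pearson),
                 mean_mse = mean(per$mse))
  if (mi) {
    mean_pred <- Reduce(`+`, lapply(predictions, `[[`, "fc_pred")) /
      length(predictions)
    mean_emp <- Reduce(`+`, lapply(cohort$pairs[idx],
                                   function(p) unclass_matrix(p$fc))) /
      length(idx)
    part_emp <- detect_communities(mean_emp, resolution, seed)
    part_pred <- detect_communities(mean_pred, resolution, seed)
    report$partition_empirical <- part_emp
    report$partition_predicted <- part_pred
    report$mi_table <- data.frame(
      comparison = c("empirical vs empirical", "empirical vs predicted",
                     "predicted vs predicted"),
      mutual_information = c(mutual_information(part_emp, part_emp),
                             mutual_information(part_emp, part_pred),
                             mutual_information(part_pred, part_pred))
    )
  }
  structure(report, class = "aghn_eval_report")
}

#' @export
print.aghn_eval_report <- function(x, ...) {
  cat(sprintf("<aghn_eval_report> %d subjects: mean Pearson %.4f, mean MSE %.5f\n",
              nrow(x$per_subject), x$mean_pearson, x$mean_mse))
  if (!is.null(x$mi_table)) {
    cat(sprintf("communities: empirical %d, predicted %d; MI(emp, pred) = %.3f bits\n",
                x$partition_empirical$n_communities,
                x$partition_predicted$n_communities,
                x$mi_table$mutual_information[2]))
  }
  invisible(x)
}

#' Power-law SC perturbation experiment
#'
#' For each test subject, replaces the SC by `n_replicates` fresh
#' power-law draws, predicts FC from each perturbed SC with the trained
#' (unchanged) parameters, and correlates every prediction against the
#' subject's empirical FC. A model that learned the SC-FC mapping should
#' degrade sharply relative to its unperturbed performance.
#'
#' @param params Trained `aghn_params`.
#' @param cohort The `aghn_cohort` whose test split is perturbed.
#' @param spec The [synthetic_spec()] providing the power-law generator
#'   (its `seed` governs the perturbation draws).
#' @param scale_config The [aghn_config()] used at training time.
#' @param variant Model variant.
#' @param n_replicates Perturbed draws per subject (must be positive).
#' @return An `aghn_perturbation_summary`: list with `per_subject` (data
#'   frame of `id` and `mean_pearson` over replicates), `pooled`
#'   (mean/min/max over all subject-replicate pairs), and `n_replicates`.
#' @export
perturbation_experiment <- function(params, cohort, spec, scale_config,
                                    variant = c("aghn", "m_ghn", "random_aghn"),
                                    n_replicates = 25L) {
  variant <- match.arg(variant)
  if (n_replicates < 1) {
    stop("n_replicates must be a positive integer", call. = FALSE)
  }
  idx <- split_indices(cohort, "test")
  if (length(idx) == 0) stop("empty test split", call. = FALSE)
  per <- lapply(seq_along(idx), function(k) {
    i <- idx[k]
    emp <- unclass_matrix(cohort$pairs[[i]]$fc)
    r <- vapply(seq_len(n_replicates), function(rep) {
      sc_p <- perturb_sc(cohort$pairs[[i]]$sc, spec,
                         replicate = (k - 1L) * n_replicates + rep)
      pred <- aghn_forward(sc_p, params, scale_config, variant = variant)
      pearson_fc(pred$fc_pred, emp)
    }, numeric(1))
    r
  })
  pooled <- unlist(per)
  structure(list(
    per_subject = data.frame(
      id = vapply(cohort$pairs[idx], function(p) p$id %||% NA_character_,
                  character(1)),
      mean_pearson = vapply(per, mean, numeric(1))),
    pooled = c(mean = mean(pooled), min = min(pooled), max = max(pooled)),
    n_replicates = as.integer(n_replicates)),
    class = "aghn_perturbation_summary")
}

#' @export
print.aghn_perturbation_summary <- function(x, ...) {
  cat(sprintf("<aghn_perturbation_summary> %d subjects x %d replicates: pooled mean r = %.3f (range %.3f to %.3f)\n",
              nrow(x$per_subject), x$n_replicates,
              x$pooled["mean"], x$pooled["min"], x$pooled["max"]))
  invisible(x)
}
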
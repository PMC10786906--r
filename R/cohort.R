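#' Assemble a cohort of SC-FC pairs
#'
#' A cohort is the unit of training data: an ordered collection of
#' per-subject structural/functional connectivity pairs plus a train /
#' validation / test split label per subject.
#'
#' @param pairs List of subjects, each a list with elements `sc`
#'   (structural [connectivity_matrix]), `fc` (functional
#'   [connectivity_matrix]) and `id` (character identifier).
#' @param split Character vector (one of `"train"`, `"val"`, `"test"` per
#'   subject), same length as `pairs`.
#' @return An `aghn_cohort` object.
#' @export
make_cohort <- function(pairs, split) {
  if (length(pairs) != length(split)) {
    stop("one split label per subject is required", call. = FALSE)
  }
  if (!all(split %in% c("train", "val", "test"))) {
    stop("split labels must be 'train', 'val' or 'test'", call. = FALSE)
  }
  ns <- vapply(pairs, function(p) nrow(p$sc), integer(1))
  if (length(unique(ns)) > 1) {
    stop("all subjects must share the same number of regions", call. = FALSE)
  }
  structure(list(pairs = pairs, split = split, n_regions = ns[1]),
            class = "aghn_cohort")
}

#' @export
print.aghn_cohort <- function(x, ...) {
  tab <- table(factor(x$split, levels = c("train", "val", "test")))
  cat(sprintf("<aghn_cohort> %d subjects, N = %d regions (train %d / val %d / test %d)\n",
              length(x$pairs), x$n_regions, tab["train"], tab["val"], tab["test"]))
  invisible(x)
}

#' @rdname make_cohort
#' @param cohort An `aghn_cohort`.
#' @param which Split name.
#' @return `split_indices()` returns the integer subject indices in a split.
#' @export
split_indices <- function(cohort, which = c("train", "val", "test")) {
  which <- match.arg(which)
  which(cohort$split == which)
}
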
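#' Construct a validated connectivity matrix
#'
#' Wraps a square numeric matrix as either a structural connectivity (SC)
#' matrix or a functional connectivity (FC) matrix and enforces the
#' invariants of each kind. SC matrices hold non-negative streamline-density
#' weights with a zero diagonal; FC matrices hold Pearson correlations in
#' \eqn{[-1, 1]} with a unit diagonal. Both must be symmetric.
#'
#' @param values Square numeric matrix.
#' @param kind Either `"structural"` or `"functional"`.
#' @param tol Symmetry tolerance (maximum absolute difference between the
#'   matrix and its transpose).
#'
#' @return A `connectivity_matrix` object: the numeric matrix with
#'   attributes `kind` and `n_regions`.
#' @examples
#' sc <- connectivity_matrix(matrix(c(0, 1, 1, 0), 2), "structural")
#' n_regions(sc)
#' @export
connectivity_matrix <- function(values, kind = c("structural", "functional"),
                                tol = 1e-10) {
  kind <- match.arg(kind)
  stopifnot_square(values, "connectivity matrix")
  if (!is.numeric(values) || any(!is.finite(values))) {
    stop("connectivity matrix must be finite numeric", call. = FALSE)
  }
  asym <- max(abs(values - t(values)))
  if (asym > tol) {
    stop(sprintf("connectivity matrix is not symmetric (max |M - t(M)| = %.3g)",
                 asym), call. = FALSE)
  }
  values <- symmetrize(values)
  if (kind == "structural") {
    if (any(values < 0)) {
      stop("structural connectivity weights must be non-negative", call. = FALSE)
    }
    if (any(diag(values) != 0)) {
      stop("structural connectivity must have a zero diagonal", call. = FALSE)
    }
  } else {
    if (any(values < -1 - tol) || any(values > 1 + tol)) {
      stop("functional connectivity entries must lie in [-1, 1]", call. = FALSE)
    }
    if (any(abs(diag(values) - 1) > tol)) {
      stop("functional connectivity must have a unit diagonal", call. = FALSE)
    }
  }
  structure(values,
            kind = kind,
            n_regions = nrow(values),
            class = c("connectivity_matrix", "matrix", "array"))
}

#' @rdname connectivity_matrix
#' @param x Object to test or query.
#' @export
is_connectivity_matrix <- function(x) inherits(x, "connectivity_matrix")

#' @rdname connectivity_matrix
#' @export
n_regions <- function(x) {
  attr(x, "n_regions") %||% nrow(x)
}

#' @rdname connectivity_matrix
#' @export
connectivity_kind <- function(x) attr(x, "kind")

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat(sprintf("<connectivity_matrix> kind=%s, %d regions\n",
              attr(x, "kind"), nrow(x)))
  print(unclass_matrix(x), ...)
  invisible(x)
}

unclass_matrix <- function(x) {
  attributes(x) <- list(dim = dim(x))
  x
}

# Internal: accept either a connectivity_matrix or a plain matrix and return
# the plain numeric matrix, checking structural preconditions.
as_sc_matrix <- function(sc, tol = 1e-10) {
  if (is_connectivity_matrix(sc)) {
    if (connectivity_kind(sc) != "structural") {
      stop("expected a structural connectivity matrix", call. = FALSE)
    }
    return(unclass_matrix(sc))
  }
  unclass_matrix(connectivity_matrix(sc, "structural", tol = tol))
}
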
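#' Combinatorial graph Laplacian of a structural connectivity matrix
#'
#' Builds \eqn{L = D - A} where \eqn{D} is the diagonal weighted-degree
#' matrix, \eqn{D_{ii} = \sum_j A_{ij}}. The combinatorial Laplacian is
#' symmetric positive semi-definite, every row sums to zero, and its
#' smallest eigenvalue is zero (with multiplicity equal to the number of
#' connected components).
#'
#' @param sc Structural connectivity: a [connectivity_matrix] of kind
#'   `"structural"`, or a plain symmetric non-negative square matrix with a
#'   zero diagonal.
#' @return A `laplacian` object: list with `values` (the N x N matrix
#'   \eqn{L}) and `degrees` (the weighted degrees, diagonal of \eqn{D}).
#' @examples
#' lap <- build_laplacian(matrix(c(0, 1, 1, 0), 2))
#' lap$values
#' @export
build_laplacian <- function(sc) {
  a <- as_sc_matrix(sc)
  d <- rowSums(a)
  l <- diag(d, nrow = nrow(a)) - a
  structure(list(values = l, degrees = d, n_regions = nrow(a)),
            class = "laplacian")
}

#' Spectral decomposition of a graph Laplacian
#'
#' Full symmetric eigendecomposition \eqn{L = U \Lambda U^T} with
#' eigenvalues sorted in increasing order. One decomposition per subject
#' serves every diffusion scale, since the heat kernel at any scale is a
#' spectral function of the same eigensystem.
#'
#' @param lap A `laplacian` object from [build_laplacian()], or a symmetric
#'   positive semi-definite matrix.
#' @return A `spectral_decomposition` object: list with `eigenvectors`
#'   (orthonormal N x N matrix `U`, columns ordered to match `eigenvalues`)
#'   and `eigenvalues` (non-decreasing, first approximately 0).
#' @export
spectral_decompose <- function(lap) {
  l <- if (inherits(lap, "laplacian")) lap$values else lap
  stopifnot_square(l, "Laplacian")
  if (any(!is.finite(l))) stop("Laplacian contains non-finite entries", call. = FALSE)
  e <- eigen(symmetrize(l), symmetric = TRUE)
  # eigen() returns decreasing order; flip to increasing
  idx <- rev(seq_along(e$values))
  structure(list(eigenvectors = e$vectors[, idx, drop = FALSE],
                 eigenvalues = e$values[idx]),
            class = "spectral_decomposition")
}

#' Graph heat kernel at one diffusion scale
#'
#' Computes \eqn{H_\gamma = e^{-\gamma L} = U e^{-\gamma \Lambda} U^T} from
#' a precomputed spectral decomposition. Because the Laplacian annihilates
#' the constant vector, each row of \eqn{H_\gamma} sums to 1: the kernel is
#' the transition operator of heat diffusion on the graph, interpolating
#' between the identity (\eqn{\gamma = 0}, purely local) and the projector
#' onto the component-wise constant subspace (\eqn{\gamma \to \infty},
#' fully global).
#'
#' @param decomp A `spectral_decomposition` from [spectral_decompose()].
#' @param gamma Diffusion scale, a single non-negative number.
#' @return Symmetric N x N matrix with non-negative entries and unit row
#'   sums (up to numerical tolerance).
#' @export
heat_kernel <- function(decomp, gamma) {
  if (!inherits(decomp, "spectral_decomposition")) {
    stop("decomp must be a spectral_decomposition", call. = FALSE)
  }
  if (length(gamma) != 1 || !is.finite(gamma) || gamma < 0) {
    stop("gamma must be a single non-negative number", call. = FALSE)
  }
  u <- decomp$eigenvectors
  h <- u %*% (exp(-gamma * decomp$eigenvalues) * t(u))
  # eigensolver round-off leaves ~1e-16 asymmetry; remove it at source
  symmetrize(h)
}

#' Bank of heat kernels over multiple diffusion scales
#'
#' Computes \eqn{\{e^{-\gamma_i L}\}_{i=1}^m} for one subject from a single
#' spectral decomposition of its structural Laplacian. The default scale
#' set used throughout the package is `c(0.6, 0.8, 1, 2, 4, 6, 8)`.
#'
#' @inheritParams build_laplacian
#' @param scales Strictly increasing positive diffusion scales.
#' @return A `heat_kernel_bank` object: list with `scales` and `kernels`
#'   (one symmetric row-stochastic matrix per scale, named by scale).
#' @examples
#' bank <- build_kernel_bank(matrix(c(0, 1, 1, 0), 2), scales = c(0.5, 1))
#' sapply(bank$kernels, function(h) range(rowSums(h)))
#' @export
build_kernel_bank <- function(sc, scales = c(0.6, 0.8, 1, 2, 4, 6, 8)) {
  if (length(scales) < 1 || any(!is.finite(scales)) || any(scales <= 0)) {
    stop("scales must be positive finite numbers", call. = FALSE)
  }
  if (any(diff(scales) <= 0)) {
    stop("scales must be strictly increasing (no duplicates)", call. = FALSE)
  }
  decomp <- spectral_decompose(build_laplacian(sc))
  kernels <- lapply(scales, function(g) heat_kernel(decomp, g))
  names(kernels) <- as.character(scales)
  structure(list(scales = scales, kernels = kernels,
                 n_regions = nrow(kernels[[1]])),
            class = "heat_kernel_bank")
}
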
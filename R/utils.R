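# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
#' @noRd
symmetrize <- function(m) (m + t(m)) / 2

# Row-major vectorization. The attention module scores each sub-model output
# by a dot product with a shared weight vector; the flattening order is a
# convention that must stay fixed (tests pin it).
vec_rowmajor <- function(m) as.vector(t(m))

mat_rowmajor <- function(v, n) matrix(v, nrow = n, ncol = n, byrow = TRUE)

# Derive a child seed from a master seed, a stream id and an index.
# Arithmetic stays in exact double range and the result fits a 32-bit integer.
derive_seed <- function(seed, stream, index = 0L) {
  s <- (abs(as.numeric(seed)) %% 2147483647) + 1
  h <- (s * 69069 + as.numeric(stream) * 1013904 + as.numeric(index) * 7919) %%
    2147483629
  as.integer(h + 1)
}

stopifnot_square <- function(m, what = "matrix") {
  if (!is.matrix(m) || nrow(m) != ncol(m)) {
    stop(sprintf("%s must be a square matrix, got %s x %s",
                 what, NROW(m), NCOL(m)), call. = FALSE)
  }
  invisible(m)
}

softmax <- function(x) {
  z <- exp(x - max(x))
  z / sum(z)
}

upper_tri_values <- function(m) m[upper.tri(m, diag = FALSE)]
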
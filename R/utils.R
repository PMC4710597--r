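# Internal helpers shared across modules.

#' @keywords internal
soft_threshold <- function(z, lambda) {
  sign(z) * pmax(abs(z) - lambda, 0)
}

# Solve a symmetric PSD system, falling back to a pseudo-inverse when the
# matrix is numerically singular (e.g. near-collinear group indicators).
#' @keywords internal
psolve <- function(A, b = NULL, tol = 1e-12) {
  s <- svd(A)
  pos <- s$d > tol * max(s$d)
  Ainv <- s$v[, pos, drop = FALSE] %*%
    (t(s$u[, pos, drop = FALSE]) / s$d[pos])
  if (is.null(b)) Ainv else Ainv %*% b
}

# Derive a stage seed from a root seed; stays below .Machine$integer.max.
#' @keywords internal
derive_seed <- function(root, k) {
  as.integer((as.double(root) * 10007 + 97 * k) %% 2147483629 + 1)
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

# Format doubles so that write/read round-trips are exact.
#' @keywords internal
fmt_double <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- NA_character_
  out
}

#' @keywords internal
is_flag <- function(x) is.logical(x) && length(x) == 1L && !is.na(x)

#' @keywords internal
check_psd <- function(mat, tol = 1e-8) {
  if (!isSymmetric(unname(mat), tol = 1e-10)) {
    stop("correlation matrix must be symmetric", call. = FALSE)
  }
  ev <- eigen(mat, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -tol) {
    stop("correlation matrix is not positive semi-definite", call. = FALSE)
  }
  invisible(TRUE)
}
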
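#' Multiplicative zero replacement for compositional data
#'
#' Replaces zero parts of a composition by a small proportion `delta` and
#' rescales the nonzero parts multiplicatively so the composition still sums
#' to one. Ratios among the nonzero parts are preserved exactly, which is the
#' property that makes this the standard pre-treatment before log-ratio
#' transforms.
#'
#' @param x A numeric vector holding one composition, or a matrix/data.frame
#'   with one composition per row. Parts must be non-negative and each
#'   composition must sum to 1 (within `tol`). Rows containing `NA` are passed
#'   through unchanged (a missing composition stays missing).
#' @param delta Replacement proportion for a zero part. Default is 0.65 times
#'   the smallest nonzero part observed anywhere in `x`, a common choice when
#'   the detection limit is unknown.
#' @param tol Tolerance for the sum-to-one check.
#' @return Object of the same shape as `x` with strictly positive parts
#'   (except untouched `NA` rows), each composition summing to 1. The delta
#'   used is attached as attribute `"delta"`.
#' @examples
#' replace_zeros(c(0.5, 0.5, 0, 0), delta = 0.05)
#' @export
replace_zeros <- function(x, delta = NULL, tol = 1e-8) {
  vec <- is.null(dim(x))
  m <- if (vec) matrix(as.numeric(x), nrow = 1) else as.matrix(x)
  if (ncol(m) < 2L) stop("a composition needs at least 2 parts")
  ok <- stats::complete.cases(m)
  vals <- m[ok, , drop = FALSE]
  if (any(vals < 0)) stop("compositional parts must be non-negative")
  if (any(abs(rowSums(vals) - 1) > max(tol, 1e-6)))
    stop("each composition must sum to 1; normalise before zero replacement")
  if (any(rowSums(vals > 0) == 0)) stop("all-zero composition cannot be replaced")
  if (is.null(delta)) {
    nz <- vals[vals > 0]
    delta <- 0.65 * min(nz)
  }
  if (delta <= 0) stop("delta must be positive")
  nzero <- rowSums(vals == 0)
  if (any(delta * nzero >= 1))
    stop("delta too large: delta * (number of zero parts) must be < 1")
  shrink <- 1 - delta * nzero
  out <- vals * shrink
  out[vals == 0] <- delta
  m[ok, ] <- out
  res <- if (vec) drop(m) else m
  attr(res, "delta") <- delta
  res
}

#' Centered log-ratio (CLR) transform
#'
#' Takes the logarithm of each compositional part relative to the geometric
#' mean of the parts, removing the constant-sum constraint. The transformed
#' values of each composition sum to zero, and the transform is invariant to
#' rescaling of the input (closure).
#'
#' @param x Strictly positive composition (vector) or matrix of compositions
#'   (rows). Rows containing `NA` are passed through as `NA`.
#' @return Same shape as `x`; each complete row sums to 0.
#' @examples
#' clr_transform(c(0.8, 0.1, 0.1))
#' @export
clr_transform <- function(x) {
  vec <- is.null(dim(x))
  m <- if (vec) matrix(as.numeric(x), nrow = 1) else as.matrix(x)
  ok <- stats::complete.cases(m)
  vals <- m[ok, , drop = FALSE]
  if (any(vals <= 0))
    stop("clr requires strictly positive parts; apply replace_zeros() first")
  lg <- log(vals)
  m[ok, ] <- lg - rowMeans(lg)
  m[!ok, ] <- NA_real_
  if (vec) drop(m) else m
}
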
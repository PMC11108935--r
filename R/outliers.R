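#' Medcouple robust skewness
#'
#' Robust measure of skewness in `[-1, 1]`: the median of the kernel
#' h(x_i, x_j) = ((x_j - m) - (m - x_i)) / (x_j - x_i) over all pairs with
#' x_i <= m <= x_j, where m is the sample median. For pairs of observations
#' tied at the median the standard -1/0/+1 kernel is used. Zero for
#' symmetric samples, positive for right skew. Naive O(n^2) enumeration --
#' ample at cohort scale.
#'
#' @param x Numeric vector, at least 3 finite values.
#' @return Medcouple in `[-1, 1]`; 0 by convention when all values are
#'   identical.
#' @examples
#' medcouple(c(1, 2, 4, 10))  # 5/18
#' @export
medcouple <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 3L) stop("medcouple needs at least 3 finite values")
  if (max(x) == min(x)) return(0)
  x <- sort(x)
  m <- stats::median(x)
  xi <- x[x <= m]           # ascending
  xj <- x[x >= m]           # ascending
  k <- sum(x == m)          # values tied at the median
  h <- matrix(NA_real_, length(xi), length(xj))
  for (a in seq_along(xi)) {
    for (b in seq_along(xj)) {
      lo <- xi[a]; hi <- xj[b]
      if (hi > lo) {
        h[a, b] <- ((hi - m) - (m - lo)) / (hi - lo)
      } else {
        # both equal the median: xi holds the k tied values last (positions
        # length(xi)-k+1 .. length(xi)), xj holds them first (1..k)
        i <- a - (length(xi) - k)   # 1..k within the tied set
        j <- b                      # 1..k within the tied set
        h[a, b] <- sign(i + j - 1 - k)
      }
    }
  }
  stats::median(h)
}

#' Skewness-adjusted boxplot fences
#'
#' Whisker cutoffs of the adjusted boxplot: with MC the medcouple and IQR
#' the interquartile range, the fences are
#' `[Q1 - 1.5 exp(-4 MC) IQR, Q3 + 1.5 exp(3 MC) IQR]` when MC >= 0 and
#' `[Q1 - 1.5 exp(-3 MC) IQR, Q3 + 1.5 exp(4 MC) IQR]` otherwise, so a
#' skewed tail gets a wider whisker instead of flagging routine skewness as
#' outlying. At MC = 0 this is the classic Tukey boxplot. Quartiles use
#' linear interpolation of order statistics (R's default type 7).
#'
#' @param x Numeric vector, at least 4 finite values.
#' @return Object of class `adjusted_fences`: `q1`, `q3`, `iqr`,
#'   `medcouple`, `lower`, `upper`.
#' @export
adjusted_fences <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 4L) stop("adjusted fences need at least 4 finite values")
  q <- stats::quantile(x, c(0.25, 0.75), names = FALSE, type = 7)
  iqr <- q[2] - q[1]
  mc <- medcouple(x)
  if (iqr == 0) {
    warning("degenerate IQR = 0: fences collapse to [Q1, Q3]")
    lower <- q[1]; upper <- q[2]
  } else if (mc >= 0) {
    lower <- q[1] - 1.5 * exp(-4 * mc) * iqr
    upper <- q[2] + 1.5 * exp(3 * mc) * iqr
  } else {
    lower <- q[1] - 1.5 * exp(-3 * mc) * iqr
    upper <- q[2] + 1.5 * exp(4 * mc) * iqr
  }
  structure(list(q1 = q[1], q3 = q[2], iqr = iqr, medcouple = mc,
                 lower = lower, upper = upper),
            class = "adjusted_fences")
}

#' @export
print.adjusted_fences <- function(x, ...) {
  cat(sprintf("adjusted fences: [%.4g, %.4g]  (Q1 = %.4g, Q3 = %.4g, MC = %.3f)\n",
              x$lower, x$upper, x$q1, x$q3, x$medcouple))
  invisible(x)
}

#' Detect highly contributing outlier donors
#'
#' A donor is removed only when it meets both adjusted-boxplot criteria:
#' (a) its contribution to at least one selected dimension exceeds the upper
#' whisker fence of the contributions, and (b) it is a univariate outlier
#' (outside either fence) on at least one continuous input variable,
#' evaluated on the observed (unimputed) values -- missing cells never flag.
#'
#' @param fit A fitted `famd` object.
#' @param x The raw (unimputed) input `mixed_table` or data frame the model
#'   was fitted to (after imputation); row order must match.
#' @param selected_dims Integer vector of dimension indices to screen
#'   (typically from [select_dimensions()]).
#' @param iteration Round number recorded in the report.
#' @return Object of class `outlier_report`: `iteration`,
#'   `contribution_flags` (donors exceeding the fence, per dimension),
#'   `univariate_flags` (donors outside fences, per variable), `removed`
#'   (donor ids meeting both), and `fences_used`.
#' @export
detect_outliers <- function(fit, x, selected_dims, iteration = 1L) {
  stopifnot(inherits(fit, "famd"))
  mt <- mixed_table(x)
  if (length(mt$ids) != fit$n)
    stop("raw table and fitted model have different numbers of donors")
  fences <- list()
  if (length(selected_dims) == 0L) {
    warning("no selected dimensions: empty outlier report")
    return(structure(list(iteration = iteration,
                          contribution_flags = list(),
                          univariate_flags = list(),
                          removed = character(0), fences_used = fences),
                     class = "outlier_report"))
  }
  contrib_flags <- list()
  for (s in selected_dims) {
    cs <- fit$donor_contrib[, s]
    fen <- adjusted_fences(cs)
    fences[[paste0("contrib_dim", s)]] <- fen
    contrib_flags[[paste0("dim", s)]] <- mt$ids[cs > fen$upper]
  }
  uni_flags <- list()
  for (j in colnames(mt$cont)) {
    v <- mt$cont[, j]
    obs <- !is.na(v)
    fen <- adjusted_fences(v[obs])
    fences[[j]] <- fen
    uni_flags[[j]] <- mt$ids[obs & (v < fen$lower | v > fen$upper)]
  }
  removed <- intersect(unique(unlist(contrib_flags)), unique(unlist(uni_flags)))
  structure(list(iteration = iteration, contribution_flags = contrib_flags,
                 univariate_flags = uni_flags,
                 removed = removed, fences_used = fences),
            class = "outlier_report")
}

#' @export
print.outlier_report <- function(x, ...) {
  cat("outlier report (round ", x$iteration, "): ",
      length(unique(unlist(x$contribution_flags))), " contribution-flagged, ",
      length(unique(unlist(x$univariate_flags))), " univariate-flagged, ",
      length(x$removed), " removed\n", sep = "")
  if (length(x$removed)) cat("  removed:", paste(x$removed, collapse = ", "), "\n")
  invisible(x)
}
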
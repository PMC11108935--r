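#' Rank values under the two tie conventions
#'
#' `averaged` gives conventional mid-ranks (used for the statistical tests);
#' `order_of_appearance` gives unique integer ranks 1..n with ties broken by
#' position in the input (used for plotting donors along an axis, so every
#' donor gets its own rank). Missing values keep `NA` ranks and are reported
#' via the `"n_missing"` attribute.
#'
#' @param x Numeric vector.
#' @param ties `"averaged"` or `"order_of_appearance"`.
#' @return Numeric vector of ranks aligned with `x`.
#' @export
rank_values <- function(x, ties = c("averaged", "order_of_appearance")) {
  ties <- match.arg(ties)
  if (length(x) == 0L || all(is.na(x))) stop("no values to rank")
  r <- rank(x, na.last = "keep",
            ties.method = if (ties == "averaged") "average" else "first")
  attr(r, "n_missing") <- sum(is.na(x))
  r
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks, with a two-sided p-value from the t
#' approximation `t = rho * sqrt((n - 2) / (1 - rho^2))` on n - 2 degrees of
#' freedom. Incomplete pairs are dropped (pairwise deletion).
#'
#' @param x,y Numeric vectors of equal length.
#' @return List with `statistic` (rho), `p_value`, `n_used`. Degenerate rank
#'   variance yields `NA` statistics.
#' @export
spearman_test <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 3L) stop("spearman needs at least 3 complete pairs")
  rx <- rank(x[ok]); ry <- rank(y[ok])
  n <- sum(ok)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    return(list(statistic = NA_real_, p_value = NA_real_, n_used = n))
  rho <- stats::cor(rx, ry)
  p <- if (abs(rho) >= 1) 0 else {
    tval <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(tval), df = n - 2)
  }
  list(statistic = rho, p_value = p, n_used = n)
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum comparison of two groups. Exact enumeration for small
#' tie-free samples (total n <= 8), otherwise the normal approximation with
#' continuity and tie correction.
#'
#' @param a,b Numeric vectors (missing values dropped).
#' @return List with `statistic` (U of group `a`), `p_value`, `n_used`.
#' @export
mann_whitney_test <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) == 0L || length(b) == 0L) stop("both groups need observations")
  ties <- any(duplicated(c(a, b)))
  ex <- (length(a) + length(b) <= 8) && !ties
  wt <- stats::wilcox.test(a, b, exact = ex, correct = TRUE)
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       n_used = length(a) + length(b))
}

#' Kruskal-Wallis test
#'
#' Omnibus rank test across >= 2 groups with tie correction.
#'
#' @param values Numeric vector.
#' @param groups Grouping factor aligned with `values`.
#' @return List with `statistic` (H), `p_value`, `n_used`.
#' @export
kruskal_wallis_test <- function(values, groups) {
  ok <- !is.na(values) & !is.na(groups)
  groups <- droplevels(as.factor(groups[ok]))
  if (nlevels(groups) < 2L) stop("kruskal-wallis needs at least 2 groups")
  if (any(table(groups) == 0L)) stop("empty group")
  kt <- stats::kruskal.test(values[ok], groups)
  list(statistic = unname(kt$statistic), p_value = kt$p.value, n_used = sum(ok))
}

#' Benjamini-Hochberg FDR adjustment within a test family
#'
#' Step-up adjusted q-values with enforced monotonicity; significance is
#' declared at q <= `threshold` (default 0.1, the threshold used throughout
#' the dimension validation).
#'
#' @param p Vector of p-values belonging to one family.
#' @param threshold Significance cutoff on q.
#' @return List with `q` and logical `significant`.
#' @export
bh_fdr <- function(p, threshold = 0.1) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  q <- stats::p.adjust(p, method = "BH")
  list(q = q, significant = !is.na(q) & q <= threshold)
}

#' Centered moving average over rank-ordered values
#'
#' Smooths a series aligned to donor rank order with an even window
#' (default 20) anchored 10 positions before and 9 after each point.
#' Positions outside the series count as missing; a smoothed value is
#' emitted only where the window holds at most `max_missing` missing slots.
#'
#' @param values Numeric vector in rank order (`NA` allowed).
#' @param window Even window width.
#' @param max_missing Maximum number of missing/out-of-range slots tolerated.
#' @return Numeric vector aligned with `values`; `NA` where suppressed.
#' @export
centered_moving_average <- function(values, window = 20, max_missing = 10) {
  stopifnot(window %% 2 == 0, window > 0)
  n <- length(values)
  half <- window %/% 2
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    idx <- (i - half):(i + half - 1)
    inside <- idx >= 1 & idx <= n
    vals <- values[idx[inside]]
    n_missing <- (window - sum(inside)) + sum(is.na(vals))
    if (n_missing <= max_missing) out[i] <- mean(vals, na.rm = TRUE)
  }
  out
}

#' Least-squares regression on ranked data
#'
#' Ordinary least squares of y-ranks on x-ranks, the fitted line drawn
#' through ranked scatter plots. When both vectors are complete untied rank
#' sets the slope equals the Spearman correlation.
#'
#' @param x_ranks,y_ranks Numeric rank vectors (incomplete pairs dropped).
#' @return List with `slope` and `intercept`.
#' @export
ranked_regression <- function(x_ranks, y_ranks) {
  ok <- !is.na(x_ranks) & !is.na(y_ranks)
  if (sum(ok) < 2L) stop("ranked regression needs at least 2 complete pairs")
  x <- x_ranks[ok]; y <- y_ranks[ok]
  if (stats::var(x) == 0) stop("zero variance in x ranks")
  slope <- stats::cov(x, y) / stats::var(x)
  list(slope = slope, intercept = mean(y) - slope * mean(x))
}

#' Run the dimension-validation test battery
#'
#' Tests every requested dimension-covariate pair with the test matching the
#' covariate type (continuous: Spearman; binary: Mann-Whitney U on scores
#' between the two groups; multi-level: Kruskal-Wallis, optionally followed
#' by pairwise post-hoc Mann-Whitney tests kept in the same family), using
#' pairwise-complete data, then applies Benjamini-Hochberg FDR within each
#' family of closely related tests.
#'
#' @param scores Matrix or data frame of dimension scores (columns `dim1`,
#'   ...), rows aligned with `covariates`.
#' @param covariates Data frame of validation covariates (numeric columns
#'   are continuous; factor/logical columns categorical).
#' @param families Named list: family label -> character vector of covariate
#'   names belonging to that family. Every tested covariate must appear in
#'   exactly one family.
#' @param dims Dimension indices to test (default: all score columns).
#' @param fdr_threshold Significance cutoff on q (default 0.1).
#' @param posthoc Add pairwise Mann-Whitney contrasts after each
#'   Kruskal-Wallis test (same family).
#' @return Data frame of class `association_results` with columns `family`,
#'   `dimension`, `covariate`, `test`, `n_used`, `statistic`, `p_value`,
#'   `q_value`, `significant`.
#' @export
run_validation_battery <- function(scores, covariates, families,
                                   dims = NULL, fdr_threshold = 0.1,
                                   posthoc = TRUE) {
  scores <- as.matrix(scores)
  if (is.null(dims)) dims <- seq_len(ncol(scores))
  all_cov <- unlist(families)
  if (anyDuplicated(all_cov))
    stop("covariate(s) assigned to more than one family: ",
         paste(unique(all_cov[duplicated(all_cov)]), collapse = ", "))
  unknown <- setdiff(all_cov, names(covariates))
  if (length(unknown))
    stop("unknown covariate(s): ", paste(unknown, collapse = ", "))

  rows <- list()
  for (fam in names(families)) {
    for (cv in families[[fam]]) {
      v <- covariates[[cv]]
      if (is.logical(v)) v <- factor(ifelse(v, "yes", "no"))
      if (is.character(v)) v <- factor(v)
      for (s in dims) {
        f <- scores[, s]
        if (is.numeric(v)) {
          r <- spearman_test(f, v)
          rows[[length(rows) + 1]] <- data.frame(
            family = fam, dimension = s, covariate = cv, test = "spearman",
            n_used = r$n_used, statistic = r$statistic, p_value = r$p_value)
        } else if (nlevels(droplevels(v[!is.na(v)])) == 2L) {
          lv <- levels(droplevels(v[!is.na(v)]))
          r <- mann_whitney_test(f[!is.na(v) & v == lv[1]],
                                 f[!is.na(v) & v == lv[2]])
          rows[[length(rows) + 1]] <- data.frame(
            family = fam, dimension = s, covariate = cv, test = "mann_whitney",
            n_used = r$n_used, statistic = r$statistic, p_value = r$p_value)
        } else {
          r <- kruskal_wallis_test(f, v)
          rows[[length(rows) + 1]] <- data.frame(
            family = fam, dimension = s, covariate = cv, test = "kruskal_wallis",
            n_used = r$n_used, statistic = r$statistic, p_value = r$p_value)
          if (posthoc) {
            lv <- levels(droplevels(v[!is.na(v)]))
            for (i in seq_len(length(lv) - 1)) for (j in (i + 1):length(lv)) {
              rp <- mann_whitney_test(f[!is.na(v) & v == lv[i]],
                                      f[!is.na(v) & v == lv[j]])
              rows[[length(rows) + 1]] <- data.frame(
                family = fam, dimension = s,
                covariate = paste0(cv, ":", lv[i], "-", lv[j]),
                test = "mann_whitney_posthoc",
                n_used = rp$n_used, statistic = rp$statistic,
                p_value = rp$p_value)
            }
          }
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  out$q_value <- NA_real_
  out$significant <- NA
  for (fam in unique(out$family)) {
    sel <- out$family == fam
    adj <- bh_fdr(out$p_value[sel], threshold = fdr_threshold)
    out$q_value[sel] <- adj$q
    out$significant[sel] <- adj$significant
  }
  class(out) <- c("association_results", class(out))
  out
}
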
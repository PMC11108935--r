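#' FAMD preprocessing of a mixed table
#'
#' Builds the centered, scaled matrix on which factor analysis of mixed data
#' operates. Continuous columns are centered and divided by their population
#' standard deviation (divisor n), so each carries unit inertia. Each
#' categorical level's indicator column is divided by the square root of the
#' level proportion and centered, the multiple-correspondence-analysis
#' scaling under which a categorical variable with L observed levels carries
#' inertia L - 1. Fuzzy indicator rows (from imputation) are accepted;
#' level proportions are then the column means.
#'
#' @param x A `mixed_table` (or data frame) without missing cells.
#' @return List with the processed matrix `M` (n x P, uniform row weights
#'   1/n implied), the preprocessing parameters (`centers`, `scales`,
#'   `level_props`), the per-column owning variable `col_var`, and
#'   `total_inertia`.
#' @export
preprocess_mixed <- function(x) {
  mt <- mixed_table(x)
  if (has_missing(mt))
    stop("mixed table has missing cells; impute before FAMD preprocessing")
  n <- length(mt$ids)
  blocks <- list()
  col_var <- character(0)
  centers <- numeric(0)
  scales <- numeric(0)
  if (ncol(mt$cont) > 0) {
    mu <- colMeans(mt$cont)
    sdev <- sqrt(colMeans(sweep(mt$cont, 2, mu)^2))
    if (any(sdev == 0))
      stop("constant continuous column(s): ",
           paste(colnames(mt$cont)[sdev == 0], collapse = ", "))
    blocks$cont <- sweep(sweep(mt$cont, 2, mu), 2, sdev, "/")
    col_var <- c(col_var, colnames(mt$cont))
    centers <- mu
    scales <- sdev
  }
  level_props <- list()
  for (v in names(mt$cat)) {
    z <- mt$cat[[v]]
    p <- colMeans(z)
    if (any(p == 0)) {
      warning("dropping zero-frequency level(s) of '", v, "': ",
              paste(colnames(z)[p == 0], collapse = ", "))
      z <- z[, p > 0, drop = FALSE]
      p <- p[p > 0]
    }
    if (ncol(z) < 2L)
      stop("categorical variable '", v, "' has a single observed level")
    m <- sweep(sweep(z, 2, sqrt(p), "/"), 2, sqrt(p))
    colnames(m) <- paste(v, colnames(z), sep = ".")
    blocks[[v]] <- m
    col_var <- c(col_var, rep(v, ncol(m)))
    level_props[[v]] <- p
  }
  M <- do.call(cbind, unname(blocks))
  list(M = M, n = n, centers = centers, scales = scales,
       level_props = level_props, col_var = col_var,
       total_inertia = sum(colMeans(M^2)))
}

#' Factor analysis of mixed data
#'
#' Truncated weighted singular value decomposition of the FAMD-preprocessed
#' matrix (see [preprocess_mixed()]), balancing standardized continuous
#' variables against MCA-scaled categorical indicators. Eigenvalues are the
#' squared singular values under uniform row weights 1/n; donor scores are
#' principal coordinates; the contribution of donor i to dimension s is
#' 100 * F_is^2 / (n * lambda_s).
#'
#' @param x A `mixed_table` or data frame without missing cells (numeric
#'   columns continuous, factor/character/logical categorical). The completed
#'   table from [impute_famd()] can be passed directly, in which case
#'   imputed categorical cells enter fuzzily.
#' @param ncp Number of components to retain (default 12); silently capped
#'   at the matrix rank, with a warning if capping occurred.
#' @return Object of class `famd` with elements `eigenvalues` (full positive
#'   spectrum), `pct_variance`, `scores`, `donor_contrib`, `loadings`,
#'   `var_correlations` (continuous variables), `var_sq_cosines`,
#'   `var_contrib`, `total_inertia`, `ncp`, and the preprocessing parameters.
#' @examples
#' df <- data.frame(a = rnorm(30), b = rnorm(30),
#'                  g = factor(sample(c("x", "y"), 30, TRUE)))
#' fit <- famd(df)
#' fit$eigenvalues
#' @export
famd <- function(x, ncp = 12) {
  mt <- mixed_table(x)
  pp <- preprocess_mixed(mt)
  n <- pp$n
  sv <- svd(pp$M / sqrt(n))
  rank <- sum(sv$d > max(sv$d[1], 1) * 1e-10)
  lambda <- sv$d[seq_len(rank)]^2
  if (ncp > rank) {
    warning("ncp = ", ncp, " exceeds matrix rank ", rank, "; truncated")
    ncp <- rank
  }
  s_idx <- seq_len(ncp)
  scores <- sqrt(n) * sv$u[, s_idx, drop = FALSE] %*% diag(sv$d[s_idx], ncp)
  dimnames(scores) <- list(mt$ids, paste0("dim", s_idx))
  contrib <- 100 * scores^2 / (n * matrix(lambda[s_idx], n, ncp, byrow = TRUE))
  loadings <- sv$v[, s_idx, drop = FALSE]
  rownames(loadings) <- colnames(pp$M)
  colnames(loadings) <- colnames(scores)

  cont_names <- colnames(mt$cont)
  var_cor <- NULL
  if (length(cont_names)) {
    var_cor <- stats::cor(mt$cont, scores)
    rownames(var_cor) <- cont_names
  }
  vars <- c(cont_names, names(mt$cat))
  sq_cos <- matrix(NA_real_, length(vars), ncp, dimnames = list(vars, colnames(scores)))
  if (length(cont_names)) sq_cos[cont_names, ] <- var_cor^2
  for (v in names(mt$cat)) {
    z <- mt$cat[[v]]
    fit <- stats::lm.fit(cbind(1, z[, -1, drop = FALSE]), scores)
    res <- as.matrix(fit$residuals)
    tot <- colSums(sweep(scores, 2, colMeans(scores))^2)
    sq_cos[v, ] <- 1 - colSums(res^2) / tot
  }
  var_contrib <- matrix(0, length(vars), ncp, dimnames = dimnames(sq_cos))
  for (v in vars)
    var_contrib[v, ] <- 100 * colSums(loadings[pp$col_var == v, , drop = FALSE]^2)

  structure(list(eigenvalues = lambda,
                 pct_variance = 100 * lambda / pp$total_inertia,
                 total_inertia = pp$total_inertia,
                 scores = scores, donor_contrib = contrib,
                 loadings = loadings, var_correlations = var_cor,
                 var_sq_cosines = sq_cos, var_contrib = var_contrib,
                 centers = pp$centers, scales = pp$scales,
                 level_props = pp$level_props, col_var = pp$col_var,
                 n = n, ncp = ncp, ids = mt$ids),
            class = "famd")
}

#' @export
print.famd <- function(x, ...) {
  cat("Factor analysis of mixed data:", x$n, "observations,",
      length(x$col_var), "processed columns, total inertia",
      format(x$total_inertia, digits = 4), "\n")
  k <- min(length(x$eigenvalues), 5L)
  tab <- data.frame(eigenvalue = round(x$eigenvalues[1:k], 3),
                    pct_var = round(x$pct_variance[1:k], 2),
                    cum_pct = round(cumsum(x$pct_variance)[1:k], 2))
  rownames(tab) <- paste0("dim", 1:k)
  print(tab)
  invisible(x)
}

#' Select dimensions above an eigenvalue threshold
#'
#' @param fit A fitted `famd` object.
#' @param threshold Eigenvalue cutoff; dimensions with eigenvalue strictly
#'   greater are retained. Default 1.5.
#' @return Integer vector of dimension indices (possibly empty), in
#'   decreasing-eigenvalue order.
#' @export
select_dimensions <- function(fit, threshold = 1.5) {
  stopifnot(inherits(fit, "famd"))
  which(fit$eigenvalues[seq_len(fit$ncp)] > threshold)
}

#' Fix the sign of FAMD dimensions with anchor variables
#'
#' The SVD determines each dimension only up to sign. To make results
#' comparable across runs, each anchored dimension is negated if needed so
#' that the anchor variable's correlation with it is non-negative.
#'
#' @param fit A fitted `famd` object.
#' @param anchors Character vector of continuous variable names; position s
#'   anchors dimension s. `NA` entries leave a dimension untouched.
#' @return The `famd` object with scores, loadings and variable correlations
#'   sign-flipped where required; eigenvalues, squared cosines and
#'   contributions are unchanged.
#' @export
orient_dimensions <- function(fit, anchors) {
  stopifnot(inherits(fit, "famd"))
  for (s in seq_along(anchors)) {
    v <- anchors[s]
    if (is.na(v) || s > fit$ncp) next
    if (is.null(fit$var_correlations) || !v %in% rownames(fit$var_correlations))
      stop("anchor variable '", v, "' is not a continuous input variable")
    r <- fit$var_correlations[v, s]
    if (r == 0) {
      warning("anchor '", v, "' has zero correlation with dimension ", s,
              "; orientation unchanged")
      next
    }
    if (r < 0) {
      fit$scores[, s] <- -fit$scores[, s]
      fit$loadings[, s] <- -fit$loadings[, s]
      fit$var_correlations[, s] <- -fit$var_correlations[, s]
    }
  }
  fit
}

#' Variable-by-dimension summary table
#'
#' One row per (variable, dimension): signed correlation (continuous
#' variables only), squared cosine (quality of representation) and
#' percentage contribution. Contributions sum to 100 over variables within
#' each dimension.
#'
#' @param fit A fitted `famd` object.
#' @param dims Dimensions to tabulate; default all retained.
#' @return Data frame with columns `variable`, `dimension`, `correlation`,
#'   `sq_cosine`, `contribution`.
#' @export
variable_dimension_summary <- function(fit, dims = seq_len(fit$ncp)) {
  stopifnot(inherits(fit, "famd"))
  vars <- rownames(fit$var_sq_cosines)
  out <- expand.grid(variable = vars, dimension = dims,
                     stringsAsFactors = FALSE)
  out$correlation <- NA_real_
  cont <- rownames(fit$var_correlations)
  for (i in seq_len(nrow(out))) {
    v <- out$variable[i]; s <- out$dimension[i]
    if (!is.null(cont) && v %in% cont)
      out$correlation[i] <- fit$var_correlations[v, s]
  }
  idx <- cbind(match(out$variable, vars), out$dimension)
  out$sq_cosine <- fit$var_sq_cosines[idx]
  out$contribution <- fit$var_contrib[idx]
  out
}
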
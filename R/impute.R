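# Runs expr with a temporarily-seeded RNG, restoring the caller's stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Impute missing cells with regularized iterative FAMD
#'
#' Iterative low-rank imputation of a mixed table: missing continuous cells
#' are initialised with column means and missing categorical cells with the
#' observed level proportions; the completed table is FAMD-preprocessed, a
#' rank-`ncp` reconstruction with regularized (shrunk) singular values is
#' computed, and only the originally-missing cells are overwritten with the
#' fitted values, until the fitted values stabilise. The shrinkage replaces
#' each retained singular value d_s by (d_s^2 - sigma^2)/d_s (floored at 0),
#' where sigma^2 is the mean of the discarded eigenvalues -- the regularized
#' variant that guards against overfitting the missing cells.
#'
#' Imputed categorical cells are returned fuzzily: fractional indicator
#' weights clipped to [0, 1] and renormalised to sum to 1 per variable.
#' With `ncp = 0` the scheme reduces to mean/proportion imputation.
#'
#' @param x A `mixed_table` or data frame with missing cells (`NA`).
#' @param ncp Number of components of the reconstruction, typically chosen
#'   with [estimate_ncp()].
#' @param tol Convergence tolerance on the relative change of fitted values.
#' @param max_iter Iteration cap; non-convergence returns the current state
#'   with `converged = FALSE` and a warning.
#' @return Object of class `famd_imputation`: `completed` (a `mixed_table`
#'   with no missing cells, categorical cells possibly fuzzy),
#'   `imputed_mask`, `ncp`, `n_iterations`, `converged`, and `change_path`
#'   (relative change per iteration).
#' @export
impute_famd <- function(x, ncp, tol = 1e-6, max_iter = 1000) {
  mt <- mixed_table(x)
  stopifnot(ncp >= 0)
  mask <- missing_mask(mt)
  n <- length(mt$ids)

  if (!has_missing(mt)) {
    return(structure(list(completed = mt, imputed_mask = mask, ncp = ncp,
                          n_iterations = 0L, converged = TRUE,
                          change_path = numeric(0)),
                     class = "famd_imputation"))
  }

  # initialisation: column means / observed level proportions
  cur <- mt
  for (j in seq_len(ncol(cur$cont))) {
    mj <- mask$cont[, j]
    if (all(mj)) stop("continuous column '", colnames(cur$cont)[j],
                      "' is entirely missing")
    cur$cont[mj, j] <- mean(cur$cont[!mj, j])
  }
  for (v in names(cur$cat)) {
    mv <- mask$cat[, v]
    if (all(mv)) stop("categorical variable '", v, "' is entirely missing")
    if (any(mv)) {
      p <- colMeans(cur$cat[[v]][!mv, , drop = FALSE])
      cur$cat[[v]][mv, ] <- matrix(p, sum(mv), length(p), byrow = TRUE)
    }
  }

  fitted_cells <- function(m) {
    c(m$cont[mask$cont],
      unlist(lapply(names(m$cat), function(v) m$cat[[v]][mask$cat[, v], ])))
  }

  old_fit <- fitted_cells(cur)
  change_path <- numeric(0)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    pp <- preprocess_mixed(cur)
    if (ncp == 0) {
      Mhat <- matrix(0, n, ncol(pp$M))
    } else {
      sv <- svd(pp$M / sqrt(n))
      k <- min(ncp, sum(sv$d > max(sv$d[1], 1) * 1e-12))
      lam <- sv$d^2
      sigma2 <- if (length(lam) > k) mean(lam[(k + 1):length(lam)]) else 0
      shrunk <- pmax(lam[1:k] - sigma2, 0) / sv$d[1:k]
      Mhat <- sqrt(n) * sv$u[, 1:k, drop = FALSE] %*%
        (shrunk * t(sv$v[, 1:k, drop = FALSE]))
    }
    # back to original scale, overwrite missing cells only
    idx <- 0L
    if (ncol(cur$cont) > 0) {
      kc <- ncol(cur$cont)
      fit_cont <- sweep(sweep(Mhat[, 1:kc, drop = FALSE], 2, pp$scales, "*"),
                        2, pp$centers, "+")
      cur$cont[mask$cont] <- fit_cont[mask$cont]
      idx <- kc
    }
    for (v in names(cur$cat)) {
      p <- pp$level_props[[v]]
      L <- length(p)
      zf <- sweep(sweep(Mhat[, idx + seq_len(L), drop = FALSE], 2, sqrt(p), "*"),
                  2, p, "+")
      idx <- idx + L
      zf <- pmin(pmax(zf, 0), 1)
      rs <- rowSums(zf)
      if (any(rs == 0))
        zf[rs == 0, ] <- matrix(p, sum(rs == 0), L, byrow = TRUE)
      zf <- zf / rowSums(zf)
      mv <- mask$cat[, v]
      cur$cat[[v]][mv, ] <- zf[mv, , drop = FALSE]
    }
    new_fit <- fitted_cells(cur)
    change <- sum((new_fit - old_fit)^2) / max(sum(old_fit^2), .Machine$double.eps)
    change_path <- c(change_path, change)
    old_fit <- new_fit
    if (change < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("imputation did not converge in ", max_iter, " iterations")
  structure(list(completed = cur, imputed_mask = mask, ncp = ncp,
                 n_iterations = iter, converged = converged,
                 change_path = change_path),
            class = "famd_imputation")
}

#' @export
print.famd_imputation <- function(x, ...) {
  nmiss <- sum(x$imputed_mask$cont) + sum(x$imputed_mask$cat)
  cat("FAMD imputation: ncp =", x$ncp, ",", nmiss, "missing cells,",
      x$n_iterations, "iterations,",
      if (x$converged) "converged" else "NOT converged", "\n")
  invisible(x)
}

#' Cross-validated choice of the number of imputation components
#'
#' For each candidate number of components 0..`max_ncp`, repeatedly masks a
#' random fraction of the observed cells, imputes with [impute_famd()], and
#' scores the squared prediction error on the FAMD-preprocessed scale
#' (standardized continuous cells; indicator cells for categoricals). The
#' candidate minimising the mean error is returned (ties to the smaller).
#'
#' @param x A `mixed_table` or data frame (missing cells allowed).
#' @param max_ncp Largest candidate (default 12).
#' @param n_folds Number of random masking repetitions per candidate.
#' @param cell_fraction Fraction of observed cells masked per repetition.
#' @param seed Optional seed for the masking draws; the caller's RNG stream
#'   is left untouched.
#' @param tol,max_iter Passed to the inner [impute_famd()] calls.
#' @return Integer in `[0, max_ncp]`, with the per-candidate mean CV error
#'   attached as attribute `"cv_error"`.
#' @export
estimate_ncp <- function(x, max_ncp = 12, n_folds = 5, cell_fraction = 0.05,
                         seed = NULL, tol = 1e-4, max_iter = 200) {
  mt <- mixed_table(x)
  stopifnot(max_ncp >= 0, cell_fraction > 0, cell_fraction < 1)
  mask <- missing_mask(mt)
  n <- length(mt$ids)

  obs_cont <- which(!mask$cont)
  obs_cat <- lapply(colnames(mask$cat), function(v) which(!mask$cat[, v]))
  names(obs_cat) <- colnames(mask$cat)
  n_obs <- length(obs_cont) + sum(lengths(obs_cat))
  n_mask <- max(1L, round(cell_fraction * n_obs))

  # standardisation parameters from the observed data, fixed across folds
  mu <- sdv <- numeric(ncol(mt$cont))
  for (j in seq_len(ncol(mt$cont))) {
    v <- mt$cont[!mask$cont[, j], j]
    mu[j] <- mean(v)
    sdv[j] <- max(stats::sd(v), .Machine$double.eps)
  }

  draw_fold <- function() {
    for (try in 1:100) {
      take <- sample.int(n_obs, n_mask)
      cont_take <- obs_cont[take[take <= length(obs_cont)]]
      cat_take <- take[take > length(obs_cont)] - length(obs_cont)
      cat_sel <- lapply(seq_along(obs_cat), function(q) {
        off <- if (q == 1) 0 else sum(lengths(obs_cat)[1:(q - 1)])
        obs_cat[[q]][cat_take[cat_take > off & cat_take <= off + length(obs_cat[[q]])] - off]
      })
      names(cat_sel) <- names(obs_cat)
      m2 <- mt
      m2$cont[cont_take] <- NA_real_
      for (v in names(cat_sel)) m2$cat[[v]][cat_sel[[v]], ] <- NA_real_
      bad <- any(vapply(seq_len(ncol(m2$cont)),
                        function(j) all(is.na(m2$cont[, j])), logical(1))) ||
        any(vapply(m2$cat, function(z) all(is.na(z[, 1])), logical(1)))
      if (!bad) return(list(mt = m2, cont = cont_take, cat = cat_sel))
    }
    stop("could not draw a masking fold that keeps every variable observed")
  }

  err <- matrix(NA_real_, n_folds, max_ncp + 1)
  with_seed(seed, {
    for (f in seq_len(n_folds)) {
      fold <- draw_fold()
      for (k in 0:max_ncp) {
        imp <- impute_famd(fold$mt, ncp = k, tol = tol, max_iter = max_iter)
        se <- 0; m <- 0
        if (length(fold$cont)) {
          jj <- ((fold$cont - 1) %/% n) + 1
          se <- se + sum(((imp$completed$cont[fold$cont] - mt$cont[fold$cont]) / sdv[jj])^2)
          m <- m + length(fold$cont)
        }
        for (v in names(fold$cat)) {
          rows <- fold$cat[[v]]
          if (length(rows)) {
            se <- se + sum((imp$completed$cat[[v]][rows, , drop = FALSE] -
                              mt$cat[[v]][rows, , drop = FALSE])^2)
            m <- m + length(rows)
          }
        }
        err[f, k + 1] <- se / m
      }
    }
  })
  mean_err <- colMeans(err)
  best <- which.min(mean_err) - 1L
  structure(best, cv_error = stats::setNames(mean_err, 0:max_ncp))
}
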
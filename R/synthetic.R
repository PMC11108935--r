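#' Configuration of the synthetic cohort generator
#'
#' Defines the generative model of the synthetic autopsy cohort: three
#' independent standard-normal latent dimensions drive, through linear
#' predictors, (i) a 4-part white-matter lesion-type composition and a
#' 3-part microglia-morphology composition sampled multinomially from
#' logistic-normal probabilities (so the CLR stage recovers linear latent
#' structure, and real structural zeros arise from small counts), (ii)
#' negative-binomial brainstem lesion and reactive-site loads, (iii) a
#' gamma cortical lesion rate, and (iv) Bernoulli cuff/nodule presence via a
#' logistic link. The activation score is derived from the morphology counts
#' exactly as in the feature definitions. Missingness is MCAR with the
#' cohort's observed rates: lesion and reactive-site load jointly missing
#' for 14/228 donors, cortical lesion rate for 25/228. Validation covariates
#' are Gaussian copies of a designated latent calibrated (via the exact
#' Gaussian rank-correlation identity r = 2 sin(pi * rho / 6)) to hit a
#' target Spearman correlation.
#'
#' Latent-to-variable loadings mirror the structure the analysis expects:
#' latent 1 is an "immune activity & demyelination" axis (more lesions and
#' reactive sites, more active/mixed and foamy, cuffs and nodules), latent 2
#' a "microglia (re)activity" axis (more reactive sites, active and
#' ramified), latent 3 a "burnt-out lesion" axis (more mixed/inactive, fewer
#' cuffs).
#'
#' @param activation One of `"morphology"` (activation score computed from
#'   the morphology counts, as in real data) or `"independent"` (pure noise;
#'   useful for null simulations without derived-variable coupling).
#' @return Config list consumed by [generate_cohort()].
#' @export
cohort_config <- function(activation = c("morphology", "independent")) {
  list(
    activation = match.arg(activation),
    # rows = composition parts, cols = latents; columns sum to zero so the
    # structure lives entirely in CLR space
    wm_base = log(c(active = 0.15, mixed = 0.35, inactive = 0.35, remyel = 0.15)),
    wm_loadings = cbind(l1 = 0.85 * c(1, 1, -1, -1),
                        l2 = 0.68 * c(1, -1, 1, -1),
                        l3 = 0.72 * c(-1, 1, 1, -1)),
    wm_noise = 0.25,
    wm_total = list(mu = 40, size = 4, min = 6),
    mg_base = log(c(ramified = 0.4, ameboid = 0.3, foamy = 0.3)),
    mg_loadings = cbind(l1 = c(-0.95, 0, 0.95),
                        l2 = c(0.65, -1.3, 0.65),
                        l3 = c(0, 0, 0)),
    mg_noise = 0.25,
    mg_total = list(mu = 20, size = 3, min = 3),
    load = list(base = log(8), beta = c(0.35, 0, 0.85), size = 8),
    react = list(base = log(3), beta = c(0.3, 1.25, 0), size = 8),
    cort = list(base = log(0.8), beta = c(0.35, 0, 0.9), shape = 4),
    cuff = list(base = -0.2, beta = c(1.1, 0, -0.85)),
    nodule = list(base = 0.3, beta = c(0.4, 1.2, 0)),
    missing = list(loads = 14 / 228, cortical = 25 / 228),
    covariates = list(
      age_at_death = list(latent = 1, rho = -0.48, location = 66, scale = 12),
      time_to_edss6 = list(latent = 1, rho = -0.35, location = 14, scale = 7),
      disease_duration = list(latent = 3, rho = 0.20, location = 28, scale = 9),
      symptom_load_general = list(latent = 1, rho = 0.30, location = 1.4, scale = 0.6),
      age_at_onset = list(latent = 2, rho = 0.20, location = 38, scale = 10)
    )
  )
}

#' Generate a synthetic autopsy cohort with known latent structure
#'
#' Draws a cohort from the generative model described in [cohort_config()].
#' The returned input table has the schema expected by [prepare_input()]:
#' untransformed lesion-type and morphology proportions, activation score,
#' loads, cortical lesion rate and cuff/nodule presence, with `NA` for
#' missing cells.
#'
#' @param n Number of donors (>= 20).
#' @param config Generator configuration, see [cohort_config()].
#' @param seed Seed for the whole draw; the caller's RNG stream is left
#'   untouched. Identical seeds give identical cohorts.
#' @return List with `input` (donor-level feature data frame), `covariates`
#'   (validation covariate data frame) and `truth` (latent scores, loading
#'   configuration, covariate targets, missing rates, seed).
#' @export
generate_cohort <- function(n = 228, config = cohort_config(), seed = NULL) {
  stopifnot(n >= 20)
  for (cv in config$covariates)
    if (cv$latent > 3) stop("covariate references absent latent ", cv$latent)
  with_seed(seed, {
    L <- matrix(stats::rnorm(n * 3), n, 3)

    draw_comp <- function(base, loadings, noise_sd, total_cfg) {
      D <- length(base)
      eta <- matrix(base, n, D, byrow = TRUE) + L %*% t(loadings) +
        matrix(stats::rnorm(n * D, sd = noise_sd), n, D)
      pr <- exp(eta) / rowSums(exp(eta))
      tot <- pmax(stats::rnbinom(n, mu = total_cfg$mu, size = total_cfg$size),
                  total_cfg$min)
      cnt <- t(vapply(seq_len(n),
                      function(i) stats::rmultinom(1, tot[i], pr[i, ])[, 1],
                      numeric(D)))
      colnames(cnt) <- names(base)
      cnt
    }

    wm_cnt <- draw_comp(config$wm_base, config$wm_loadings, config$wm_noise,
                        config$wm_total)
    mg_cnt <- draw_comp(config$mg_base, config$mg_loadings, config$mg_noise,
                        config$mg_total)
    wm_prop <- wm_cnt / rowSums(wm_cnt)
    mg_prop <- mg_cnt / rowSums(mg_cnt)

    act <- if (config$activation == "morphology") {
      activation_score(mg_cnt[, "ramified"], mg_cnt[, "ameboid"], mg_cnt[, "foamy"])
    } else {
      pmin(pmax(stats::rnorm(n, 0.5, 0.2), 0), 1)
    }

    lload <- stats::rnbinom(n, mu = exp(config$load$base + L %*% config$load$beta),
                            size = config$load$size)
    rload <- stats::rnbinom(n, mu = exp(config$react$base + L %*% config$react$beta),
                            size = config$react$size)
    crate <- stats::rgamma(n, shape = config$cort$shape,
                           scale = exp(config$cort$base + L %*% config$cort$beta) /
                             config$cort$shape)
    cuff <- stats::rbinom(n, 1, stats::plogis(config$cuff$base + L %*% config$cuff$beta)) == 1
    nodule <- stats::rbinom(n, 1, stats::plogis(config$nodule$base + L %*% config$nodule$beta)) == 1

    # MCAR missingness at the cohort's observed rates
    n_load_miss <- round(config$missing$loads * n)
    n_cort_miss <- round(config$missing$cortical * n)
    if (n_load_miss > 0) {
      i <- sample.int(n, n_load_miss)
      lload[i] <- NA_integer_; rload[i] <- NA_integer_
    }
    if (n_cort_miss > 0) crate[sample.int(n, n_cort_miss)] <- NA_real_

    input <- data.frame(
      donor_id = sprintf("D%03d", seq_len(n)),
      wm_prop_active = wm_prop[, "active"], wm_prop_mixed = wm_prop[, "mixed"],
      wm_prop_inactive = wm_prop[, "inactive"],
      wm_prop_remyelinated = wm_prop[, "remyel"],
      mg_prop_ramified = mg_prop[, "ramified"],
      mg_prop_ameboid = mg_prop[, "ameboid"], mg_prop_foamy = mg_prop[, "foamy"],
      activation_score = act,
      lesion_load = as.numeric(lload), reactive_site_load = as.numeric(rload),
      cortical_lesion_rate = crate,
      cuff_present = cuff, nodule_present = nodule,
      stringsAsFactors = FALSE
    )

    covariates <- data.frame(donor_id = input$donor_id, stringsAsFactors = FALSE)
    for (nm in names(config$covariates)) {
      cv <- config$covariates[[nm]]
      r <- 2 * sin(pi * cv$rho / 6)
      z <- r * L[, cv$latent] + sqrt(1 - r^2) * stats::rnorm(n)
      covariates[[nm]] <- cv$location + abs(cv$scale) * z
    }

    truth <- list(latent_scores = L, config = config,
                  injected_outlier_ids = character(0),
                  target_covariate_correlations = lapply(config$covariates,
                                                         function(cv) cv[c("latent", "rho")]),
                  missing_rates = config$missing, seed = seed)
    list(input = input, covariates = covariates, truth = truth)
  })
}

#' Inject high-leverage outlier donors into a cohort
#'
#' Displaces the lesion load, reactive-site load and cortical lesion rate of
#' randomly chosen donors to `magnitude` IQRs beyond the cohort's adjusted
#' upper fence, producing donors that are simultaneously univariate outliers
#' and high contributors to the leading dimension -- the profile the outlier
#' loop is designed to remove. Donors are chosen among those with all three
#' variables observed so missingness is unchanged.
#'
#' @param input Cohort input table from [generate_cohort()].
#' @param n_outliers Number of donors to displace (< n/10).
#' @param magnitude Displacement beyond the upper fence, in IQR units
#'   (> 0).
#' @param seed Optional seed; caller's RNG untouched.
#' @return List with the modified `input` and `outlier_ids`.
#' @export
inject_outliers <- function(input, n_outliers, magnitude = 5, seed = NULL) {
  stopifnot(n_outliers >= 0)
  if (n_outliers == 0) return(list(input = input, outlier_ids = character(0)))
  if (magnitude <= 0) stop("magnitude must be positive")
  if (n_outliers >= nrow(input) / 10) stop("too many outliers requested")
  vars <- c("lesion_load", "reactive_site_load", "cortical_lesion_rate")
  eligible <- which(stats::complete.cases(input[, vars]))
  with_seed(seed, {
    pick <- sample(eligible, n_outliers)
    for (v in vars) {
      fen <- adjusted_fences(input[[v]][!is.na(input[[v]])])
      val <- fen$upper + magnitude * fen$iqr
      if (v != "cortical_lesion_rate") val <- ceiling(val)
      input[[v]][pick] <- val
    }
    list(input = input, outlier_ids = input$donor_id[pick])
  })
}
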
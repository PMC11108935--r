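#' Pipeline configuration
#'
#' Collects every tunable of the dimension-discovery pipeline in one
#' auditable object: the eigenvalue threshold for dimension selection, the
#' imputation settings (cross-validated or fixed number of components,
#' capped at 12), the outlier-loop bounds, the sign anchors of the
#' dimensions, and the FDR threshold of the validation battery.
#'
#' @param eigen_threshold Dimensions with eigenvalue strictly above this are
#'   retained (default 1.5).
#' @param max_ncp Cap on the number of imputation components (default 12).
#' @param ncp Fixed number of imputation components; `NULL` (default) means
#'   cross-validate with [estimate_ncp()] each round.
#' @param n_folds,cell_fraction Cross-validation settings for
#'   [estimate_ncp()].
#' @param famd_ncp Number of FAMD components computed (default 12, capped at
#'   the matrix rank).
#' @param max_rounds Cap on imputation/FAMD/outlier-removal rounds.
#' @param cohort_floor Abort if the cohort shrinks below this size.
#' @param anchors Continuous variables fixing the sign of dimensions 1..3
#'   (correlation forced non-negative).
#' @param fdr_threshold Significance cutoff on q in the validation battery.
#' @param delta Optional fixed zero-replacement deltas, list with `wm`, `mg`.
#' @param tol,max_iter Convergence control of [impute_famd()].
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(eigen_threshold = 1.5, max_ncp = 12, ncp = NULL,
                            n_folds = 5, cell_fraction = 0.05, famd_ncp = 12,
                            max_rounds = 10, cohort_floor = 50,
                            anchors = c("lesion_load", "wm_clr_active",
                                        "cortical_lesion_rate"),
                            fdr_threshold = 0.1,
                            delta = list(wm = NULL, mg = NULL),
                            tol = 1e-6, max_iter = 1000) {
  stopifnot(eigen_threshold > 0, max_ncp >= 1, max_rounds >= 1)
  structure(list(eigen_threshold = eigen_threshold, max_ncp = max_ncp,
                 ncp = ncp, n_folds = n_folds, cell_fraction = cell_fraction,
                 famd_ncp = famd_ncp, max_rounds = max_rounds,
                 cohort_floor = cohort_floor, anchors = anchors,
                 fdr_threshold = fdr_threshold, delta = delta,
                 tol = tol, max_iter = max_iter),
            class = "pipeline_config")
}

#' Build the 13-variable mixed input table
#'
#' Transforms a donor-level feature table (proportions, counts, rate,
#' binaries -- the schema produced by [generate_cohort()] or assembled from
#' [derive_features()] output) into the mixed table the factorisation
#' consumes: zero-replaced, CLR-transformed white-matter and morphology
#' compositions; activation score, lesion load, reactive-site load and
#' cortical lesion rate as continuous columns; cuff and nodule as two-level
#' factors. CLR is applied per compositional block, never across blocks.
#'
#' @param input Data frame with columns `donor_id`, `wm_prop_*` (4),
#'   `mg_prop_*` (3), `activation_score`, `lesion_load`,
#'   `reactive_site_load`, `cortical_lesion_rate`, `cuff_present`,
#'   `nodule_present`.
#' @param delta Optional list with per-block zero-replacement deltas
#'   (`wm`, `mg`); defaults derive from the smallest nonzero observed part.
#' @return Data frame with `donor_id` and the 13 input variables; deltas
#'   used attached as attribute `"delta"`.
#' @export
prepare_input <- function(input, delta = list(wm = NULL, mg = NULL)) {
  wm_cols <- c("wm_prop_active", "wm_prop_mixed", "wm_prop_inactive",
               "wm_prop_remyelinated")
  mg_cols <- c("mg_prop_ramified", "mg_prop_ameboid", "mg_prop_foamy")
  need <- c("donor_id", wm_cols, mg_cols, "activation_score", "lesion_load",
            "reactive_site_load", "cortical_lesion_rate", "cuff_present",
            "nodule_present")
  miss <- setdiff(need, names(input))
  if (length(miss)) stop("missing input columns: ", paste(miss, collapse = ", "))
  wm <- replace_zeros(as.matrix(input[, wm_cols]), delta = delta$wm)
  mg <- replace_zeros(as.matrix(input[, mg_cols]), delta = delta$mg)
  wm_clr <- clr_transform(wm)
  mg_clr <- clr_transform(mg)
  out <- data.frame(
    donor_id = as.character(input$donor_id),
    wm_clr_active = wm_clr[, 1], wm_clr_mixed = wm_clr[, 2],
    wm_clr_inactive = wm_clr[, 3], wm_clr_remyelinated = wm_clr[, 4],
    mg_clr_ramified = mg_clr[, 1], mg_clr_ameboid = mg_clr[, 2],
    mg_clr_foamy = mg_clr[, 3],
    activation_score = input$activation_score,
    lesion_load = input$lesion_load,
    reactive_site_load = input$reactive_site_load,
    cortical_lesion_rate = input$cortical_lesion_rate,
    cuff = factor(ifelse(input$cuff_present, "yes", "no"), levels = c("no", "yes")),
    nodule = factor(ifelse(input$nodule_present, "yes", "no"), levels = c("no", "yes")),
    stringsAsFactors = FALSE
  )
  attr(out, "delta") <- list(wm = attr(wm, "delta"), mg = attr(mg, "delta"))
  out
}

#' Run the iterative imputation / FAMD / outlier-removal pipeline
#'
#' The core loop of the analysis: impute missing cells (re-estimating the
#' number of imputation components each round unless fixed), fit the FAMD,
#' select dimensions above the eigenvalue threshold, detect donors meeting
#' both adjusted-boxplot outlier criteria, remove them, and repeat on the
#' reduced raw table until no donor is removed (or the round cap is hit).
#' The final model, fitted on the surviving cohort, is sign-anchored with
#' [orient_dimensions()].
#'
#' @param table13 The 13-variable mixed input table from [prepare_input()]
#'   (missing cells allowed).
#' @param config A [pipeline_config()].
#' @param seed Seed driving the cross-validation fold draws (one derived
#'   seed per round); imputation and FAMD are deterministic given ncp.
#' @return Object of class `dimension_fit`: final `model` (oriented `famd`),
#'   `selected_dims`, `outlier_reports` (one per round), `removed` (donor
#'   ids per round), `ncp_history`, `n_final`, `table_final` (surviving raw
#'   table), `imputation` (final round), and `config`.
#' @export
run_dimension_pipeline <- function(table13, config = pipeline_config(),
                                   seed = NULL) {
  current <- table13
  reports <- list()
  removed <- list()
  ncp_hist <- integer(0)
  for (round in seq_len(config$max_rounds)) {
    if (nrow(current) < config$cohort_floor)
      stop("cohort shrank below the floor of ", config$cohort_floor, " donors")
    ncp <- if (!is.null(config$ncp)) config$ncp else {
      estimate_ncp(current, max_ncp = config$max_ncp,
                   n_folds = config$n_folds,
                   cell_fraction = config$cell_fraction,
                   seed = if (is.null(seed)) NULL else seed + round)
    }
    ncp_hist <- c(ncp_hist, as.integer(ncp))
    imp <- impute_famd(current, ncp = ncp, tol = config$tol,
                       max_iter = config$max_iter)
    fit <- famd(imp$completed, ncp = config$famd_ncp)
    dims <- select_dimensions(fit, config$eigen_threshold)
    rep <- detect_outliers(fit, current, dims, iteration = round)
    reports[[round]] <- rep
    if (length(rep$removed) == 0L) {
      usable <- ifelse(config$anchors %in% rownames(fit$var_correlations),
                       config$anchors, NA_character_)
      fit <- orient_dimensions(fit, usable)
      return(structure(list(model = fit, selected_dims = dims,
                            outlier_reports = reports, removed = removed,
                            ncp_history = ncp_hist,
                            n_final = nrow(current), table_final = current,
                            imputation = imp, config = config),
                       class = "dimension_fit"))
    }
    removed[[round]] <- rep$removed
    current <- current[!current$donor_id %in% rep$removed, , drop = FALSE]
  }
  stop("outlier loop did not reach a fixed point in ", config$max_rounds,
       " rounds")
}

#' @export
print.dimension_fit <- function(x, ...) {
  cat("Neuropathology dimension fit\n")
  cat("  final cohort:", x$n_final, "donors;",
      length(unlist(x$removed)), "removed in", length(x$removed), "round(s)\n")
  cat("  ncp per round:", paste(x$ncp_history, collapse = ", "), "\n")
  cat("  selected dimensions (eigenvalue > ", x$config$eigen_threshold, "): ",
      paste(x$selected_dims, collapse = ", "), "\n", sep = "")
  k <- seq_len(min(length(x$model$eigenvalues), max(x$selected_dims, 3)))
  cat("  eigenvalues:",
      paste(sprintf("%.2f (%.2f%%)", x$model$eigenvalues[k],
                    x$model$pct_variance[k]), collapse = ", "), "\n")
  invisible(x)
}

#' Donor score table under both rank conventions
#'
#' @param fit A `dimension_fit` or `famd` object.
#' @param dims Dimensions to tabulate (default: selected, or all).
#' @return Data frame with `donor_id`, per-dimension scores, mid-ranks
#'   (`rank_avg_*`) and unique order-of-appearance ranks (`rank_unique_*`).
#' @export
donor_score_table <- function(fit, dims = NULL) {
  model <- if (inherits(fit, "dimension_fit")) fit$model else fit
  stopifnot(inherits(model, "famd"))
  if (is.null(dims))
    dims <- if (inherits(fit, "dimension_fit")) fit$selected_dims
            else seq_len(model$ncp)
  out <- data.frame(donor_id = model$ids, stringsAsFactors = FALSE)
  for (s in dims) {
    f <- model$scores[, s]
    out[[paste0("dim", s)]] <- f
    out[[paste0("rank_avg_dim", s)]] <- as.numeric(rank_values(f, "averaged"))
    out[[paste0("rank_unique_dim", s)]] <- as.numeric(rank_values(f, "order_of_appearance"))
  }
  out
}

#' Write the pipeline's result tables and log
#'
#' Emits the eigenvalue table, the donor score table (both rank
#' conventions), the variable-by-dimension summary, the per-round outlier
#' reports, and a JSON log capturing every configuration value, seed, and
#' removal decision -- enough to re-derive the run.
#'
#' @param fit A `dimension_fit`.
#' @param dir Output directory (created if needed).
#' @param seed Seed used for the run, recorded in the log.
#' @return Invisibly, the paths written.
#' @export
write_pipeline_results <- function(fit, dir, seed = NULL) {
  stopifnot(inherits(fit, "dimension_fit"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  m <- fit$model
  eig <- data.frame(dimension = seq_along(m$eigenvalues),
                    eigenvalue = m$eigenvalues,
                    pct_variance = m$pct_variance,
                    cum_pct_variance = cumsum(m$pct_variance))
  p1 <- file.path(dir, "eigenvalues.csv")
  utils::write.csv(eig, p1, row.names = FALSE)
  p2 <- file.path(dir, "donor_scores.csv")
  utils::write.csv(donor_score_table(fit), p2, row.names = FALSE)
  p3 <- file.path(dir, "variable_summary.csv")
  utils::write.csv(variable_dimension_summary(m, fit$selected_dims), p3,
                   row.names = FALSE)
  log <- list(
    config = fit$config[setdiff(names(fit$config), "delta")],
    delta = attr(fit$table_final, "delta"),
    seed = seed,
    ncp_history = fit$ncp_history,
    rounds = lapply(fit$outlier_reports, function(r) list(
      iteration = r$iteration,
      contribution_flagged = r$contribution_flags,
      univariate_flagged = r$univariate_flags,
      removed = r$removed)),
    n_final = fit$n_final,
    selected_dims = fit$selected_dims,
    eigenvalues = m$eigenvalues,
    imputation = list(ncp = fit$imputation$ncp,
                      iterations = fit$imputation$n_iterations,
                      converged = fit$imputation$converged)
  )
  p4 <- file.path(dir, "pipeline_log.json")
  jsonlite::write_json(log, p4, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(c(p1, p2, p3, p4))
}

#' Read a donor feature table written by this package
#'
#' @param path CSV path with the [prepare_input()] input schema.
#' @return Data frame with logical cuff/nodule columns.
#' @export
read_feature_table <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (v in c("cuff_present", "nodule_present"))
    if (v %in% names(x) && !is.logical(x[[v]])) x[[v]] <- as.logical(x[[v]])
  x
}
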
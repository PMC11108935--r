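#' Donor-level neuropathology features
#'
#' These helpers derive the donor-level summaries that constitute the input
#' and validation variables of the dimension-discovery pipeline: white-matter
#' lesion-type proportions, brainstem lesion and reactive-site loads, the
#' cortical lesion rate, the microglia/macrophage activation score, binary
#' presence of perivascular cuffs and microglia nodules, grey-matter lesion
#' proportions, and the per-domain symptom load and median onset age.
#'
#' All functions are vectorised over donors where that is natural and return
#' `NA` (with a warning where informative) when the quantity is undefined,
#' e.g. a proportion with zero total lesions. A donor whose standard blocks
#' were assessed but lesion-free gets a 0 load; a donor with no assessed
#' standard blocks gets `NA` -- zero and missing are deliberately distinct.
#'
#' @name features
NULL

#' White-matter lesion-type proportions
#'
#' Proportions of active, mixed, inactive and remyelinated lesions relative
#' to the total number of demyelinating white-matter lesions over all
#' dissected blocks. Reactive sites are not demyelinated and are excluded
#' from both numerator and denominator.
#'
#' @param active,mixed,inactive,remyelinated Integer lesion counts per donor
#'   over all dissected blocks.
#' @return A matrix with one row per donor and columns
#'   `active`, `mixed`, `inactive`, `remyelinated`, each row summing to 1.
#'   Donors with zero total lesions get an `NA` row with a warning.
#' @export
lesion_type_proportions <- function(active, mixed, inactive, remyelinated) {
  cnt <- cbind(active = active, mixed = mixed, inactive = inactive,
               remyelinated = remyelinated)
  if (any(cnt < 0, na.rm = TRUE)) stop("lesion counts must be non-negative")
  tot <- rowSums(cnt)
  undef <- !is.na(tot) & tot == 0
  if (any(undef))
    warning(sum(undef), " donor(s) with zero white-matter lesions: proportions set to NA")
  tot[undef] <- NA_real_
  cnt / tot
}

#' Brainstem lesion load
#'
#' Total number of demyelinating lesions (active + mixed + inactive +
#' remyelinated) in the standardly dissected brainstem blocks. Reactive sites
#' are excluded. Returns `NA` when the brainstem counts are missing (no
#' standard blocks dissected).
#'
#' @param active,mixed,inactive,remyelinated Integer counts in standard
#'   brainstem blocks; `NA` when unassessed.
#' @return Integer vector of loads, `NA` where brainstem data is missing.
#' @export
lesion_load <- function(active, mixed, inactive, remyelinated) {
  cnt <- cbind(active, mixed, inactive, remyelinated)
  if (any(cnt < 0, na.rm = TRUE)) stop("lesion counts must be non-negative")
  rowSums(cnt)
}

#' Brainstem reactive site load
#'
#' Total number of reactive sites (HLA+ microglia clusters without
#' demyelination) in the standard brainstem blocks.
#'
#' @param reactive Integer count of reactive sites in standard brainstem
#'   blocks; `NA` when unassessed.
#' @return Integer vector, `NA` where missing.
#' @export
reactive_site_load <- function(reactive) {
  if (any(reactive < 0, na.rm = TRUE)) stop("counts must be non-negative")
  reactive
}

#' Cortical lesion rate
#'
#' Number of cortical lesions per dissected tissue block containing cortex.
#' Donors without any cortical block get `NA` (the rate is undefined, not
#' zero).
#'
#' @param n_lesions Total cortical lesion count per donor.
#' @param n_blocks Number of dissected blocks containing cortex.
#' @return Numeric vector of rates.
#' @export
cortical_lesion_rate <- function(n_lesions, n_blocks) {
  if (any(n_lesions < 0, na.rm = TRUE) || any(n_blocks < 0, na.rm = TRUE))
    stop("counts must be non-negative")
  rate <- n_lesions / n_blocks
  rate[!is.na(n_blocks) & n_blocks == 0] <- NA_real_
  rate
}

#' Microglia/macrophage activation score
#'
#' Scores the predominant microglia morphology of each active or mixed lesion
#' (ramified = 0, ameboid = 0.5, foamy = 1) and averages over a donor's
#' scorable lesions. Donors without scorable lesions get `NA`.
#'
#' @param ramified,ameboid,foamy Counts of active+mixed lesions whose
#'   predominant morphology falls in each class.
#' @return Numeric vector in `[0, 1]`.
#' @export
activation_score <- function(ramified, ameboid, foamy) {
  cnt <- cbind(ramified, ameboid, foamy)
  if (any(cnt < 0, na.rm = TRUE)) stop("morphology counts must be non-negative")
  tot <- rowSums(cnt)
  score <- unname((0 * cnt[, 1] + 0.5 * cnt[, 2] + 1 * cnt[, 3]) / tot)
  score[!is.na(tot) & tot == 0] <- NA_real_
  score
}

#' Donor-level presence from per-block assessments
#'
#' Collapses per-block presence/absence flags (e.g. perivascular cuffs,
#' microglia nodules) to a single donor-level binary: present iff observed in
#' at least one assessed block. No assessed blocks gives `NA`.
#'
#' @param flags Logical vector of per-block flags for one donor; `NA` entries
#'   (unassessable blocks) are ignored.
#' @return `TRUE`, `FALSE`, or `NA` when no block was assessed.
#' @export
binarize_presence <- function(flags) {
  flags <- flags[!is.na(flags)]
  if (length(flags) == 0L) return(NA)
  any(flags)
}

#' Symptom load of a clinical domain
#'
#' Lifetime number of observations of all attributes within a symptom domain,
#' divided by the donor's disease duration in years.
#'
#' @param n_observations Total lifetime observation count.
#' @param duration Disease duration in years; must be positive, `NA`
#'   otherwise.
#' @return Observations per year; `NA` where duration is missing or
#'   non-positive.
#' @export
symptom_load <- function(n_observations, duration) {
  if (any(n_observations < 0, na.rm = TRUE)) stop("observation counts must be non-negative")
  load <- n_observations / duration
  load[is.na(duration) | duration <= 0] <- NA_real_
  load
}

#' Median age at onset of a clinical domain
#'
#' Median over the ages at which each attribute of the domain was first
#' observed; for an even number of onset ages the midpoint of the two central
#' values is used.
#'
#' @param onset_ages Numeric vector of first-onset ages (years) for one
#'   donor; `NA` entries are dropped.
#' @return Median onset age, or `NA` when no onset was recorded.
#' @export
median_domain_onset <- function(onset_ages) {
  onset_ages <- onset_ages[!is.na(onset_ages)]
  if (length(onset_ages) == 0L) return(NA_real_)
  if (any(onset_ages < 0)) stop("onset ages must be non-negative")
  stats::median(onset_ages)
}

#' Grey-matter lesion-type proportions
#'
#' Relative proportions of leukocortical, intracortical and subpial lesions,
#' defined only for donors with at least one cortical lesion.
#'
#' @param leukocortical,intracortical,subpial Integer cortical lesion counts
#'   per donor.
#' @return Matrix with one row per donor, rows summing to 1; `NA` rows where
#'   no cortical lesion was present.
#' @export
grey_matter_proportions <- function(leukocortical, intracortical, subpial) {
  cnt <- cbind(leukocortical = leukocortical, intracortical = intracortical,
               subpial = subpial)
  if (any(cnt < 0, na.rm = TRUE)) stop("lesion counts must be non-negative")
  tot <- rowSums(cnt)
  tot[!is.na(tot) & tot == 0] <- NA_real_
  cnt / tot
}

#' Derive the mixed input table from raw donor records
#'
#' Builds the 13-variable mixed input table of the dimension pipeline from a
#' tidy per-donor record of raw counts: CLR-transformed white-matter
#' lesion-type proportions (4), CLR-transformed microglia morphology
#' proportions (3), activation score, lesion load, reactive site load,
#' cortical lesion rate (continuous), and cuff/nodule presence (binary
#' factors). Compositional blocks are zero-replaced and CLR-transformed
#' per block, never across blocks.
#'
#' @param records Data frame with one row per donor and columns
#'   `donor_id`,
#'   `bs_reactive`, `bs_active`, `bs_mixed`, `bs_inactive`, `bs_remyelinated`
#'   (standard brainstem blocks; `NA` when not dissected),
#'   `wm_active`, `wm_mixed`, `wm_inactive`, `wm_remyelinated` (all blocks),
#'   `mg_ramified`, `mg_ameboid`, `mg_foamy` (morphology of active+mixed
#'   lesions), `cortical_blocks`, `cortical_lesions`, and logical
#'   `cuff_present`, `nodule_present`.
#' @param delta Optional named list with elements `wm` and `mg` giving the
#'   zero-replacement delta per compositional block; default derives each
#'   from the smallest nonzero observed part of that block.
#' @return Data frame with `donor_id` plus the 13 input variables
#'   (`wm_clr_*`, `mg_clr_*`, `activation_score`, `lesion_load`,
#'   `reactive_site_load`, `cortical_lesion_rate`, `cuff`, `nodule`).
#'   Deltas used are attached as attribute `"delta"`.
#' @export
derive_features <- function(records, delta = list(wm = NULL, mg = NULL)) {
  need <- c("donor_id", "bs_reactive", "bs_active", "bs_mixed", "bs_inactive",
            "bs_remyelinated", "wm_active", "wm_mixed", "wm_inactive",
            "wm_remyelinated", "mg_ramified", "mg_ameboid", "mg_foamy",
            "cortical_blocks", "cortical_lesions", "cuff_present",
            "nodule_present")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("missing record columns: ", paste(miss, collapse = ", "))

  wm <- lesion_type_proportions(records$wm_active, records$wm_mixed,
                                records$wm_inactive, records$wm_remyelinated)
  mg_tot <- records$mg_ramified + records$mg_ameboid + records$mg_foamy
  mg <- cbind(ramified = records$mg_ramified, ameboid = records$mg_ameboid,
              foamy = records$mg_foamy)
  mg <- mg / ifelse(!is.na(mg_tot) & mg_tot > 0, mg_tot, NA_real_)

  wm_rz <- replace_zeros(wm, delta = delta$wm)
  mg_rz <- replace_zeros(mg, delta = delta$mg)
  wm_clr <- clr_transform(wm_rz)
  mg_clr <- clr_transform(mg_rz)
  d_used <- list(wm = attr(wm_rz, "delta"), mg = attr(mg_rz, "delta"))

  out <- data.frame(
    donor_id = as.character(records$donor_id),
    wm_clr_active = wm_clr[, "active"],
    wm_clr_mixed = wm_clr[, "mixed"],
    wm_clr_inactive = wm_clr[, "inactive"],
    wm_clr_remyelinated = wm_clr[, "remyelinated"],
    mg_clr_ramified = mg_clr[, "ramified"],
    mg_clr_ameboid = mg_clr[, "ameboid"],
    mg_clr_foamy = mg_clr[, "foamy"],
    activation_score = activation_score(records$mg_ramified,
                                        records$mg_ameboid, records$mg_foamy),
    lesion_load = lesion_load(records$bs_active, records$bs_mixed,
                              records$bs_inactive, records$bs_remyelinated),
    reactive_site_load = reactive_site_load(records$bs_reactive),
    cortical_lesion_rate = cortical_lesion_rate(records$cortical_lesions,
                                                records$cortical_blocks),
    cuff = factor(ifelse(records$cuff_present, "yes", "no"),
                  levels = c("no", "yes")),
    nodule = factor(ifelse(records$nodule_present, "yes", "no"),
                    levels = c("no", "yes")),
    stringsAsFactors = FALSE
  )
  attr(out, "delta") <- d_used
  out
}
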
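#' Mixed continuous/categorical table
#'
#' Internal canonical representation of an n x K table of mixed variables:
#' a continuous block (numeric matrix, `NA` allowed) and a categorical block
#' stored as one indicator matrix per variable. Indicator rows may be fuzzy
#' (fractional weights summing to 1), which is how imputed categorical cells
#' enter the factorisation; a missing categorical cell is an all-`NA`
#' indicator row.
#'
#' @param x Data frame with one row per observation. Numeric columns form the
#'   continuous block; factor, character and logical columns the categorical
#'   block. A `donor_id` column (or row names) provides observation ids.
#' @return Object of class `mixed_table` with elements `ids`, `cont`
#'   (n x Kc numeric matrix), `cat` (named list of n x L indicator matrices)
#'   and `cat_levels`.
#' @export
mixed_table <- function(x) {
  if (inherits(x, "mixed_table")) return(x)
  stopifnot(is.data.frame(x))
  ids <- if ("donor_id" %in% names(x)) as.character(x$donor_id) else {
    if (is.null(rownames(x))) as.character(seq_len(nrow(x))) else rownames(x)
  }
  x <- x[, setdiff(names(x), "donor_id"), drop = FALSE]
  if (nrow(x) < 3L) stop("a mixed table needs at least 3 rows")
  is_cont <- vapply(x, is.numeric, logical(1))
  cont <- as.matrix(x[, is_cont, drop = FALSE])
  storage.mode(cont) <- "double"
  cat_cols <- names(x)[!is_cont]
  cat <- list()
  cat_levels <- list()
  for (v in cat_cols) {
    f <- x[[v]]
    if (is.logical(f)) f <- factor(ifelse(f, "yes", "no"), levels = c("no", "yes"))
    f <- as.factor(f)
    lev <- levels(f)
    if (length(lev) < 2L)
      stop("categorical variable '", v, "' has fewer than 2 levels")
    z <- matrix(0, nrow(x), length(lev), dimnames = list(NULL, lev))
    z[cbind(seq_len(nrow(x)), as.integer(f))] <- 1
    z[is.na(f), ] <- NA_real_
    cat[[v]] <- z
    cat_levels[[v]] <- lev
  }
  structure(list(ids = ids, cont = cont, cat = cat, cat_levels = cat_levels),
            class = "mixed_table")
}

#' @export
print.mixed_table <- function(x, ...) {
  cat("mixed_table:", length(x$ids), "observations,",
      ncol(x$cont), "continuous and", length(x$cat), "categorical variables\n")
  nmiss <- sum(is.na(x$cont)) + sum(vapply(x$cat, function(z) sum(is.na(z[, 1])), 0))
  cat("  missing cells:", nmiss, "\n")
  invisible(x)
}

#' @export
dim.mixed_table <- function(x) {
  c(length(x$ids), ncol(x$cont) + length(x$cat))
}

# TRUE where a cell is missing; continuous cells and one flag per
# categorical variable (a missing categorical cell is a whole NA row).
missing_mask <- function(mt) {
  list(cont = is.na(mt$cont),
       cat = vapply(mt$cat, function(z) is.na(z[, 1]), logical(length(mt$ids))))
}

has_missing <- function(mt) {
  m <- missing_mask(mt)
  any(m$cont) || any(unlist(m$cat))
}

# Subset rows of a mixed table.
mt_subset <- function(mt, keep) {
  structure(list(ids = mt$ids[keep],
                 cont = mt$cont[keep, , drop = FALSE],
                 cat = lapply(mt$cat, function(z) z[keep, , drop = FALSE]),
                 cat_levels = mt$cat_levels),
            class = "mixed_table")
}

# Back-conversion for reporting: hard-assigns fuzzy categorical cells to
# their highest-weight level.
#' Convert a mixed table back to a data frame
#'
#' Fuzzy categorical cells (from imputation) are hard-assigned to the level
#' with the largest weight.
#'
#' @param x A `mixed_table`.
#' @param ... Unused.
#' @return Data frame with `donor_id` first.
#' @export
as.data.frame.mixed_table <- function(x, ...) {
  out <- data.frame(donor_id = x$ids, stringsAsFactors = FALSE)
  for (j in colnames(x$cont)) out[[j]] <- x$cont[, j]
  for (v in names(x$cat)) {
    z <- x$cat[[v]]
    lab <- ifelse(is.na(z[, 1]), NA_character_,
                  colnames(z)[max.col(replace(z, is.na(z), 0), "first")])
    out[[v]] <- factor(lab, levels = x$cat_levels[[v]])
  }
  out
}
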
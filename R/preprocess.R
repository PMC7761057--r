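#' Log-transform and standardize metabolite abundances
#'
#' Per metabolite, natural-log transforms the observed (present) values and
#' centres/scales them so they have mean 0 and variance 1 (n - 1
#' denominator). Missing cells are untouched. A metabolite with fewer than
#' two observed values, or zero variance among them, is log-transformed but
#' left unscaled and reported in the `"unscaled"` attribute.
#'
#' Standardization statistics are computed on observed values only; missing
#' cells cannot contribute.
#'
#' @param table Numeric matrix (samples x metabolites) with strictly positive
#'   present values.
#' @return The transformed matrix, with attributes `"unscaled"` (metabolite
#'   ids left unscaled), `"center"` and `"scale"` (named vectors of the
#'   log-scale means and SDs used for scaled metabolites).
#' @export
log_standardize <- function(table) {
  validate_metabolite_table(table)
  bad <- which(!is.na(table) & table <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop("nonpositive abundance at sample '", rownames(table)[bad[1L, 1L]],
         "', metabolite '", colnames(table)[bad[1L, 2L]],
         "'; log transform requires strictly positive values")
  out <- log(table)
  unscaled <- character(0)
  ctr <- scl <- stats::setNames(numeric(0), character(0))
  for (j in seq_len(ncol(out))) {
    v <- out[, j]
    obs <- which(!is.na(v))
    s <- if (length(obs) >= 2L) stats::sd(v[obs]) else NA_real_
    if (length(obs) < 2L || !is.finite(s) || s == 0) {
      unscaled <- c(unscaled, colnames(out)[j])
      next
    }
    m <- mean(v[obs])
    out[obs, j] <- (v[obs] - m) / s
    ctr[colnames(out)[j]] <- m
    scl[colnames(out)[j]] <- s
  }
  structure(out, unscaled = unscaled, center = ctr, scale = scl)
}

#' Route metabolites to an imputation strategy
#'
#' Builds the imputation plan from the class annotations and per-metabolite
#' missing fractions:
#' * xenobiotic metabolites with any missing cell -> zero imputation
#'   (absence is read as true absence);
#' * non-xenobiotic metabolites with missing fraction >= `cutoff` -> zero
#'   imputation, and recorded as *reclassified* (treated as xenobiotic);
#' * non-xenobiotic metabolites with missing fraction in (0, cutoff) ->
#'   multivariate imputation;
#' * metabolites with no missing cells -> complete.
#'
#' A metabolite missing exactly `cutoff` of its values is zero-imputed
#' (multivariate imputation only when the missing fraction is strictly below
#' the cutoff). Routing depends only on class and missing fraction, so it is
#' invariant to any permutation of samples, and re-planning a plan-applied
#' table puts previously zeroed metabolites in the complete set.
#'
#' @param table Numeric matrix (samples x metabolites).
#' @param annotations Annotation data frame covering every metabolite.
#' @param cutoff High-missingness cutoff in (0, 1], default 0.90.
#' @return A list of class `"imputation_plan"` with elements
#'   `zero_impute_ids`, `multivariate_ids`, `complete_ids`,
#'   `reclassified_ids`, `missing_fraction` (named vector) and `cutoff`.
#' @export
build_plan <- function(table, annotations, cutoff = 0.90) {
  validate_metabolite_table(table)
  validate_annotations(annotations, data_ids = colnames(table))
  if (cutoff <= 0 || cutoff > 1) stop("'cutoff' must lie in (0, 1]")
  ids <- colnames(table)
  cls <- annotations$class[match(ids, annotations$metabolite_id)]
  frac <- if (nrow(table) > 0L) colMeans(is.na(table)) else
    stats::setNames(rep(0, length(ids)), ids)
  xeno <- cls == "xenobiotic"
  zero <- (xeno & frac > 0) | (!xeno & frac >= cutoff)
  reclassified <- !xeno & frac >= cutoff
  multivariate <- !xeno & frac > 0 & frac < cutoff
  complete <- frac == 0
  structure(list(zero_impute_ids = ids[zero],
                 multivariate_ids = ids[multivariate],
                 complete_ids = ids[complete],
                 reclassified_ids = ids[reclassified],
                 missing_fraction = stats::setNames(frac, ids),
                 cutoff = cutoff),
            class = "imputation_plan")
}

#' @export
print.imputation_plan <- function(x, ...) {
  cat("<imputation_plan> cutoff =", x$cutoff, "\n",
      " zero-impute:", length(x$zero_impute_ids),
      "(of which reclassified:", length(x$reclassified_ids), ")\n",
      " multivariate:", length(x$multivariate_ids), "\n",
      " complete:", length(x$complete_ids), "\n")
  invisible(x)
}

#' Impute listed metabolites to zero
#'
#' Sets every missing cell of the listed metabolites to exactly 0; all other
#' cells (including observed cells of the listed metabolites) are unchanged.
#'
#' @param table Numeric matrix (samples x metabolites).
#' @param ids Metabolite ids to zero-impute; must all exist in `table`.
#' @return The table with the listed metabolites completed by zeros.
#' @export
apply_zero_imputation <- function(table, ids) {
  validate_metabolite_table(table)
  unknown <- setdiff(ids, colnames(table))
  if (length(unknown))
    stop("unknown metabolite id(s): ", paste(unknown, collapse = ", "))
  for (j in ids) {
    v <- table[, j]
    v[is.na(v)] <- 0
    table[, j] <- v
  }
  table
}
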
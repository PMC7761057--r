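#' Pairwise-complete Pearson correlation matrix
#'
#' Each entry is the Pearson coefficient over the samples where both
#' metabolites are observed. An entry whose pairwise-complete overlap is
#' below `min_overlap`, or where either metabolite is constant on the
#' overlap, is undefined (`NA`); the overlap count is retained either way.
#' Intended to be run on the non-xenobiotic part of the panel.
#'
#' @param table Numeric matrix (samples x metabolites), typically
#'   log-standardized (Pearson r is scale-invariant, so this equals the
#'   raw-log correlation).
#' @param min_overlap Minimum joint-observation count for a defined
#'   coefficient; default 5 guards against 2-point degenerate correlations.
#' @return A list of class `"pairwise_cor"` with `ids`, `r` (symmetric
#'   matrix, `NA` = undefined), `n_overlap` (symmetric integer matrix) and
#'   `min_overlap`.
#' @export
pairwise_complete_correlation <- function(table, min_overlap = 5L) {
  validate_metabolite_table(table)
  obs <- !is.na(table)
  n_overlap <- crossprod(obs)
  r <- suppressWarnings(stats::cor(table, use = "pairwise.complete.obs"))
  r[n_overlap < min_overlap] <- NA_real_
  r[!is.finite(r)] <- NA_real_
  structure(list(ids = colnames(table), r = r,
                 n_overlap = n_overlap, min_overlap = as.integer(min_overlap)),
            class = "pairwise_cor")
}

#' Select auxiliary metabolites for one incomplete target
#'
#' Picks the up-to-`n_aux` *complete* metabolites with the largest absolute
#' Pearson correlation to the target. If fewer than `n_aux` complete
#' candidates have a defined correlation, all of them are taken and -- only
#' if still short -- the set is topped up from incomplete metabolites with
#' defined correlations (flagged via `topped_up` so the choice can be
#' audited). Ties in |r| at the selection boundary are broken by
#' lexicographic metabolite id (C collation), so selection is deterministic
#' and invariant to row and column order.
#'
#' @param corr A `"pairwise_cor"` object.
#' @param target_id The incomplete metabolite to impute.
#' @param complete_ids Ids of metabolites with no missing values (the
#'   preferred candidate pool; xenobiotics should already be excluded).
#' @param n_aux Maximum number of auxiliaries, default 10.
#' @return A list of class `"aux_set"`: `target_id`, `aux_ids`, `aux_abs_r`
#'   (non-increasing), `mean_abs_r`, `topped_up`.
#' @export
select_auxiliary <- function(corr, target_id, complete_ids, n_aux = 10L) {
  if (!inherits(corr, "pairwise_cor")) stop("'corr' must be a pairwise_cor")
  if (!target_id %in% corr$ids) stop("unknown target id: ", target_id)
  rv <- corr$r[target_id, ]
  rv[target_id] <- NA_real_
  defined <- names(rv)[!is.na(rv)]
  if (length(defined) == 0L)
    stop("no defined correlations for target '", target_id,
         "'; it cannot be imputed multivariately")
  pick <- function(cands, k) {
    if (k <= 0L || length(cands) == 0L) return(character(0))
    ord <- order(-abs(rv[cands]), id_rank(cands))
    utils::head(cands[ord], k)
  }
  comp <- intersect(defined, setdiff(complete_ids, target_id))
  sel <- pick(comp, n_aux)
  topped_up <- FALSE
  if (length(sel) < n_aux) {
    extra <- pick(setdiff(defined, c(comp, target_id)), n_aux - length(sel))
    topped_up <- length(extra) > 0L
    sel <- c(sel, extra)
  }
  absr <- abs(rv[sel])
  ord <- order(-absr, id_rank(sel))
  sel <- sel[ord]
  absr <- unname(absr[ord])
  structure(list(target_id = target_id, aux_ids = sel, aux_abs_r = absr,
                 mean_abs_r = mean(absr), topped_up = topped_up),
            class = "aux_set")
}

#' Select auxiliaries for many targets, tolerating failures
#'
#' Applies [select_auxiliary()] to each target; targets with zero defined
#' correlations are collected in `excluded` (they must be left out of
#' multivariate imputation) instead of aborting the run.
#'
#' @inheritParams select_auxiliary
#' @param target_ids Character vector of incomplete metabolite ids.
#' @return A list with `sets` (named list of `"aux_set"`) and `excluded`
#'   (character vector of targets without any defined correlation).
#' @export
select_all_auxiliary <- function(corr, target_ids, complete_ids, n_aux = 10L) {
  sets <- list()
  excluded <- character(0)
  for (t in target_ids) {
    s <- tryCatch(select_auxiliary(corr, t, complete_ids, n_aux),
                  error = function(e) NULL)
    if (is.null(s)) excluded <- c(excluded, t) else sets[[t]] <- s
  }
  list(sets = sets, excluded = excluded)
}

#' Tidy export of auxiliary selections
#'
#' One row per (target, auxiliary) pair for audit: rank, absolute
#' correlation and the target's mean absolute auxiliary correlation.
#'
#' @param sets Named list of `"aux_set"` objects (e.g.
#'   `select_all_auxiliary()$sets`).
#' @return A tibble with columns `target_id`, `rank`, `aux_id`, `abs_r`,
#'   `mean_abs_r`, `topped_up`.
#' @export
auxiliary_table <- function(sets) {
  rows <- lapply(sets, function(s) {
    tibble::tibble(target_id = s$target_id,
                   rank = seq_along(s$aux_ids),
                   aux_id = s$aux_ids,
                   abs_r = s$aux_abs_r,
                   mean_abs_r = s$mean_abs_r,
                   topped_up = s$topped_up)
  })
  tibble::as_tibble(do.call(rbind, rows))
}
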
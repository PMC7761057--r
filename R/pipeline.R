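#' Run the full imputation workflow on a panel
#'
#' End-to-end driver: routes every metabolite with [build_plan()], applies
#' zero imputation on the raw abundance scale (zero-imputed metabolites are
#' excluded from the log transform -- log 0 is undefined -- and carried
#' through unscaled), log-standardizes the remaining non-xenobiotic
#' metabolites, computes their pairwise-complete correlation matrix,
#' selects the auxiliary metabolites per incomplete target, and imputes
#' with MICE-pmm or kNN-obs-sel.
#'
#' Completed tables therefore mix two scales: non-xenobiotic metabolites
#' are on the log-standardized scale, zero-routed (xenobiotic and
#' reclassified) metabolites stay on the raw abundance scale with zeros in
#' place of missing cells. Targets without any defined correlation are
#' excluded from multivariate imputation and reported in `excluded`.
#'
#' @param table Raw-abundance matrix (samples x metabolites), positive
#'   observed values, `NA` for missing.
#' @param annotations Annotation data frame covering every metabolite.
#' @param covariates Optional covariate data frame (`age`, `sex`, `BMI`)
#'   used as extra MICE predictors.
#' @param config A [run_config()].
#' @return A list of class `"imputation_result"`: `completed` (list of
#'   completed matrices, length `m` for MICE, 1 for kNN), `method`, `m`,
#'   `params`, `seed`, `plan`, `aux`, `excluded`, `unscaled`,
#'   `fallback_count`.
#' @export
impute_metabolites <- function(table, annotations, covariates = NULL,
                               config = run_config()) {
  validate_metabolite_table(table)
  validate_annotations(annotations, colnames(table))
  if (!inherits(config, "run_config")) stop("'config' must be a run_config")
  plan <- build_plan(table, annotations, config$high_missing_cutoff)
  zeroed <- apply_zero_imputation(table, plan$zero_impute_ids)
  xeno_ids <- annotations$metabolite_id[annotations$class == "xenobiotic"]
  scale_ids <- setdiff(colnames(table), union(plan$zero_impute_ids, xeno_ids))
  std <- log_standardize(zeroed[, scale_ids, drop = FALSE])
  corr <- pairwise_complete_correlation(std, config$min_pairwise_overlap)
  candidates <- setdiff(plan$complete_ids, xeno_ids)
  sel <- select_all_auxiliary(corr, plan$multivariate_ids, candidates,
                              config$n_aux)
  fallback <- 0L
  if (config$method == "knn_obs_sel") {
    done <- knn_obs_sel_impute(std, sel$sets, k = config$knn_k)
    fallback <- attr(done, "fallback_count")
    completed_std <- list(done)
  } else {
    res <- mice_pmm(std, sel$sets, covariates = covariates, m = config$m,
                    iterations = config$chained_iterations,
                    d = config$donors, seed = config$seed)
    completed_std <- res$completed
  }
  assemble <- function(s) {
    full <- zeroed
    full[, scale_ids] <- s[, scale_ids]
    full
  }
  structure(list(completed = lapply(completed_std, assemble),
                 method = config$method,
                 m = length(completed_std),
                 targets = names(sel$sets),
                 params = config, seed = config$seed, plan = plan,
                 aux = sel$sets, excluded = sel$excluded,
                 unscaled = attr(std, "unscaled"),
                 fallback_count = fallback),
            class = "imputation_result")
}
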
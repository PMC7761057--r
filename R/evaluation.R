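# accept covariate tables with case-insensitive age/sex/BMI column names
normalize_covariates <- function(covariates) {
  if (!is.data.frame(covariates)) stop("covariates must be a data frame")
  nm <- tolower(colnames(covariates))
  pick <- function(want) {
    i <- which(nm == want)
    if (length(i) == 0L) stop("covariate table lacks column '", want, "'")
    as.numeric(covariates[[i[1L]]])
  }
  out <- data.frame(age = pick("age"), sex = pick("sex"), BMI = pick("bmi"))
  if (anyNA(out)) stop("covariates must be complete (no missing values)")
  out
}

#' Fit the outcome model BMI ~ age + sex + metabolite
#'
#' Ordinary least squares with BMI as the outcome and age, sex, and one
#' metabolite as exposures. With a list of m metabolite vectors (one per
#' imputed dataset) the per-dataset fits are pooled by Rubin's rules
#' ([pool_rubin()]) with complete-data df `n - 4`.
#'
#' @param covariates Data frame with numeric `age`, `sex`, `BMI` columns
#'   (case-insensitive names), complete.
#' @param metabolite Numeric vector, or list of m numeric vectors.
#' @return A list: `estimate` and `se` of the metabolite coefficient, `m`,
#'   and `pooled` (the `"pooled_estimate"`, or `NULL` for a single fit).
#' @export
fit_outcome_model <- function(covariates, metabolite) {
  cv <- normalize_covariates(covariates)
  fit1 <- function(met) {
    met <- as.numeric(met)
    if (length(met) != nrow(cv))
      stop("metabolite vector length does not match the covariate table")
    if (anyNA(met)) stop("outcome model requires a complete metabolite vector")
    d <- data.frame(BMI = cv$BMI, age = cv$age, sex = cv$sex, metabolite = met)
    f <- stats::lm(BMI ~ age + sex + metabolite, data = d)
    if (anyNA(stats::coef(f))) stop("rank-deficient outcome model design")
    s <- summary(f)$coefficients
    c(s["metabolite", "Estimate"], s["metabolite", "Std. Error"])
  }
  if (is.list(metabolite)) {
    fits <- vapply(metabolite, fit1, numeric(2))
    m <- ncol(fits)
    if (m == 1L)
      return(list(estimate = fits[1L, 1L], se = fits[2L, 1L], m = 1L,
                  pooled = NULL))
    pooled <- pool_rubin(fits[1L, ], fits[2L, ]^2, dfcom = nrow(cv) - 4)
    list(estimate = pooled$q_bar, se = pooled$se, m = m, pooled = pooled)
  } else {
    v <- fit1(metabolite)
    list(estimate = v[1L], se = v[2L], m = 1L, pooled = NULL)
  }
}

#' Distribution-preserving subsample
#'
#' Draws `n_sub` samples while maintaining the joint distribution of sex,
#' age and BMI: proportional (largest-remainder) allocation over the
#' sex x age-tertile x BMI-tertile cells, with uniform sampling without
#' replacement inside each cell. If the stratification cannot be honoured,
#' cells are merged across BMI tertiles with a warning. Consumes the
#' current RNG stream.
#'
#' @param covariates Data frame with `age`, `sex`, `BMI` columns.
#' @param n_sub Subsample size (`n_sub == nrow` returns the identity).
#' @return Sorted integer vector of selected row indices.
#' @export
subsample_preserving_distribution <- function(covariates, n_sub) {
  cv <- normalize_covariates(covariates)
  n <- nrow(cv)
  if (n_sub > n) stop("'n_sub' exceeds the number of samples")
  if (n_sub < 1L) stop("'n_sub' must be positive")
  if (n_sub == n) return(seq_len(n))
  draw <- function(cell) {
    cell <- as.integer(cell)
    cells <- sort(unique(cell))
    cnt <- vapply(cells, function(cc) sum(cell == cc), integer(1))
    quota <- n_sub * cnt / n
    base <- floor(quota)
    rem <- quota - base
    short <- n_sub - sum(base)
    extra <- integer(length(cells))
    if (short > 0) {
      ord <- order(-rem, seq_along(cells))
      extra[ord[seq_len(short)]] <- 1L
    }
    alloc <- base + extra
    if (any(alloc > cnt)) return(NULL)
    idx <- unlist(lapply(seq_along(cells), function(i) {
      members <- which(cell == cells[i])
      members[sample.int(length(members), alloc[i])]
    }))
    sort(idx)
  }
  cell_full <- as.integer(interaction(cv$sex, tertile_of(cv$age),
                                      tertile_of(cv$BMI), drop = TRUE))
  idx <- draw(cell_full)
  if (is.null(idx)) {
    warning("stratified allocation infeasible; merging across BMI tertiles")
    idx <- draw(as.integer(interaction(cv$sex, tertile_of(cv$age),
                                       drop = TRUE)))
    if (is.null(idx)) stop("subsampling allocation infeasible")
  }
  idx
}

#' Enumerate a factorial scenario grid
#'
#' Crosses the factor levels into one row per simulation scenario, ordered
#' for nested-loop plotting: mechanism, then sample size, then missing
#' percentage, then metabolite, then method. The reference factorial (3
#' sample sizes x 4 metabolites x 3 missing percentages x 2 mechanisms x 2
#' methods) yields 144 scenarios.
#'
#' @param n Sample sizes, default `c(50, 150, 599)`.
#' @param target_ids Metabolite ids to blank and re-impute.
#' @param pct Missing fractions, default `c(0.15, 0.30, 0.60)`.
#' @param mechanism Subset of `c("MCAR", "PLoD")`.
#' @param method Subset of `c("mice_pmm", "knn_obs_sel")`.
#' @param reps Repetitions per scenario, default 1000.
#' @return A tibble with columns `mechanism`, `n`, `pct`, `target_id`,
#'   `method`, `reps`.
#' @export
scenario_grid <- function(n = c(50L, 150L, 599L), target_ids,
                          pct = c(0.15, 0.30, 0.60),
                          mechanism = c("MCAR", "PLoD"),
                          method = c("mice_pmm", "knn_obs_sel"),
                          reps = 1000L) {
  mechanism <- match.arg(mechanism, several.ok = TRUE)
  method <- match.arg(method, several.ok = TRUE)
  g <- expand.grid(method = method, target_id = target_ids, pct = pct,
                   n = n, mechanism = mechanism,
                   stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  g <- g[, c("mechanism", "n", "pct", "target_id", "method")]
  g$reps <- as.integer(reps)
  tibble::as_tibble(g)
}

#' Summarise simulation estimates against the complete-data truth
#'
#' Implements the evaluation measures: raw bias (mean estimate minus
#' truth, signed), percentage bias `100 |raw_bias| / |truth|`, RMSE
#' `sqrt(mean((est - truth)^2))` and its percentage `100 rmse / |truth|`.
#' Percentage measures are invariant to the sign of the truth. The identity
#' `rmse^2 = raw_bias^2 + est_sd^2 (reps - 1) / reps` holds by construction.
#'
#' @param estimates Numeric vector of per-repetition estimates (`NA` =
#'   failed repetition, dropped).
#' @param truth Complete-data coefficient.
#' @return A one-row tibble: `truth`, `est_mean`, `est_sd`, `raw_bias`,
#'   `pct_bias`, `rmse`, `rmse_pct`, `reps`, `reps_failed`.
#' @export
scenario_summary <- function(estimates, truth) {
  failed <- sum(is.na(estimates))
  est <- estimates[!is.na(estimates)]
  if (length(est) == 0L) stop("no successful repetitions")
  est_mean <- mean(est)
  raw_bias <- est_mean - truth
  tibble::tibble(truth = truth,
                 est_mean = est_mean,
                 est_sd = if (length(est) > 1L) stats::sd(est) else 0,
                 raw_bias = raw_bias,
                 pct_bias = 100 * abs(raw_bias) / abs(truth),
                 rmse = sqrt(mean((est - truth)^2)),
                 rmse_pct = 100 * sqrt(mean((est - truth)^2)) / abs(truth),
                 reps = length(estimates),
                 reps_failed = failed)
}

#' Run one simulation scenario
#'
#' Computes the complete-data coefficient (the truth) once, then per
#' repetition: induces missingness in the target metabolite, imputes with
#' the chosen method, refits the outcome model (pooling over the m MICE
#' datasets), and records the estimate. Auxiliaries are fixed inputs derived
#' from the complete data of this (sub)cohort; missingness is induced only
#' in the target, as in the reference design. A repetition whose imputation
#' fails is recorded as failed; more than 5% failures aborts the scenario.
#'
#' @param table Complete (in the target), log-standardized metabolite
#'   matrix for this cohort or subcohort.
#' @param covariates Matching covariate data frame (`age`, `sex`, `BMI`).
#' @param target_id Metabolite to blank and re-impute; must be complete.
#' @param pct Missing fraction.
#' @param mechanism `"MCAR"` or `"PLoD"`.
#' @param method `"mice_pmm"` or `"knn_obs_sel"`.
#' @param aux An `"aux_set"` for the target, or a named list containing one.
#' @param reps Number of repetitions.
#' @param seed Integer seed for this scenario.
#' @param m,iterations,donors MICE parameters (see [mice_pmm()]).
#' @param k kNN neighbour count (see [knn_obs_sel_impute()]).
#' @return A one-row tibble: scenario factors, the [scenario_summary()]
#'   measures, with the per-repetition estimates in the `"estimates"`
#'   attribute.
#' @export
run_scenario <- function(table, covariates, target_id, pct,
                         mechanism = c("MCAR", "PLoD"),
                         method = c("mice_pmm", "knn_obs_sel"),
                         aux, reps = 1000L, seed = 1L,
                         m = 5L, iterations = 5L, donors = 5L, k = 10L) {
  mechanism <- match.arg(mechanism)
  method <- match.arg(method)
  validate_metabolite_table(table)
  if (!target_id %in% colnames(table)) stop("unknown target id: ", target_id)
  if (anyNA(table[, target_id]))
    stop("target '", target_id, "' must be complete in the input table")
  if (inherits(aux, "aux_set")) aux <- stats::setNames(list(aux), target_id)
  if (!target_id %in% names(aux))
    stop("no auxiliary set supplied for target '", target_id, "'")
  aux <- aux[target_id]
  truth <- fit_outcome_model(covariates, table[, target_id])$estimate
  induce <- if (mechanism == "MCAR") induce_mcar else induce_plod
  set.seed(as.integer(seed))
  rep_seeds <- sample.int(2147483646L, reps)
  estimates <- rep(NA_real_, reps)
  for (r in seq_len(reps)) {
    estimates[r] <- tryCatch({
      set.seed(rep_seeds[r])
      mask <- induce(table[, target_id], pct)
      masked <- apply_mask(table, mask, target_id)
      if (method == "knn_obs_sel") {
        done <- knn_obs_sel_impute(masked, aux, k = k)
        fit_outcome_model(covariates, done[, target_id])$estimate
      } else {
        res <- mice_pmm(masked, aux, covariates = covariates, m = m,
                        iterations = iterations, d = donors,
                        seed = sample.int(2147483646L, 1L))
        mets <- lapply(res$completed, function(tb) tb[, target_id])
        fit_outcome_model(covariates, mets)$estimate
      }
    }, error = function(e) NA_real_)
  }
  failed <- sum(is.na(estimates))
  if (failed > 0.05 * reps)
    stop("scenario aborted: ", failed, " of ", reps, " repetitions failed")
  out <- tibble::tibble(mechanism = mechanism, n = nrow(table), pct = pct,
                        target_id = target_id, method = method)
  out <- cbind(out, scenario_summary(estimates, truth))
  out <- tibble::as_tibble(out)
  attr(out, "estimates") <- estimates
  out
}

#' Run a factorial grid of simulation scenarios
#'
#' Drives [run_scenario()] over a [scenario_grid()]. For each distinct
#' sample size a single distribution-preserving subcohort is drawn and kept
#' fixed across all its scenarios; within each subcohort the metabolites are
#' log-standardized, the pairwise-complete correlation matrix is computed,
#' and auxiliaries are selected once from the complete data (they may differ
#' slightly between subcohorts). Everything is seeded from `seed`, so a
#' rerun reproduces the results table exactly.
#'
#' @param table Raw-abundance metabolite matrix (targets complete),
#'   non-xenobiotic columns only unless `annotations` is supplied.
#' @param covariates Covariate data frame aligned with `table` rows.
#' @param grid A tibble from [scenario_grid()] (duplicated rows are dropped
#'   with a warning).
#' @param annotations Optional annotation data frame; if given, xenobiotic
#'   columns are removed before correlation and imputation.
#' @param reps Optional override of the grid's `reps` column.
#' @param seed Master seed.
#' @param n_aux,min_overlap Auxiliary-selection parameters.
#' @param m,iterations,donors,k Imputer parameters.
#' @return A tibble with one row per scenario, ordered mechanism > n > pct >
#'   metabolite > method, with columns `mechanism`, `n`, `pct`, `target_id`,
#'   `method`, `truth`, `est_mean`, `est_sd`, `raw_bias`, `pct_bias`,
#'   `rmse`, `rmse_pct`, `reps`, `reps_failed`.
#' @export
run_grid <- function(table, covariates, grid, annotations = NULL,
                     reps = NULL, seed = 1L, n_aux = 10L, min_overlap = 5L,
                     m = 5L, iterations = 5L, donors = 5L, k = 10L) {
  validate_metabolite_table(table)
  if (nrow(grid) == 0L) stop("empty scenario grid")
  key <- c("mechanism", "n", "pct", "target_id", "method")
  dup <- duplicated(grid[, key])
  if (any(dup)) {
    warning("dropping ", sum(dup), " duplicated scenario(s)")
    grid <- grid[!dup, ]
  }
  if (!is.null(reps)) grid$reps <- as.integer(reps)
  if (!is.null(annotations)) {
    validate_annotations(annotations, colnames(table))
    xeno <- annotations$metabolite_id[annotations$class == "xenobiotic"]
    table <- table[, setdiff(colnames(table), xeno), drop = FALSE]
  }
  set.seed(as.integer(seed))
  sizes <- sort(unique(grid$n))
  sub_seeds <- stats::setNames(sample.int(2147483646L, length(sizes)), sizes)
  scen_seeds <- sample.int(2147483646L, nrow(grid))
  # one fixed subcohort + auxiliary selection per sample size
  ctx <- list()
  for (nn in sizes) {
    set.seed(sub_seeds[as.character(nn)])
    idx <- subsample_preserving_distribution(covariates, nn)
    std <- log_standardize(table[idx, , drop = FALSE])
    corr <- pairwise_complete_correlation(std, min_overlap)
    complete_ids <- colnames(std)[colSums(is.na(std)) == 0L]
    targets <- unique(grid$target_id[grid$n == nn])
    sel <- select_all_auxiliary(corr, targets, complete_ids, n_aux)
    if (length(sel$excluded))
      stop("target(s) without defined correlations at n = ", nn, ": ",
           paste(sel$excluded, collapse = ", "))
    ctx[[as.character(nn)]] <- list(std = std, cov = covariates[idx, ,
                                                                drop = FALSE],
                                    aux = sel$sets)
  }
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    gi <- grid[i, ]
    cx <- ctx[[as.character(gi$n)]]
    rows[[i]] <- run_scenario(cx$std, cx$cov, gi$target_id, gi$pct,
                              mechanism = gi$mechanism, method = gi$method,
                              aux = cx$aux, reps = gi$reps,
                              seed = scen_seeds[i], m = m,
                              iterations = iterations, donors = donors, k = k)
    attr(rows[[i]], "estimates") <- NULL
  }
  out <- tibble::as_tibble(do.call(rbind, rows))
  ord <- order(match(out$mechanism, c("MCAR", "PLoD")), out$n, out$pct,
               match(out$target_id, unique(grid$target_id)),
               match(out$method, c("mice_pmm", "knn_obs_sel")))
  out[ord, ]
}
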
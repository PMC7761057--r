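#' One Bayesian predictive-mean-matching draw
#'
#' Fits ridge-stabilised least squares of `y_obs` on `X_obs`, draws the
#' residual variance from its scaled inverse-chi-square posterior and the
#' coefficients from their normal posterior, and performs type-1 matching:
#' observed rows are predicted with the least-squares coefficients
#' (`beta_hat`), missing rows with the posterior draw (`beta_star`); for
#' each missing row one of the `d` observed rows with the closest
#' predictions is drawn uniformly and its *observed* value is imputed. Every
#' imputed value is therefore an element of `y_obs`.
#'
#' Uses the current R RNG stream; seed control belongs to the caller (see
#' [mice_pmm()]).
#'
#' @param y_obs Observed response values.
#' @param X_obs Design matrix for observed rows (include the intercept).
#' @param X_mis Design matrix for missing rows (same columns).
#' @param d Number of candidate donors per missing row, default 5; clipped
#'   to the number of observed rows with a warning.
#' @param ridge Ridge epsilon added to the cross-product diagonal to survive
#'   near-collinear auxiliaries, default 1e-5.
#' @return Numeric vector of imputed values, one per row of `X_mis`.
#' @export
pmm_draw <- function(y_obs, X_obs, X_mis, d = 5L, ridge = 1e-5) {
  n <- length(y_obs)
  if (!is.matrix(X_obs) || nrow(X_obs) != n)
    stop("X_obs must be a matrix with one row per observed value")
  if (!is.matrix(X_mis) || ncol(X_mis) != ncol(X_obs))
    stop("X_mis must have the same columns as X_obs")
  if (nrow(X_mis) == 0L) return(numeric(0))
  rk <- qr(X_obs)$rank
  if (n <= rk)
    stop("too few observed rows (", n, ") for ", rk,
         " model degrees of freedom; shrink the predictor set (n_aux)")
  if (d > n) {
    warning("d = ", d, " donors requested but only ", n,
            " observed rows; using d = ", n)
    d <- n
  }
  p <- ncol(X_obs)
  A <- crossprod(X_obs) + diag(ridge, p)
  Ainv <- chol2inv(chol(A))
  beta_hat <- Ainv %*% crossprod(X_obs, y_obs)
  ssr <- sum((y_obs - X_obs %*% beta_hat)^2)
  sigma2_star <- ssr / stats::rchisq(1L, df = n - rk)
  beta_star <- beta_hat + t(chol(Ainv)) %*% stats::rnorm(p) * sqrt(sigma2_star)
  yhat_obs <- drop(X_obs %*% beta_hat)
  yhat_mis <- drop(X_mis %*% beta_star)
  vapply(yhat_mis, function(yh) {
    cand <- utils::head(order(abs(yhat_obs - yh)), d)
    y_obs[cand[sample.int(length(cand), 1L)]]
  }, numeric(1))
}

#' Multiple imputation by chained equations with predictive mean matching
#'
#' Runs `m` independent chains. Each chain initialises every incomplete
#' target by sampling with replacement from its observed values, then for
#' `iterations` sweeps visits the targets in ascending missing-count order,
#' regressing each on its auxiliary metabolites (current completed values)
#' plus the covariates (age, sex, BMI) and an intercept, and refills its
#' missing cells via [pmm_draw()]. Chain seeds are derived deterministically
#' from `seed`, so identical seeds give bitwise-identical results while
#' chains differ from each other.
#'
#' @param table Numeric matrix (samples x metabolites), log-standardized;
#'   targets named in `aux` may contain `NA`.
#' @param aux Named list of `"aux_set"` objects for the targets to impute.
#' @param covariates Optional data frame with numeric `age`, `sex`, `BMI`
#'   for each sample (same row order as `table`); entered as predictors in
#'   every conditional model, never imputed themselves.
#' @param m Number of imputed datasets, default 5. `m = 1` gives
#'   single-imputation mode.
#' @param iterations Chained-equation sweeps, default 5; must be >= 1.
#' @param d PMM donors, default 5.
#' @param ridge Ridge epsilon for [pmm_draw()].
#' @param seed Integer master seed.
#' @return A list of class `"imputation_result"`: `completed` (list of `m`
#'   matrices), `method`, `m`, `params`, `seed`, `targets`.
#' @export
mice_pmm <- function(table, aux, covariates = NULL, m = 5L, iterations = 5L,
                     d = 5L, ridge = 1e-5, seed = 1L) {
  validate_metabolite_table(table)
  if (iterations < 1L) stop("'iterations' must be at least 1")
  if (m < 1L) stop("'m' must be at least 1")
  C <- NULL
  if (!is.null(covariates)) {
    cv <- normalize_covariates(covariates)
    if (nrow(cv) != nrow(table))
      stop("covariates must have one row per sample")
    C <- cbind(age = cv$age, sex = cv$sex, BMI = cv$BMI)
  }
  targets <- names(aux)
  bad <- setdiff(targets, colnames(table))
  if (length(bad)) stop("unknown target id(s): ", paste(bad, collapse = ", "))
  n_miss <- vapply(targets, function(j) sum(is.na(table[, j])), integer(1))
  targets <- targets[n_miss > 0L]
  targets <- targets[order(n_miss[targets], id_rank(targets))]
  # auxiliaries that are themselves incomplete but not visited as targets
  # still need values to serve as predictors: give them the same random-
  # margin initialisation (they are never updated).
  aux_ids_all <- unique(unlist(lapply(aux, `[[`, "aux_ids")))
  init_only <- setdiff(aux_ids_all[colSums(is.na(table[, aux_ids_all,
                                                       drop = FALSE])) > 0L],
                       targets)
  set.seed(as.integer(seed))
  chain_seeds <- sample.int(2147483646L, m)
  completed <- vector("list", m)
  for (ch in seq_len(m)) {
    set.seed(chain_seeds[ch])
    work <- table
    for (j in c(targets, init_only)) {
      mis <- which(is.na(work[, j]))
      obs_vals <- work[!is.na(work[, j]), j]
      if (length(obs_vals) == 0L)
        stop("target '", j, "' has no observed values to draw from")
      work[mis, j] <- obs_vals[sample.int(length(obs_vals), length(mis),
                                          replace = TRUE)]
    }
    for (it in seq_len(iterations)) {
      for (j in targets) {
        s <- aux[[j]]
        mis <- which(is.na(table[, j]))
        obs <- which(!is.na(table[, j]))
        X <- cbind(`(Intercept)` = 1, work[, s$aux_ids, drop = FALSE])
        if (!is.null(C)) X <- cbind(X, C)
        imp <- tryCatch(
          pmm_draw(table[obs, j], X[obs, , drop = FALSE],
                   X[mis, , drop = FALSE], d = d, ridge = ridge),
          error = function(e)
            stop("imputation of target '", j, "' failed: ",
                 conditionMessage(e), call. = FALSE))
        work[mis, j] <- imp
      }
    }
    completed[[ch]] <- work
  }
  structure(list(completed = completed, method = "mice_pmm", m = m,
                 params = list(iterations = iterations, d = d, ridge = ridge),
                 seed = as.integer(seed), targets = targets),
            class = "imputation_result")
}

#' @export
print.imputation_result <- function(x, ...) {
  cat("<imputation_result>", x$method, "| m =", length(x$completed),
      "| targets:", length(x$targets %||% character(0)),
      "| seed:", x$seed %||% NA, "\n")
  invisible(x)
}

#' Pool estimates across imputed datasets by Rubin's rules
#'
#' Pooled point estimate `q_bar` = mean of the per-dataset estimates;
#' within-imputation variance `W` = mean of the squared SEs;
#' between-imputation variance `B` = sample variance of the estimates (0
#' when m = 1); total variance `T = W + (1 + 1/m) B`, with Barnard-Rubin
#' adjusted degrees of freedom when the complete-data degrees of freedom
#' `dfcom` are supplied.
#'
#' @param estimates Numeric vector of m per-dataset coefficients.
#' @param variances Numeric vector of m squared standard errors.
#' @param dfcom Complete-data residual degrees of freedom; `Inf` (default)
#'   gives the classical large-sample df `(m - 1) / lambda^2`.
#' @return A list of class `"pooled_estimate"`: `q_bar`, `W`, `B`, `T`,
#'   `df`, `m`, `se`.
#' @export
pool_rubin <- function(estimates, variances, dfcom = Inf) {
  if (length(estimates) != length(variances))
    stop("'estimates' and 'variances' must have the same length")
  m <- length(estimates)
  if (m < 1L) stop("need at least one estimate")
  if (any(variances < 0)) stop("variances must be nonnegative")
  q_bar <- mean(estimates)
  W <- mean(variances)
  B <- if (m > 1L) stats::var(estimates) else 0
  Tv <- W + (1 + 1 / m) * B
  if (B == 0 || Tv == 0) {
    df <- dfcom
  } else {
    lambda <- (1 + 1 / m) * B / Tv
    df_old <- (m - 1) / lambda^2
    df <- if (is.finite(dfcom)) {
      df_obs <- (dfcom + 1) / (dfcom + 3) * dfcom * (1 - lambda)
      df_old * df_obs / (df_old + df_obs)
    } else df_old
  }
  structure(list(q_bar = q_bar, W = W, B = B, T = Tv, df = df, m = m,
                 se = sqrt(Tv)),
            class = "pooled_estimate")
}

#' @export
print.pooled_estimate <- function(x, ...) {
  cat(sprintf("<pooled_estimate> q_bar = %.6g (se %.6g), W = %.6g, B = %.6g, T = %.6g, df = %.3g, m = %d\n",
              x$q_bar, x$se, x$W, x$B, x$T, x$df, x$m))
  invisible(x)
}
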
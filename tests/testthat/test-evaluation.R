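test_that("outcome model recovers exact and oracle coefficients, and pools", {
  set.seed(31)
  n <- 40
  cv <- data.frame(age = runif(n, 45, 65), sex = rbinom(n, 1, 0.5), BMI = 0)
  met <- rnorm(n)
  cv$BMI <- 25 + 0 * cv$age + 0 * cv$sex + 3 * met  # noiseless
  f <- suppressWarnings(fit_outcome_model(cv, met))  # "perfect fit" warning
  expect_equal(f$estimate, 3, tolerance = 1e-10)

  # 6-row fixture against the SVD pseudoinverse oracle
  cv6 <- data.frame(age = c(46, 50, 53, 57, 60, 64),
                    sex = c(0, 1, 0, 1, 0, 1),
                    BMI = c(22.5, 25.1, 23.0, 27.2, 24.8, 28.9))
  met6 <- c(0.2, -1.1, 0.5, 1.4, -0.3, 0.9)
  expect_equal(fit_outcome_model(cv6, met6)$estimate, pinv_ols(cv6, met6),
               tolerance = 1e-10)

  # m identical imputed datasets: pooled estimate = single fit, B = 0
  noisy <- met + rnorm(n, 0, 0.1)
  cvn <- cv; cvn$BMI <- cv$BMI + rnorm(n)
  fm <- fit_outcome_model(cvn, replicate(5, noisy, simplify = FALSE))
  expect_equal(fm$estimate, fit_outcome_model(cvn, noisy)$estimate)
  expect_equal(fm$pooled$B, 0)

  expect_error(fit_outcome_model(cvn, replace(noisy, 3, NA)), "complete")
  cvd <- cvn; cvd$sex <- 1  # constant regressor -> rank-deficient
  expect_error(fit_outcome_model(cvd, noisy), "rank-deficient")
})

test_that("stratified subsampling preserves covariate distributions", {
  set.seed(32)
  n <- 400
  cv <- data.frame(age = runif(n, 45, 65), sex = rep(c(0, 1), n / 2),
                   BMI = rnorm(n, 26, 4))
  expect_identical(subsample_preserving_distribution(cv, n), seq_len(n))
  idx <- subsample_preserving_distribution(cv, 50)
  expect_length(idx, 50)
  expect_length(unique(idx), 50)
  # 50/50 sex split carries over (+/- 1 by the remainder rule)
  expect_lte(abs(sum(cv$sex[idx]) - 25), 1)

  # paired Monte-Carlo: stratified KS distance on BMI beats simple random
  ks <- function(i) suppressWarnings(
    stats::ks.test(cv$BMI[i], cv$BMI)$statistic)
  d_strat <- d_srs <- numeric(200)
  for (r in 1:200) {
    d_strat[r] <- ks(subsample_preserving_distribution(cv, 150))
    d_srs[r] <- ks(sample.int(n, 150))
  }
  expect_lt(mean(d_strat), mean(d_srs))
})

test_that("scenario summary implements the bias and RMSE formulas", {
  s <- scenario_summary(c(1.1, 0.9), truth = 1)
  expect_equal(s$raw_bias, 0)
  expect_equal(s$pct_bias, 0)
  expect_equal(s$rmse, 0.1)
  expect_equal(s$rmse_pct, 10)
  # sign of the truth does not affect the percentage measures
  s_neg <- scenario_summary(c(-1.1, -0.9), truth = -1)
  expect_equal(s_neg$pct_bias, s$pct_bias)
  expect_equal(s_neg$rmse_pct, s$rmse_pct)
  # variance decomposition identity
  set.seed(33)
  est <- rnorm(100, 1.2, 0.3)
  sv <- scenario_summary(est, truth = 1)
  expect_equal(sv$rmse^2,
               sv$raw_bias^2 + sv$est_sd^2 * (sv$reps - 1) / sv$reps,
               tolerance = 1e-10)
})

test_that("a single scenario runs both methods and honours reps", {
  set.seed(34)
  co <- generate_cohort(cohort_spec(n_samples = 120, block_rho = 0.6,
                                    block_size = 6, n_incomplete = 0,
                                    n_xenobiotic = 0, seed = 9))
  std <- log_standardize(co$table)
  corr <- pairwise_complete_correlation(std)
  sel <- select_all_auxiliary(corr, "B1_target",
                              setdiff(colnames(std), "B1_target"), n_aux = 5)
  for (meth in c("knn_obs_sel", "mice_pmm")) {
    r <- run_scenario(std, co$covariates, "B1_target", pct = 0.2,
                      mechanism = "MCAR", method = meth, aux = sel$sets,
                      reps = 30, seed = 77, m = 3, iterations = 3)
    expect_equal(nrow(r), 1)
    expect_length(attr(r, "estimates"), 30)
    expect_equal(r$reps, 30)
    expect_equal(r$reps_failed, 0)
    expect_gte(r$rmse, abs(r$raw_bias))
    expect_equal(r$rmse^2, r$raw_bias^2 + r$est_sd^2 * 29 / 30,
                 tolerance = 1e-10)
  }
  # pct -> 0: nothing is blanked, the estimate equals the truth exactly
  r0 <- run_scenario(std, co$covariates, "B1_target", pct = 0,
                     mechanism = "PLoD", method = "knn_obs_sel",
                     aux = sel$sets, reps = 3, seed = 1)
  expect_equal(r0$raw_bias, 0)
  expect_equal(r0$rmse, 0)
})

test_that("the factorial grid enumerates, deduplicates, and reproduces", {
  g <- scenario_grid(target_ids = c("T1", "T2", "T3", "T4"))
  expect_equal(nrow(g), 144)
  expect_equal(nrow(scenario_grid(n = 50, target_ids = "T1", pct = 0.15,
                                  mechanism = "MCAR", method = "mice_pmm")), 1)

  set.seed(35)
  co <- generate_cohort(cohort_spec(n_samples = 90, block_rho = c(0.6, 0.4),
                                    block_size = 5, n_incomplete = 0,
                                    n_xenobiotic = 0, seed = 10))
  g2 <- scenario_grid(n = c(40, 90), target_ids = co$truth$target_ids,
                      pct = 0.3, mechanism = "MCAR",
                      method = c("mice_pmm", "knn_obs_sel"), reps = 5)
  res <- run_grid(co$table, co$covariates, g2, seed = 7, n_aux = 3,
                  m = 2, iterations = 2)
  expect_equal(nrow(res), 8)
  expect_true(all(res$reps_failed == 0))
  # bitwise reproducibility under the master seed
  res2 <- run_grid(co$table, co$covariates, g2, seed = 7, n_aux = 3,
                   m = 2, iterations = 2)
  expect_identical(res, res2)
  # duplicated scenarios are dropped with a warning
  expect_warning(res3 <- run_grid(co$table, co$covariates,
                                  rbind(g2, g2[1, ]), seed = 7, n_aux = 3,
                                  m = 2, iterations = 2),
                 "duplicated")
  expect_equal(nrow(res3), 8)
})
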
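test_that("block correlation converges to the exchangeable target", {
  co <- generate_cohort(cohort_spec(n_samples = 5000, block_rho = 0.5,
                                    block_size = 6, n_incomplete = 0,
                                    n_xenobiotic = 0, seed = 41))
  cc <- cor(log(co$table))
  off <- cc[upper.tri(cc)]
  expect_equal(mean(off), 0.5, tolerance = 0.02)

  # infeasible exchangeable correlation is rejected up front
  expect_error(cohort_spec(block_rho = 1.2), "positive-definite")
})

test_that("the target's mean |r| with its ten block-mates tracks the spec", {
  for (s in 1:3) {
    co <- generate_cohort(cohort_spec(n_samples = 599, block_rho = 0.64,
                                      block_size = 11, n_incomplete = 0,
                                      n_xenobiotic = 0, seed = 50 + s))
    cc <- cor(log(co$table))
    expect_equal(mean(abs(cc["B1_target", -1])), 0.64, tolerance = 0.05)
  }
})

test_that("noiseless single-block cohort identifies the BMI effect exactly", {
  co <- generate_cohort(cohort_spec(n_samples = 200, block_rho = 0.6,
                                    block_size = 4, n_incomplete = 0,
                                    n_xenobiotic = 0, noise_sd = 0,
                                    beta_metabolite = 1.7, seed = 42))
  std <- log_standardize(co$table)
  f <- suppressWarnings(fit_outcome_model(co$covariates, std[, "B1_target"]))
  expect_equal(f$estimate, 1.7, tolerance = 1e-9)
})

test_that("xenobiotic and filler missingness follow the spec counts", {
  co <- generate_cohort(cohort_spec(n_samples = 100, block_rho = 0.5,
                                    block_size = 3, n_incomplete = 4,
                                    endo_missing_range = c(0.1, 0.3),
                                    n_xenobiotic = 3, xeno_present_frac = 0.1,
                                    seed = 43))
  xeno <- co$annotations$metabolite_id[co$annotations$class == "xenobiotic"]
  expect_length(xeno, 3)
  for (j in xeno) expect_equal(sum(is.na(co$table[, j])), 90)
  fillers <- grep("^F", colnames(co$table), value = TRUE)
  fr <- colMeans(is.na(co$table[, fillers]))
  expect_true(all(fr >= 0.05 & fr <= 0.35))
  # designated targets always complete
  expect_false(anyNA(co$table[, co$truth$target_ids]))
})

test_that("fixtures are written deterministically and load cleanly", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  p1 <- make_fixture("tiny", d1)
  tb <- read_metabolite_table(p1[["metabolites"]])
  ann <- read_annotations(p1[["annotations"]], data_ids = colnames(tb))
  cov <- read_covariates(p1[["covariates"]])
  expect_equal(dim(tb), c(8L, 6L))
  expect_equal(nrow(cov), 8L)
  expect_setequal(ann$class, c("endogenous", "unannotated", "xenobiotic"))

  q1 <- make_fixture("paper_like", d1, seed = 6)
  q2 <- make_fixture("paper_like", d2, seed = 6)
  for (nm in names(q1)) {
    expect_identical(readLines(q1[[nm]]), readLines(q2[[nm]]))
  }
  big <- read_metabolite_table(q1[["metabolites"]])
  expect_equal(nrow(big), 599L)
  targets <- grep("_target$", colnames(big), value = TRUE)
  expect_length(targets, 4L)
  expect_false(anyNA(big[, targets]))
})

test_that("the full factorial grid runs end to end on the synthetic cohort", {
  co <- generate_cohort(cohort_spec(seed = 6))
  g <- scenario_grid(target_ids = co$truth$target_ids, reps = 10)
  res <- run_grid(co$table, co$covariates, g, annotations = co$annotations,
                  seed = 6, m = 2, iterations = 2)
  expect_equal(nrow(res), 144L)
  expect_true(all(is.finite(res$pct_bias)))
  expect_true(all(res$rmse >= abs(res$raw_bias) - 1e-12))
  expect_true(all(res$reps_failed == 0))
  # exported ordering: mechanism > n > pct > metabolite > method
  expect_equal(res$mechanism, rep(c("MCAR", "PLoD"), each = 72))
  expect_equal(res$n[1:72], rep(c(50L, 150L, 599L), each = 24))
})

test_that("generate -> blank -> impute -> pool recovers the effect at scale", {
  # compact version of the recovery chain (the full 200-rep check lives in
  # the acceptance suite): n = 599, mean |r| 0.64 target, 15% MCAR, MICE
  co <- generate_cohort(cohort_spec(seed = 61))
  std <- log_standardize(co$table[, grep("^B", colnames(co$table))])
  corr <- pairwise_complete_correlation(std)
  complete_ids <- colnames(std)[colSums(is.na(std)) == 0]
  sel <- select_all_auxiliary(corr, "B1_target",
                              setdiff(complete_ids, "B1_target"), n_aux = 10)
  r <- run_scenario(std, co$covariates, "B1_target", pct = 0.15,
                    mechanism = "MCAR", method = "mice_pmm", aux = sel$sets,
                    reps = 25, seed = 62)
  expect_lt(r$pct_bias, 5)
})
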
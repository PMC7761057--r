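test_that("pairwise-complete correlations match the brute-force oracle", {
  # full-overlap pair against the sum-formula oracle
  tb <- cbind(X = c(1, 2, 3, 4), Y = c(2, 4, 5, 4))
  rownames(tb) <- sprintf("S%d", 1:4)
  corr <- pairwise_complete_correlation(tb, min_overlap = 3)
  expect_equal(corr$r["X", "Y"], bf_pearson(tb[, "X"], tb[, "Y"]),
               tolerance = 1e-14)

  # a duplicated column correlates perfectly with itself
  tb2 <- cbind(A = c(1.2, 3.4, 2.2, 5.1, 4.4), B = c(1.2, 3.4, 2.2, 5.1, 4.4))
  rownames(tb2) <- sprintf("S%d", 1:5)
  corr2 <- pairwise_complete_correlation(tb2, min_overlap = 3)
  expect_equal(corr2$r["A", "B"], 1)

  # on a complete table every entry agrees with the dense oracle
  tb3 <- random_table(30, 6, miss_frac = 0, seed = 7)
  corr3 <- pairwise_complete_correlation(tb3)
  for (i in 1:5) for (j in (i + 1):6) {
    expect_equal(corr3$r[i, j], bf_pearson(tb3[, i], tb3[, j]),
                 tolerance = 1e-12)
  }

  # sparse pairwise missingness still matches the masked oracle
  tb4 <- random_table(40, 5, miss_frac = 0.25, seed = 8)
  corr4 <- pairwise_complete_correlation(tb4, min_overlap = 5)
  for (i in 1:4) for (j in (i + 1):5) {
    ov <- sum(!is.na(tb4[, i]) & !is.na(tb4[, j]))
    expect_equal(corr4$n_overlap[i, j], ov)
    if (ov >= 5) {
      expect_equal(corr4$r[i, j], bf_pearson(tb4[, i], tb4[, j]),
                   tolerance = 1e-12)
    }
  }
})

test_that("undefined entries: low overlap and constant columns", {
  tb <- cbind(A = c(1, 2, NA, NA, NA, NA), B = c(3, 5, NA, NA, NA, NA),
              C = c(7, 7, 7, 7, 7, 7))
  rownames(tb) <- sprintf("S%d", 1:6)
  corr <- pairwise_complete_correlation(tb, min_overlap = 5)
  expect_true(is.na(corr$r["A", "B"]))      # overlap 2 < 5
  expect_equal(corr$n_overlap["A", "B"], 2) # overlap count retained
  expect_true(is.na(corr$r["A", "C"]))      # constant on the overlap
  expect_equal(corr$r["C", "C"], NA_real_)  # constant diagonal undefined
})

test_that("auxiliary selection takes the top-|r| complete metabolites", {
  set.seed(21)
  n <- 40
  base <- rnorm(n)
  p <- 16
  tb <- sapply(seq_len(p), function(j) base * (1 - j / 20) + rnorm(n, 0, j / 10))
  colnames(tb) <- sprintf("C%02d", seq_len(p))
  tb <- cbind(tb, TGT = replace(base + rnorm(n, 0, 0.3), 1:5, NA))
  rownames(tb) <- sprintf("S%02d", seq_len(n))
  corr <- pairwise_complete_correlation(tb)
  sel <- select_auxiliary(corr, "TGT", sprintf("C%02d", seq_len(p)), n_aux = 10)
  expect_length(sel$aux_ids, 10)
  # the chosen ten are exactly the ten largest |r| among complete candidates
  absr <- abs(corr$r["TGT", sprintf("C%02d", seq_len(p))])
  expect_setequal(sel$aux_ids, names(sort(absr, decreasing = TRUE))[1:10])
  expect_equal(sel$aux_abs_r, sort(sel$aux_abs_r, decreasing = TRUE))
  expect_equal(sel$mean_abs_r, mean(sel$aux_abs_r))
  expect_false(sel$topped_up)

  # selection is invariant to row order and column order
  rp <- sample(n); cp <- sample(ncol(tb))
  corr_p <- pairwise_complete_correlation(tb[rp, cp])
  sel_p <- select_auxiliary(corr_p, "TGT", sprintf("C%02d", seq_len(p)), 10)
  expect_equal(sel_p$aux_ids, sel$aux_ids)
  expect_equal(sel_p$mean_abs_r, sel$mean_abs_r)
})

test_that("short candidate pools, ties, top-up and failure behave as specified", {
  # only 4 candidates with defined correlation -> all 4 returned
  set.seed(3)
  n <- 12
  tb <- cbind(A = rnorm(n), B = rnorm(n), C = rnorm(n), D = rnorm(n),
              TGT = replace(rnorm(n), 1:2, NA))
  rownames(tb) <- sprintf("S%02d", 1:n)
  corr <- pairwise_complete_correlation(tb)
  sel <- select_auxiliary(corr, "TGT", c("A", "B", "C", "D"), n_aux = 10)
  expect_setequal(sel$aux_ids, c("A", "B", "C", "D"))

  # exact tie at the boundary rank: lexicographically earlier id wins
  x <- c(1, 2, 3, 4, 5, 6)
  tgt <- x + 0.01 * c(1, -1, 1, -1, 1, -1)
  tb2 <- cbind(AAA = x, ZZZ = x, NEG = -tgt, TGT = replace(tgt, 1, NA))
  rownames(tb2) <- sprintf("S%d", 1:6)
  corr2 <- pairwise_complete_correlation(tb2, min_overlap = 3)
  # NEG correlates perfectly; AAA and ZZZ tie at the boundary rank 2
  sel2 <- select_auxiliary(corr2, "TGT", c("AAA", "ZZZ", "NEG"), n_aux = 2)
  expect_equal(abs(corr2$r["TGT", "AAA"]), abs(corr2$r["TGT", "ZZZ"]))
  expect_equal(sel2$aux_ids, c("NEG", "AAA"))
  expect_false("ZZZ" %in% sel2$aux_ids)

  # complete pool exhausted -> top-up from incomplete metabolites, flagged
  sel3 <- select_auxiliary(corr, "TGT", c("A", "B"), n_aux = 3)
  expect_length(sel3$aux_ids, 3)
  expect_true(sel3$topped_up)

  # no defined correlation at all -> selection error; bulk helper excludes
  tb3 <- cbind(A = c(1, 2, 3, 4, 5, 6),
               TGT = c(1.5, NA, NA, NA, NA, NA))
  rownames(tb3) <- sprintf("S%d", 1:6)
  corr3 <- pairwise_complete_correlation(tb3)
  expect_error(select_auxiliary(corr3, "TGT", "A"), "no defined correlations")
  bulk <- select_all_auxiliary(corr3, "TGT", "A")
  expect_equal(bulk$excluded, "TGT")
  expect_length(bulk$sets, 0)
})

test_that("mean absolute correlation lies in [0, 1] across random panels", {
  for (s in 1:5) {
    tb <- random_table(25, 8, miss_frac = 0.15, seed = 100 + s)
    corr <- pairwise_complete_correlation(tb)
    complete_ids <- colnames(tb)[colSums(is.na(tb)) == 0]
    targets <- colnames(tb)[colSums(is.na(tb)) > 0]
    sel <- select_all_auxiliary(corr, targets, complete_ids, n_aux = 4)
    for (st in sel$sets) {
      expect_gte(st$mean_abs_r, 0)
      expect_lte(st$mean_abs_r, 1)
    }
  }
})
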
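#' Specification of a synthetic metabolomics cohort
#'
#' Defaults describe the reference study conditions: 599 middle-aged
#' participants (age uniform on 45-65, sex balanced), four designated
#' complete target metabolites each embedded in an exchangeable-correlation
#' block of 10 complete "mates" at mean absolute correlation
#' 0.64 / 0.49 / 0.49 / 0.36, a set of incomplete endogenous/unannotated
#' filler metabolites carrying the partial missingness typical of such
#' panels, xenobiotic metabolites present in only a minority of samples,
#' and a BMI outcome linear in age, sex and the standardized targets.
#'
#' @param n_samples Cohort size.
#' @param block_rho Per-block exchangeable correlation, one entry per block;
#'   equals the expected mean absolute pairwise correlation of the block.
#' @param block_size Metabolites per block (target + mates).
#' @param n_incomplete Incomplete endogenous/unannotated filler metabolites.
#' @param endo_missing_range Range of the MCAR missing fraction drawn per
#'   filler metabolite.
#' @param n_xenobiotic Number of xenobiotic metabolites.
#' @param xeno_present_frac Fraction of samples in which each xenobiotic is
#'   present (observed); the rest are missing.
#' @param beta_metabolite BMI effect per SD of each designated target.
#' @param beta_age,beta_sex,intercept Remaining BMI model coefficients.
#' @param noise_sd Residual SD of BMI (kg/m^2).
#' @param seed Integer seed.
#' @return A list of class `"cohort_spec"`.
#' @export
cohort_spec <- function(n_samples = 599L,
                        block_rho = c(0.64, 0.49, 0.49, 0.36),
                        block_size = 11L,
                        n_incomplete = 20L,
                        endo_missing_range = c(0.05, 0.50),
                        n_xenobiotic = 6L,
                        xeno_present_frac = 0.20,
                        beta_metabolite = 1.0,
                        beta_age = 0.05,
                        beta_sex = 1.0,
                        intercept = 22,
                        noise_sd = 3,
                        seed = 1L) {
  if (any(block_rho <= 0 | block_rho >= 1))
    stop("'block_rho' entries must lie in (0, 1) for a positive-definite ",
         "exchangeable block")
  if (block_size < 2L) stop("'block_size' must be at least 2")
  if (xeno_present_frac < 0 || xeno_present_frac > 1)
    stop("'xeno_present_frac' must lie in [0, 1]")
  if (length(endo_missing_range) != 2L ||
      any(endo_missing_range < 0 | endo_missing_range >= 1) ||
      diff(endo_missing_range) < 0)
    stop("'endo_missing_range' must be an increasing pair in [0, 1)")
  structure(list(n_samples = as.integer(n_samples), block_rho = block_rho,
                 block_size = as.integer(block_size),
                 n_incomplete = as.integer(n_incomplete),
                 endo_missing_range = endo_missing_range,
                 n_xenobiotic = as.integer(n_xenobiotic),
                 xeno_present_frac = xeno_present_frac,
                 beta_metabolite = beta_metabolite, beta_age = beta_age,
                 beta_sex = beta_sex, intercept = intercept,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a synthetic cohort
#'
#' Per block, a latent standard normal factor model `Z_j = sqrt(rho) g +
#' sqrt(1 - rho) e_j` gives exchangeable correlation exactly `rho`
#' (positive-definite by construction); abundances are `exp(mu_j + s_j
#' Z_j)`, i.e. log-normal, so the workflow's log transform is exact. BMI is
#' `intercept + beta_age age + beta_sex sex + beta_metabolite *
#' sum_b standardized(target_b) + N(0, noise_sd)`; placing the effect on the
#' standardized target makes the generating coefficient scale-stable.
#' Xenobiotic columns are observed in a `xeno_present_frac` subset of
#' samples and missing elsewhere; filler columns carry MCAR missingness at
#' per-metabolite rates drawn from `endo_missing_range`.
#'
#' @param spec A [cohort_spec()].
#' @return A list of class `"synthetic_cohort"`: `table` (abundance matrix
#'   with `NA`s), `annotations`, `covariates` (`sample_id`, `age`, `sex`,
#'   `BMI`), and `truth` (generating coefficients, block correlations,
#'   `target_ids`, seed).
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  if (!inherits(spec, "cohort_spec")) stop("'spec' must be a cohort_spec")
  set.seed(spec$seed)
  n <- spec$n_samples
  n_blocks <- length(spec$block_rho)
  sample_ids <- sprintf("S%04d", seq_len(n))
  cols <- list(); ann <- list(); target_z <- list()
  target_ids <- character(n_blocks)
  pathways <- rep_len(c("lipid", "energy", "nucleotide", "amino_acid",
                        "carbohydrate", "peptide"), n_blocks)
  for (b in seq_len(n_blocks)) {
    rho <- spec$block_rho[b]
    g <- stats::rnorm(n)
    Z <- sqrt(rho) * g +
      sqrt(1 - rho) * matrix(stats::rnorm(n * spec$block_size), n)
    mu <- stats::runif(spec$block_size, 4, 9)
    sdl <- stats::runif(spec$block_size, 0.3, 1.0)
    ab <- exp(sweep(sweep(Z, 2L, sdl, `*`), 2L, mu, `+`))
    ids <- c(sprintf("B%d_target", b),
             sprintf("B%d_m%02d", b, seq_len(spec$block_size - 1L)))
    colnames(ab) <- ids
    target_ids[b] <- ids[1L]
    target_z[[b]] <- Z[, 1L]
    cols[[length(cols) + 1L]] <- ab
    ann[[length(ann) + 1L]] <- data.frame(metabolite_id = ids,
                                          class = "endogenous",
                                          super_pathway = pathways[b],
                                          sub_pathway = sprintf("block_%d", b),
                                          stringsAsFactors = FALSE)
  }
  if (spec$n_incomplete > 0L) {
    ids <- sprintf("F%02d", seq_len(spec$n_incomplete))
    mu <- stats::runif(spec$n_incomplete, 4, 9)
    sdl <- stats::runif(spec$n_incomplete, 0.3, 1.0)
    ab <- exp(sweep(sweep(matrix(stats::rnorm(n * spec$n_incomplete), n),
                          2L, sdl, `*`), 2L, mu, `+`))
    rate <- stats::runif(spec$n_incomplete, spec$endo_missing_range[1L],
                         spec$endo_missing_range[2L])
    for (j in seq_len(spec$n_incomplete)) {
      nmiss <- round_half_up(rate[j] * n)
      if (nmiss > 0) ab[sample.int(n, nmiss), j] <- NA_real_
    }
    colnames(ab) <- ids
    cols[[length(cols) + 1L]] <- ab
    ann[[length(ann) + 1L]] <- data.frame(
      metabolite_id = ids,
      class = rep_len(c("endogenous", "unannotated"), spec$n_incomplete),
      super_pathway = NA_character_, sub_pathway = NA_character_,
      stringsAsFactors = FALSE)
  }
  if (spec$n_xenobiotic > 0L) {
    ids <- sprintf("X%02d", seq_len(spec$n_xenobiotic))
    mu <- stats::runif(spec$n_xenobiotic, 2, 6)
    ab <- exp(sweep(matrix(stats::rnorm(n * spec$n_xenobiotic), n), 2L, mu, `+`))
    n_present <- round_half_up(spec$xeno_present_frac * n)
    for (j in seq_len(spec$n_xenobiotic)) {
      absent <- if (n_present < n)
        sample.int(n, n - n_present) else integer(0)
      ab[absent, j] <- NA_real_
    }
    colnames(ab) <- ids
    cols[[length(cols) + 1L]] <- ab
    ann[[length(ann) + 1L]] <- data.frame(metabolite_id = ids,
                                          class = "xenobiotic",
                                          super_pathway = "xenobiotics",
                                          sub_pathway = NA_character_,
                                          stringsAsFactors = FALSE)
  }
  table <- do.call(cbind, cols)
  rownames(table) <- sample_ids
  annotations <- do.call(rbind, ann)
  age <- stats::runif(n, 45, 65)
  sex <- stats::rbinom(n, 1L, 0.5)
  signal <- Reduce(`+`, lapply(target_z, function(z) drop(scale(z))), numeric(n))
  BMI <- spec$intercept + spec$beta_age * age + spec$beta_sex * sex +
    spec$beta_metabolite * signal + stats::rnorm(n, 0, spec$noise_sd)
  covariates <- data.frame(sample_id = sample_ids, age = age, sex = sex,
                           BMI = BMI, stringsAsFactors = FALSE)
  truth <- list(beta_metabolite = spec$beta_metabolite,
                beta_age = spec$beta_age, beta_sex = spec$beta_sex,
                intercept = spec$intercept, noise_sd = spec$noise_sd,
                block_rho = spec$block_rho, target_ids = target_ids,
                seed = spec$seed)
  structure(list(table = validate_metabolite_table(table),
                 annotations = validate_annotations(annotations),
                 covariates = covariates, truth = truth),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("<synthetic_cohort>", nrow(x$table), "samples x", ncol(x$table),
      "metabolites |", length(x$truth$target_ids), "designated targets\n")
  invisible(x)
}

# the hand-placed 8 x 6 table used for exact-oracle tests
tiny_cohort <- function() {
  table <- cbind(
    M1 = c(10.2, 12.8, 15.1, 17.9, 20.3, 23.2, 25.8, 28.4),
    M2 = c(98, 121, 151, 178, 204, 229, 262, 288),
    M3 = c(55.1, 48.2, 61.3, 40.9, 66.4, 35.7, 70.2, 44.8),
    M4 = c(5.1, 6.0, NA, 8.2, 9.1, 10.3, NA, 12.2),
    M5 = c(200.5, 180.4, 160.2, NA, 140.8, 120.1, 100.9, 80.3),
    M6 = c(NA, 3.2, NA, NA, 7.5, NA, 2.2, NA))
  rownames(table) <- sprintf("S%d", 1:8)
  annotations <- data.frame(
    metabolite_id = colnames(table),
    class = c("endogenous", "endogenous", "endogenous", "endogenous",
              "unannotated", "xenobiotic"),
    super_pathway = c("lipid", "lipid", "energy", "lipid", NA, "xenobiotics"),
    sub_pathway = NA_character_, stringsAsFactors = FALSE)
  covariates <- data.frame(sample_id = rownames(table),
                           age = c(46, 48, 51, 53, 56, 58, 61, 64),
                           sex = c(0, 1, 0, 1, 0, 1, 0, 1),
                           BMI = c(22.1, 24.5, 23.8, 26.2, 25.1, 27.9,
                                   26.5, 29.3),
                           stringsAsFactors = FALSE)
  list(table = table, annotations = annotations, covariates = covariates)
}

#' Write a named fixture bundle to disk
#'
#' `"tiny"` is a hand-placed 8 samples x 6 metabolites bundle for
#' exact-oracle tests; `"paper_like"` is a 599-sample synthetic cohort with
#' four designated complete targets in correlation blocks at mean |r| of
#' 0.64 / 0.49 / 0.49 / 0.36 plus incomplete and xenobiotic columns. All
#' files are plain CSV (plus a flat key: value truth sidecar) readable by
#' the package's own readers, and are byte-identical for identical seeds.
#'
#' @param name `"tiny"` or `"paper_like"`.
#' @param out_dir Output directory, created if needed.
#' @param seed Seed for the `"paper_like"` generator (ignored for tiny).
#' @return Named character vector of the files written (`metabolites`,
#'   `annotations`, `covariates`, and `truth` for paper_like), invisibly.
#' @export
make_fixture <- function(name = c("tiny", "paper_like"), out_dir,
                         seed = 1L) {
  name <- match.arg(name)
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE,
                                          showWarnings = FALSE)
  if (!ok || !dir.exists(out_dir)) stop("cannot create directory: ", out_dir)
  co <- if (name == "tiny") tiny_cohort() else
    generate_cohort(cohort_spec(seed = seed))
  paths <- c(metabolites = file.path(out_dir, paste0(name, "_metabolites.csv")),
             annotations = file.path(out_dir, paste0(name, "_annotations.csv")),
             covariates = file.path(out_dir, paste0(name, "_covariates.csv")))
  write_metabolite_table(co$table, paths["metabolites"])
  utils::write.table(co$annotations, paths["annotations"], sep = ",",
                     na = "", row.names = FALSE, quote = 1L,
                     fileEncoding = "UTF-8")
  utils::write.table(co$covariates, paths["covariates"], sep = ",",
                     na = "", row.names = FALSE, quote = 1L,
                     fileEncoding = "UTF-8")
  if (name == "paper_like") {
    paths["truth"] <- file.path(out_dir, paste0(name, "_truth.txt"))
    kv <- vapply(co$truth, function(v) paste(format(v, digits = 15),
                                             collapse = ","), character(1))
    writeLines(paste0(names(kv), ": ", kv), paths["truth"], useBytes = TRUE)
  }
  invisible(paths)
}
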
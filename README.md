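# metimpute

Class-aware imputation of missing values in untargeted metabolomics panels,
for epidemiologists and metabolomics analysts working with wide
samples-by-metabolites tables (e.g. Metabolon HD4 exports) where more than
half the metabolites contain missing cells.

## The method

Missingness in untargeted panels has two different causes, so `metimpute`
routes every metabolite by its class annotation and missing fraction:

* **Xenobiotic metabolites** (drugs, diet-derived compounds): a missing cell
  is read as true absence and imputed to **0** on the raw scale.
  Non-xenobiotic metabolites missing ≥ 90% of values are reclassified into
  this route.
* **Endogenous and unannotated metabolites** with 0 < missing fraction <
  90%: log-transformed, standardized (observed mean 0, variance 1), and
  imputed multivariately. For each incomplete target the 10 *complete*
  metabolites with the largest absolute pairwise-complete Pearson
  correlation become its **auxiliary metabolites**, and one of two imputers
  runs:
  * **kNN-obs-sel** — k-nearest-neighbours over observations: for a missing
    cell, donor samples are ranked by Euclidean distance over the target's
    auxiliaries (rescaled by √(n_total/n_shared) for partially shared
    auxiliaries) and the median of the k = 10 nearest donors' observed
    values is imputed;
  * **MICE-pmm** — chained equations with Bayesian predictive mean
    matching: each target is regressed on its auxiliaries + age + sex +
    BMI; β\* and σ\* are drawn from the posterior, and each missing cell
    receives the *observed* value of one of the d = 5 donors with the
    closest predicted means. m = 5 completed datasets are produced and
    downstream estimates pooled by Rubin's rules
    (T = W + (1 + 1/m)B, Barnard–Rubin df).

The package also ships the machinery to evaluate the two imputers by
simulation: a missingness simulator (MCAR, and probabilistic
limit-of-detection allocating 40/50/10% of masked cells to the
lower/middle/upper concentration tertiles), a factorial bias/RMSE harness
around the outcome model `BMI ~ age + sex + metabolite`, and a synthetic
cohort generator with block-correlated log-normal metabolites. See the
vignette `vignettes/imputation-workflow.Rmd` for the full methods account.

## Worked example

```r
library(metimpute)

# a 599-sample synthetic cohort: 4 correlation blocks (mean |r| 0.64/0.49/
# 0.49/0.36), 20 incomplete endogenous/unannotated fillers, 6 xenobiotics
co <- generate_cohort(cohort_spec(seed = 1))
#> <synthetic_cohort> 599 samples x 70 metabolites | 4 designated targets

build_plan(co$table, co$annotations)
#> <imputation_plan> cutoff = 0.9
#>   zero-impute: 6 (of which reclassified: 0 )
#>   multivariate: 20
#>   complete: 44

res <- impute_metabolites(co$table, co$annotations, co$covariates,
                          run_config(method = "mice_pmm", seed = 1))
#> <imputation_result> mice_pmm | m = 5 | targets: 20 | seed: 1

# analyse one imputed metabolite across the 5 datasets, pooled by Rubin
mets <- lapply(res$completed, function(tb) tb[, "F01"])
fit_outcome_model(co$covariates, mets)$pooled
#> <pooled_estimate> q_bar = 0.256174 (se 0.14833), W = 0.0206004,
#>                   B = 0.00116782, T = 0.0220018, df = 355, m = 5
```

The 6 xenobiotic columns were zero-imputed, the 20 incomplete fillers
imputed by MICE-pmm; `q_bar` is the pooled BMI coefficient of metabolite
`F01` and `T` its total (within + between imputation) variance.

Rerunning the method comparison on this cohort:

```r
g <- scenario_grid(n = c(50, 599), target_ids = "B1_target",
                   pct = c(0.15, 0.60), mechanism = "MCAR",
                   method = c("mice_pmm", "knn_obs_sel"), reps = 100)
run_grid(co$table, co$covariates, g, annotations = co$annotations, seed = 1)
#>   mechanism   n  pct      method truth est_mean pct_bias rmse_pct
#> 1      MCAR  50 0.15    mice_pmm 0.894    0.894   0.0379    19.72
#> 2      MCAR  50 0.15 knn_obs_sel 0.894    0.934   4.4883    16.36
#> 3      MCAR  50 0.60    mice_pmm 0.894    0.672  24.8019    67.01
#> 4      MCAR  50 0.60 knn_obs_sel 0.894    1.109  24.0854    43.34
#> 5      MCAR 599 0.15    mice_pmm 1.003    1.002   0.1617     4.33
#> 6      MCAR 599 0.15 knn_obs_sel 1.003    1.012   0.9184     4.60
#> 7      MCAR 599 0.60    mice_pmm 1.003    1.005   0.2116     9.54
#> 8      MCAR 599 0.60 knn_obs_sel 1.003    1.052   4.8205     9.82
```

`truth` is the complete-data coefficient of the target in each subcohort;
`pct_bias` is 100·|mean estimate − truth|/|truth| over the repetitions. The
table shows the expected pattern: at n = 599 MICE-pmm stays essentially
unbiased even with 60% missing (0.2%), while at n = 50 both methods
degrade badly; `plot_nested_loop(results)` draws the full factorial as a
nested-loop plot.

A thin CLI covering impute / simulate-missing / make-fixture / evaluate is
in `inst/scripts/metimpute-cli.R`.

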
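---
title: "Class-aware imputation of untargeted metabolomics data: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Class-aware imputation of untargeted metabolomics data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metimpute)
```

## The problem

Untargeted mass-spectrometry panels report over a thousand metabolites per
serum sample, and a large share of the matrix is missing. The missingness is
not homogeneous. For a *xenobiotic* metabolite — a drug or dietary compound —
an empty cell most plausibly means the compound is genuinely absent from
that person's system; imputing a concentration for a medication a
participant never took manufactures false signal. For *endogenous* and
*unannotated* metabolites, an empty cell is better read as a failed or
censored measurement of a compound that is actually present, often because
its concentration sits near the instrument's limit of detection. A single
imputation rule cannot serve both regimes, and the common habits — imputing
half the minimum everywhere, or dropping every metabolite above an arbitrary
missingness cut-off — either distort the distribution or throw data away.

`metimpute` implements a two-route workflow:

1. **Zero route.** Xenobiotic metabolites have their missing cells set to
   exactly 0 on the raw abundance scale. Non-xenobiotic metabolites missing
   at least 90% of their values (configurable, `high_missing_cutoff`) are
   *reclassified* into this route: with that little data they cannot support
   a multivariate model, and such features are usually mislabelled
   xenobiotics anyway. The boundary is closed on the zero side — a
   metabolite missing exactly the cutoff fraction is zero-imputed — because
   the multivariate route is reserved for metabolites with *less than* the
   cutoff missing.
2. **Multivariate route.** Remaining incomplete metabolites are imputed
   from their most-correlated peers ("auxiliary metabolites") with either
   kNN-obs-sel or MICE-pmm, described below.

Zero imputation happens before the log transform, because `log(0)` is
undefined: zero-routed metabolites are carried through on the raw scale
(with zeros) and reported in the provenance sidecar, while all other
non-xenobiotic metabolites are natural-log transformed and standardized to
observed mean 0, variance 1 (n − 1 denominator), computed on observed values
only. Completed output tables therefore mix two scales, which the sidecar
documents.

## Auxiliary selection

The pairwise-complete Pearson correlation matrix is computed among all
non-xenobiotic metabolites (complete and incomplete alike). A coefficient is
treated as *undefined* when fewer than `min_pairwise_overlap` (default 5)
samples observe both metabolites, or when either metabolite is constant on
the overlap; five joint observations is the least we are willing to call a
correlation at all, since two-point "correlations" are always ±1. The
correlation is computed on the standardized values; Pearson r is invariant
to affine rescaling, so this equals the raw-log correlation and the order of
the two steps is immaterial — standardizing first simply lets one matrix
serve both imputers.

For each incomplete target, the `n_aux = 10` *complete* metabolites with the
largest |r| are selected. If fewer than ten complete candidates have defined
correlations, all of them are taken; only if the set is still short is it
topped up from incomplete metabolites with defined correlations, and the
selection is flagged (`topped_up`) so it can be audited. Ties in |r| at the
boundary rank are broken by lexicographic metabolite id in C collation,
making selection deterministic and invariant to row and column order. A
target with no defined correlation at all cannot be imputed multivariately;
it is excluded and reported rather than silently guessed.

The mean absolute auxiliary correlation (`mean_abs_r`) is the single best
predictor of how well either imputer will do, which is why the evaluation
harness and the synthetic generator parameterise cohorts by it.

## kNN-obs-sel

For a missing cell (sample *i*, metabolite *j*), donors are the samples that
observe *j*. The distance from *i* to a donor is Euclidean over the
auxiliaries of *j* observed in both rows, rescaled by
√(n_aux_total / n_aux_shared); without the rescaling, a donor sharing only
one auxiliary would systematically look closer than one sharing all ten.
The imputation is the **median** of the k = 10 nearest donors' observed
*j*-values (configurable to the mean; all donors are used when fewer than k
exist). Distance ties at rank k are resolved by ascending sample id, so the
result is reproducible and independent of row order. Every target is imputed
against the original table, never against partially imputed data, so target
order cannot matter. A recipient sharing no observed auxiliary with any
donor falls back to the overall median of the target's observed values and
is counted.

The number of neighbours k is not dictated by the workflow being
reproduced; k = 10 mirrors the auxiliary count and the convention of the
benchmarking literature this method family comes from, and it is exposed
prominently (`knn_k`) because results do depend on it. Consequences of the
design: imputed values always lie within the observed range of the target,
and with weakly correlated auxiliaries the median shrinks imputed values
toward the centre of the distribution, attenuating downstream regression
coefficients — exactly the failure mode the evaluation harness measures.

## MICE-pmm

Each of `m = 5` chains initialises every incomplete target by sampling with
replacement from its observed margin, then performs `iterations = 5` sweeps
visiting targets in ascending missing-count order. Each visit regresses the
target's observed values on its auxiliaries (current completed values), the
covariates age, sex, and BMI, and an intercept. Including the analysis
outcome (BMI) and covariates among the predictors is required for the
imputation model to be congenial with the analysis model; omitting them
biases the pooled coefficients toward zero.

The elementary step is Bayesian predictive mean matching (type-1 matching):

* least squares with a ridge ε = 10⁻⁵ on the cross-product diagonal
  (auxiliary sets are selected *by* correlation and are frequently
  near-collinear);
* σ*² drawn as SSR/χ²(n_obs − rank), β* drawn from
  N(β̂, σ*²(XᵀX + εI)⁻¹);
* observed rows predicted with β̂, missing rows with β*; for each missing
  row one of the `d = 5` observed rows with the closest predictions is
  drawn uniformly and its observed value imputed.

Every imputed value is therefore a genuinely observed value of the same
metabolite — PMM's defining property, asserted as an exact set-membership
invariant in the tests. When the observed count is not larger than the model
rank the step raises a degrees-of-freedom error instead of fitting a
saturated model; the caller should shrink `n_aux` (the package deliberately
does not shrink it silently, since which auxiliaries enter the model is part
of the method). `iterations = 0` is rejected: the chained-equations
structure assumes at least one proper sweep after initialisation.

Visit order, initialisation, d, and the iteration count follow standard
chained-equations practice. One master seed generates per-chain seeds, so a
run is bitwise reproducible while chains remain mutually independent.

Analyses over the m completed datasets are pooled with Rubin's rules:
q̄ = mean of estimates, W = mean of squared SEs, B = sample variance of
estimates (0 when m = 1), T = W + (1 + 1/m)B, with Barnard–Rubin adjusted
degrees of freedom when the complete-data df is supplied (the outcome-model
helper passes n − 4). `m = 1` gives single-imputation mode for downstream
methods that cannot consume multiple datasets (lasso, random forests), at
the cost of the uncertainty assessment.

## Missingness simulation

Two mechanisms blank exactly `round(pct · n)` cells (rounding half away
from zero):

* **MCAR** draws positions uniformly without replacement.
* **PLoD** (probabilistic limit of detection) allocates the masked cells
  across the tertiles of the value distribution as **40% / 50% / 10%**
  (lower/middle/upper), then draws uniformly *within* each tertile. This is
  a missing-not-at-random mechanism: low concentrations are far more likely
  to vanish, as near the instrument detection limit, but not
  deterministically truncated.

Design choices that the three published shares do not fix: "quantile" is
read as tertiles because exactly three shares are given; tertile membership
is rank-based (the lowest ⌈n/3⌉ values form the lower tertile, ties broken
by position) because rank strata are distribution-free; the lower and middle
shares are rounded half-away-from-zero and the upper share takes the
remainder so the counts always sum to the total; and when a share exceeds
its tertile's size (unavoidable at, e.g., n = 50 with 60% missing), the
overflow spills to the adjacent lower-rank tertile first, then to the
remaining one. A smooth logistic-in-concentration mechanism would also match
the verbal description, but the tertile allocation is the only quantitative
statement available, so it is what is implemented.

## Evaluation harness

The harness reruns the factorial method comparison on any cohort with
complete designated targets. The analysis of interest is OLS

> BMI ~ intercept + age + sex + metabolite,

and the performance measures compare the coefficient estimated after
blank-and-impute against the *complete-data* coefficient of the same
(sub)cohort ("truth"): raw bias (signed), percentage bias
100·|bias|/|truth|, RMSE, and RMSE as a percentage of |truth|. The identity
rmse² = raw_bias² + est_sd²·(reps−1)/reps is asserted per scenario. The
RMSE percentage is defined as 100·rmse/|truth|; a subtraction-based variant
sometimes seen in figure captions is not a well-formed formula, so the
ratio form is used and stated here explicitly.

A full grid crosses mechanism × sample size × missing percentage ×
metabolite × method — with the reference levels (2 × 3 × 3 × 4 × 2) exactly
144 scenarios, 1000 repetitions each. Per sample size one subcohort is
drawn once and reused across all its scenarios, with sex, age and BMI
distributions preserved by proportional largest-remainder allocation over
sex × age-tertile × BMI-tertile cells. Auxiliaries are selected once per
subcohort from its complete data (they can differ slightly between
subcohorts); missingness is induced in the target metabolite only. A
repetition whose imputation fails is recorded; more than 5% failures aborts
the scenario — a conservative invented policy, since failures should not
occur under these conditions at all.

## The synthetic cohort generator

No cohort data ship with the package, so the generator produces data with
the statistical structure the workflow assumes, making every stage testable:

* **Correlation blocks.** Each designated target sits in a block of 11
  metabolites with exchangeable latent correlation ρ (factor construction
  `Z = √ρ·g + √(1−ρ)·e`, positive-definite by construction; empirical block
  correlations converge to ρ). ρ maps one-to-one onto the workflow's "mean
  absolute auxiliary correlation", and the default blocks use
  ρ = 0.64, 0.49, 0.49, 0.36 — the regimes spanned by the reference
  cohort's four simulation metabolites. Block mates are complete, so they
  become the selected auxiliaries and the regime label actually holds.
* **Class-dependent missingness** lives in dedicated columns: incomplete
  endogenous/unannotated "filler" metabolites with per-metabolite MCAR
  rates drawn from `endo_missing_range`, and xenobiotic columns observed in
  only `xeno_present_frac` of samples. Keeping the block mates complete
  while fillers carry the missingness is a deliberate deviation from a
  flat blocks-plus-xenobiotics layout: it preserves the mean-|r| regimes
  while still exercising the routing and the high-missingness rule.
* **Abundances are log-normal** (`exp(μ + σZ)`, μ ~ U(4,9), σ ~ U(0.3,1)),
  so positivity holds, skew is realistic, and the workflow's log transform
  recovers exact normality.
* **Covariates and outcome.** Age ~ U(45, 65), sex ~ Bernoulli(0.5) —
  a middle-aged cohort with balanced sex — and BMI = 22 + 0.05·age +
  1.0·sex + 1.0·Σ standardized(targets) + N(0, 3²). Placing the effect on
  the standardized target makes the generating coefficient scale-stable,
  and a 1 kg/m² shift per SD of metabolite against a residual SD of
  3 kg/m² gives each target a partial R² under 10% — a strong but
  plausible metabolite–adiposity association.

What the generator does **not** emulate: real pathway structure (blocks are
mutually independent, real panels correlate across pathways), heavy-tailed
technical noise, batch effects, and missingness that is correlated across
metabolites within a sample. Passing tests on synthetic cohorts therefore
demonstrate that the machinery implements its definitions and reproduces
the qualitative method behaviour (MICE improving with sample size, kNN
degrading with missingness when auxiliaries correlate weakly); they do not
certify performance on any particular real panel.

## Numerical and testing choices

* Deterministic everywhere randomness is not intrinsic: C-collation id
  ordering for every tie-break, one master seed with derived sub-seeds for
  chains, subcohorts and scenarios.
* The test suite runs the factorial grid end-to-end at reduced problem
  sizes (144 scenarios at 10 repetitions; the qualitative bias-pattern
  checks at 200 repetitions on the default 599-sample cohort). These sizes
  are the package's own choice of a thorough-but-quick default; the
  harness accepts the full 1000-repetition design unchanged.
* The 200-repetition monotonicity checks are stochastic, so they carry a
  tolerance of twice the Monte-Carlo standard error of the percentage-bias
  difference, computed from the recorded per-repetition estimate SDs.
* Round-half-away-from-zero is used wherever counts are derived from
  fractions, because base R's `round()` rounds half to even.

## Known limitations

* Xenobiotics are always zero-imputed; imputing them from medication or
  questionnaire data is out of scope.
* Clinical covariates are predictors only and must be complete; the package
  does not impute them.
* Small cohorts with the full 10-auxiliary conditional model can exhaust
  degrees of freedom; the PMM step errors rather than regularising, and
  penalised MICE variants are not provided.
* The harness evaluates bias and RMSE of point estimates, not variance
  estimators (type-I error, CI coverage).
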
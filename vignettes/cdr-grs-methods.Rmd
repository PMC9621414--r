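---
title: "Methods: the CDR genetic risk score and its cognitive-function models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the CDR genetic risk score and its cognitive-function models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cdrgrs)
```

## Scientific setting

Vertical cup-to-disc ratio (CDR) quantifies optic-nerve cupping; a CDR of
0.6 or more in either eye ("large CDR") is a biomarker of glaucomatous
neuropathy and is itself strongly heritable. In elderly women, large CDR has
been associated with lower global cognition on the Modified Mini-Mental
State Examination (3MSE, 0–100). The question this package operationalises
is whether that association is accounted for by the genetic component of
CDR: if a genetic risk score (GRS) built from CDR-associated variants
predicts large CDR but does not attenuate the CDR–3MSE association, the
cupping–cognition link is not simply shared genetics.

## Score construction

The scoring pipeline takes a candidate panel of SNPs discovered in
European-ancestry meta-analyses of vertical CDR (the shipped panel has 18;
see `cdr_candidate_panel()`), and applies three steps.

**Imputation-quality filter.** Imputed dosages are only as good as their
imputation R² (squared correlation between imputed and true genotypes).
SNPs with R² below a threshold are dropped; the default 0.8 separates the
one low-quality SNP on the shipped panel (R² = 0.56 at 11:65337251) from the
rest (R² > 0.89), and matches common practice for candidate-SNP scores.

**Per-SNP weights.** For each surviving SNP, `estimate_snp_weights()` fits
`large_cdr ~ dosage + age + pc1 + pc2` (logistic, additive coding). The
dosage coefficient is the SNP's weight. Fits that do not converge, are
quasi-separated (|log OR| > 10 or SE > 100), or sit on a degenerate dosage
column are flagged inestimable with a reason and excluded — never silently
zeroed.

**Concordance filter.** A SNP is kept only if the risk allele implied by the
local fit — the counted allele when the log OR is positive, the other allele
otherwise — equals the discovery risk allele. Discordant SNPs most likely
reflect winner's-curse or population differences and would inject noise of
the wrong sign. On the shipped panel's two published allele columns this
retains 13 of 17 SNPs (the discordant four sit in DUSP1, EXOC2, ADAMTS8 and
HSF2).

The score is then `GRS_j = Σ_i logOR_i G_ij`. `compute_grs()` re-orients
dosage columns coded on the opposite allele (`G → 2 − G`), is linear in
dosages and invariant to SNP order, and fails hard on missing dosages unless
per-SNP mean imputation is explicitly requested. Alleles are compared
literally — the panel and cohort are assumed strand-harmonised — and
strand-ambiguous A/T and C/G SNPs trigger a warning. Two weight sources are
exposed: `"internal"` (fit in the analysis cohort, the default and the route
behind the published weight table) and `"external"` (discovery effect sizes
supplied in the panel), since both are defensible when the discovery study
measured a related but different phenotype (continuous CDR vs. the binary
large-CDR flag).

## Association models and the outcome transform

3MSE scores pile up against the ceiling of 100, so linear models use
`log(102 − 3MSE)` — defined on all of [0, 100], monotone decreasing, and
approximately symmetrising. Models fitted:

* logistic `large_cdr ~ grs + age + pc1 + pc2`, reporting the odds ratio per
  unit GRS with a Wald 95% CI (`estimate ± 1.95996·SE`, exponentiated);
* OLS `log(102 − 3MSE) ~ grs + large_cdr + covariates` with the full
  adjustment set (age, education, smoking, diabetes, BMI class,
  cardiovascular disease, diabetic retinopathy, hormone-therapy arm),
  with or without a `grs:large_cdr` interaction. Categorical covariates are
  reference-coded on their first listed level. Rank deficiency is an error
  naming the collinear terms, not a silent drop.

The clinically interpretable effect of large CDR is reported on the 3MSE
scale by G-computation (`predicted_mean_difference()`): predict every
sample's transformed outcome under CDR = 1 and CDR = 0, back-transform via
`102 − exp(·)`, average, and difference. Back-transforming predictions of a
log-scale mean understates the arithmetic mean deficit; a Duan smearing
factor (mean exponentiated residual) is available behind `smearing = TRUE`,
but the default is the plain back-transform, which is the transparent,
assumption-light choice for a difference of two counterfactual means. Wald
CIs are used throughout (profile likelihood is out of scope).

## Descriptive tables and test selection

`build_descriptive_table()` reproduces the usual "Table 1 by stratum"
workflow with an explicit, logged rule: continuous variables get a
Shapiro–Wilk check at α = 0.05 in each stratum (on an evenly spaced
subsample of at most 5,000 values for large groups, keeping the check
deterministic) and then a Welch t-test if both pass, a Wilcoxon rank-sum
otherwise; categorical variables get Fisher's exact test when any observed
cell is ≤ 5 and Pearson's chi-square (no continuity correction) otherwise.
"Cell size" is read as the observed count; a config switch
(`cell_rule = "expected"`) applies the expected-count convention instead.
Welch is the default t-test variant — with 87 cases against 1,109 controls,
equal variances should not be assumed, and the summary-level Welch oracle
`welch_from_summary()` reproduces the published group comparison
(p ≈ 0.0198 from means 97.14/96.24, SDs 3.19/3.43, n 1109/87).

## The synthetic cohort: what it emulates and what it does not

No public data exist for the motivating cohort, so `simulate_cohort()`
generates cohorts under the minimal model for which the analysis above is
correctly specified:

* **Genotypes.** Independent Hardy–Weinberg draws per SNP. Default
  risk-allele frequency 0.52 at every SNP: under the published weights this
  gives E[GRS] = 2 × 0.52 × 1.3591 ≈ 1.41 and SD(GRS) ≈ 0.36, matching the
  published GRS summaries in the reference group. No linkage disequilibrium
  is simulated (the panel's SNPs sit on distinct loci) and no population
  structure beyond supplying PC columns as covariates.
* **Imputation noise.** `apply_imputation_noise()` adds Gaussian dosage
  perturbation scaled so the squared correlation with the hard calls hits
  each SNP's R² (then clips to [0, 2]) — the simplest mechanism with a
  controllable attenuation parameter. It is off by default in
  `simulate_cohort()`: risk is always generated from the dosages the analyst
  sees, so fitted weights estimate the generating log ORs rather than
  attenuated versions of them. Turning it on demonstrates classical
  regression dilution instead.
* **Large-CDR status.** Additive logistic risk,
  `P = plogis(c + Σ β_i G_i)`, with the intercept `c` calibrated by 1-D root
  finding so the cohort-average probability equals the target prevalence
  (default 0.0727) exactly, whatever the effect sizes. Default per-SNP
  truths: the published weight for each of the 13 concordant SNPs, −0.10 on
  the discovery allele for the 4 discordant ones (so the simulated cohort
  reproduces the observed discordance; no magnitude is published for them),
  and 0.05 for the low-R² SNP (filtered out regardless). Alternatively
  `grs_log_or` drives risk through the weighted GRS itself — used when the
  published odds ratio per GRS unit (2.30) is the quantity being recovered.
* **3MSE.** `u = intercept + 0.15·CDR + 0.03·(age − 70) + N(0, noise_sd)`
  on the log working scale, returned as `102 − exp(u)` clipped into
  [0, 100]. The CDR and age coefficients are the published ones. The
  residual SD on the log scale is not published; the default 0.45 (with
  intercept 1.488, i.e. mean 3MSE ≈ 97.1 at the reference) keeps the
  fraction of draws clipped at the ceiling of 100 under ~4.5%, so OLS on the
  transformed outcome stays essentially unbiased (empirical bias on the CDR
  coefficient ≈ −0.005). The cost is a marginal 3MSE SD of ≈ 2.3 versus the
  observed ≈ 3.2: real 3MSE data have a heavier ceiling (many exact-100
  scores) than this generator produces, which is the main acknowledged gap
  between passing tests here and behaviour on real data. Scores are kept
  continuous by default (`round_3mse = TRUE` coarsens them to the integer
  grid real instruments produce, at some cost to recovery precision).
* **Covariates.** Age truncated-normal (69.6 ± 3.62, range 63–79);
  education, smoking, BMI class, diabetes, cardiovascular disease,
  retinopathy and hormone-therapy arm drawn from the published baseline
  margins; PCs standard normal. Covariates are independent of genotype and,
  apart from age, have null outcome effects by default — so covariate
  adjustment is exercised structurally, not confounding-corrected.
* **QC artifacts.** Configurable counts of duplicate samples (same
  participant re-genotyped on a smaller platform), first-degree-relative
  pairs (one member assigned the smaller platform so the removal rule is
  deterministic), and missing PCA/CDR fields, all recorded in `qc_truth`
  so the QC chain can be checked against ground truth. The defaults in the
  examples (3 pairs, 28 missing) mirror the motivating cohort's published
  counts.

Identical seed and configuration reproduce a cohort bit for bit; every
stochastic stage takes an explicit seed, and compound stages derive child
seeds from the configuration seed.

## Numerical and design choices

* Prevalence calibration brackets the intercept in [−50, 50] and solves to
  tolerance 1e−10; the bracketing function is monotone, so failure can only
  come from an invalid target, which is reported with the offending
  parameters.
* Duplicate/relative resolution breaks platform ties deterministically
  (lexicographically smallest platform ID, then sample ID) and logs the tie;
  the published protocol specifies only "larger platform".
* Relative pairs are consumed as an input table: kinship estimation happened
  upstream of the motivating analysis (IBD during cohort harmonisation) and
  is out of scope. Chained pairs are processed in input order.
* The ethnicity-consistency check is a pass-through boolean (the motivating
  cohort identified no inconsistencies); a filter hook exists but defaults
  to a no-op.
* Missing dosages at scoring time fail hard by default; mean imputation is
  opt-in and logged.
* Coordinates are 1-based chromosome:position throughout, per VCF
  convention.
* The selection-flow arithmetic from the motivating study (2,339 White
  participants of 2,708, final n 1,196) cannot be regenerated without the
  controlled-access merge keys; the published stage counts are shipped as
  constants (`whi_selection_counts()`) and the QC module reports its own
  auditable counts on whatever cohort it is given.

## Validation problem sizes

Parameter-recovery checks in the test suite and acceptance script run at
n = 200,000, where the per-SNP sampling SE of a log OR is ≈ 0.013 and the
±0.05 recovery band is a ≥ 3.5σ margin (at n = 50,000 the same band is ~1.7σ
per SNP and a joint all-SNP check would fail by chance alone in a sizeable
fraction of runs). The outcome-coefficient check uses the same n, where the
±0.02 band dominates both the sampling SE (0.0035) and the small
ceiling-censoring bias (−0.005). Null-calibration checks (CI coverage of the
GRS odds ratio; type-I error of the interaction test, accepted band 3–7%)
use 500 and 2,000 Monte Carlo replicates respectively, keeping the Monte
Carlo SE of the estimated rate at or below ~1%/0.5%.

## Known limitations

* The generator's 3MSE ceiling is thinner than real data's; analyses
  sensitive to the exact-100 mass (e.g. median-based tests) will behave
  differently on real cohorts.
* Genotypes are simulated without LD, so the score's variance decomposition
  is exactly additive; on real panels residual LD between candidate SNPs
  would correlate weight estimates.
* The external-weight mode requires user-supplied discovery effect sizes
  (the shipped panel carries none), and no strand inference is attempted —
  inputs must be pre-harmonised.
* G-computation returns a point estimate; uncertainty on the back-transformed
  difference (delta method or bootstrap) is not implemented.
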
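#' Dosage matrix constructor
#'
#' A samples-by-SNPs numeric matrix of effect-allele dosages in `[0, 2]`,
#' carrying per-SNP allele coding metadata in the `"snp_info"` attribute
#' (columns `snp`, `counted_allele`, `other_allele`).
#'
#' @param mat Numeric matrix, rows = samples, columns = SNPs; `colnames`
#'   identify SNPs (chromosome:position keys).
#' @param snp_info `data.frame` with columns `snp`, `counted_allele`,
#'   `other_allele`, one row per matrix column.
#' @return An object of class `dosage_matrix`.
#' @export
new_dosage_matrix <- function(mat, snp_info) {
  if (!is.matrix(mat) || !is.numeric(mat)) stopf("mat must be a numeric matrix")
  if (is.null(colnames(mat))) stopf("dosage matrix requires SNP column names")
  need <- c("snp", "counted_allele", "other_allele")
  if (!all(need %in% names(snp_info)))
    stopf("snp_info must have columns %s", paste(need, collapse = ", "))
  if (!identical(colnames(mat), snp_info$snp))
    stopf("snp_info rows must match dosage matrix columns in order")
  if (any(mat < 0 | mat > 2, na.rm = TRUE))
    stopf("dosages must lie in [0, 2]")
  structure(mat, snp_info = snp_info, class = c("dosage_matrix", class(mat)))
}

#' @export
print.dosage_matrix <- function(x, ...) {
  cat(sprintf("<dosage_matrix: %d samples x %d SNPs>\n", nrow(x), ncol(x)))
  print(utils::head(unclass(x)[, seq_len(min(6L, ncol(x))), drop = FALSE]))
  invisible(x)
}

snp_info <- function(dosages) attr(dosages, "snp_info")

# Deterministic non-risk allele: transition partner of the counted allele,
# so no simulated SNP is strand-ambiguous (A/T or C/G).
other_allele_for <- function(allele) {
  c(A = "G", G = "A", C = "T", T = "C")[allele]
}

#' Simulation configuration
#'
#' Bundles every parameter of the synthetic-cohort generator. Defaults encode
#' the published study conditions: 7.27% large-CDR prevalence, per-SNP risk
#' effects equal to the published GRS weights for the 13 concordant SNPs
#' (opposite-allele effects of magnitude 0.10 for the 4 discordant ones),
#' outcome coefficients 0.15 (large CDR) and 0.03 (age, per year) on the
#' log(102 - 3MSE) scale, and a residual log-scale SD of 0.45 giving a
#' right-skewed 102 - 3MSE distribution with mean 3MSE near 97.
#'
#' @param n_samples Number of participants to simulate.
#' @param panel Candidate panel (default [cdr_candidate_panel()]).
#' @param risk_allele_freqs Per-SNP frequency of the discovery risk allele,
#'   strictly inside (0, 1); scalar recycled. Default 0.52, under which the
#'   published weights give a GRS with mean 1.41 and SD 0.36.
#' @param true_log_ors Named per-SNP additive log odds ratios on large-CDR
#'   risk (counted on the discovery risk allele).
#' @param baseline_prevalence Target large-CDR fraction, inside (0, 1).
#' @param outcome_coefs Named coefficients on the log(102 - 3MSE) scale;
#'   recognised names: `intercept`, `large_cdr`, `grs`, and any covariate
#'   column (age enters as `age_c`, years centred at 70).
#' @param noise_sd Residual SD of the outcome on the log scale.
#' @param grs_log_or Optional single log odds ratio applied to the weighted
#'   GRS (computed with the published weights) instead of per-SNP effects;
#'   `NULL` (default) uses `true_log_ors`.
#' @param apply_imputation_noise Logical; if `TRUE`, dosages are perturbed to
#'   the panel's imputation R-squared before the cohort is assembled (risk is
#'   always generated from the dosages the analyst sees, so the association
#'   models remain correctly specified).
#' @param round_3mse Logical; round scores to the integer grid (default
#'   `FALSE`, keeping scores continuous).
#' @param n_duplicate_samples,n_relative_pairs,n_missing_pca,n_missing_cdr
#'   QC artifact counts injected by [inject_qc_artifacts()].
#' @param seed Integer seed; identical seed and config reproduce the cohort
#'   bit for bit.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_samples = 1196L,
                              panel = cdr_candidate_panel(),
                              risk_allele_freqs = 0.52,
                              true_log_ors = default_true_log_ors(panel),
                              baseline_prevalence = 0.0727,
                              outcome_coefs = c(intercept = 1.488,
                                                large_cdr = 0.15,
                                                age_c = 0.03),
                              noise_sd = 0.45,
                              grs_log_or = NULL,
                              apply_imputation_noise = FALSE,
                              round_3mse = FALSE,
                              n_duplicate_samples = 0L,
                              n_relative_pairs = 0L,
                              n_missing_pca = 0L,
                              n_missing_cdr = 0L,
                              seed = 1L) {
  panel <- validate_panel(panel)
  if (length(risk_allele_freqs) == 1L)
    risk_allele_freqs <- rep(risk_allele_freqs, nrow(panel))
  if (length(risk_allele_freqs) != nrow(panel))
    stopf("risk_allele_freqs must have length 1 or nrow(panel)")
  assert_prob(risk_allele_freqs, "risk_allele_freqs")
  assert_prob(baseline_prevalence, "baseline_prevalence")
  if (!is.numeric(n_samples) || n_samples < 1) stopf("n_samples must be >= 1")
  if (is.null(names(true_log_ors)) ||
      !all(names(true_log_ors) %in% panel$chr_pos))
    stopf("true_log_ors must be named by panel chr_pos keys")
  counts <- c(n_duplicate_samples, n_relative_pairs, n_missing_pca,
              n_missing_cdr)
  if (any(counts < 0)) stopf("QC artifact counts must be non-negative")
  if (n_duplicate_samples + 2L * n_relative_pairs + n_missing_pca +
      n_missing_cdr > n_samples)
    stopf("QC artifact counts exceed n_samples")
  if (!is.finite(noise_sd) || noise_sd < 0) stopf("noise_sd must be >= 0")
  structure(list(
    n_samples = as.integer(n_samples), panel = panel,
    risk_allele_freqs = risk_allele_freqs, true_log_ors = true_log_ors,
    baseline_prevalence = baseline_prevalence, outcome_coefs = outcome_coefs,
    noise_sd = noise_sd, grs_log_or = grs_log_or,
    apply_imputation_noise = apply_imputation_noise, round_3mse = round_3mse,
    n_duplicate_samples = as.integer(n_duplicate_samples),
    n_relative_pairs = as.integer(n_relative_pairs),
    n_missing_pca = as.integer(n_missing_pca),
    n_missing_cdr = as.integer(n_missing_cdr),
    seed = as.integer(seed)
  ), class = "simulation_config")
}

#' Default per-SNP generative log odds ratios
#'
#' The published weight for each of the 13 concordant SNPs, a log odds ratio
#' of -0.10 on the discovery allele for the 4 discordant SNPs (so a large
#' in-cohort fit implies the opposite allele, as observed), and 0.05 for the
#' low-imputation-quality SNP (removed by the quality filter regardless).
#'
#' @param panel Candidate panel.
#' @return Named numeric vector keyed by `chr_pos`.
#' @export
default_true_log_ors <- function(panel = cdr_candidate_panel()) {
  w <- cdr_grs_weights()
  out <- stats::setNames(rep(-0.10, nrow(panel)), panel$chr_pos)
  out[w$snp] <- w$weight
  out["11:65337251"] <- 0.05
  out
}

#' Simulate Hardy-Weinberg genotypes
#'
#' Draws hard-call risk-allele dosages (0/1/2) independently per SNP under
#' Hardy-Weinberg equilibrium at the stated risk-allele frequencies.
#'
#' @param panel Candidate panel providing SNP keys and counted alleles.
#' @param risk_allele_freqs Per-SNP risk-allele frequency in (0, 1); scalar
#'   recycled.
#' @param n_samples Number of samples (rows).
#' @param seed Integer seed.
#' @return A [new_dosage_matrix()] of hard calls; the counted allele is the
#'   panel's discovery risk allele.
#' @export
simulate_genotypes <- function(panel, risk_allele_freqs, n_samples, seed = 1L) {
  panel <- validate_panel(panel)
  if (length(risk_allele_freqs) == 1L)
    risk_allele_freqs <- rep(risk_allele_freqs, nrow(panel))
  assert_prob(risk_allele_freqs, "risk_allele_freqs")
  if (n_samples < 1) stopf("n_samples must be >= 1")
  set.seed(seed)
  mat <- vapply(risk_allele_freqs,
                function(p) stats::rbinom(n_samples, 2L, p),
                integer(n_samples))
  mat <- matrix(as.numeric(mat), nrow = n_samples,
                dimnames = list(sprintf("S%05d", seq_len(n_samples)),
                                panel$chr_pos))
  info <- data.frame(
    snp = panel$chr_pos,
    counted_allele = panel$discovery_risk_allele,
    other_allele = unname(other_allele_for(panel$discovery_risk_allele)),
    stringsAsFactors = FALSE
  )
  new_dosage_matrix(mat, info)
}

#' Perturb hard calls to a target imputation quality
#'
#' Adds Gaussian dosage noise scaled so the squared correlation between the
#' returned continuous dosages and the input hard calls approximates each
#' SNP's imputation R-squared, then clips to `[0, 2]`. R-squared of 1 returns
#' the input unchanged.
#'
#' @param dosages Hard-call [new_dosage_matrix()].
#' @param panel_r2 Per-SNP R-squared in (0, 1], named by SNP key or in column
#'   order; scalar recycled.
#' @param seed Integer seed.
#' @return A `dosage_matrix` of continuous dosages.
#' @export
apply_imputation_noise <- function(dosages, panel_r2, seed = 1L) {
  if (length(panel_r2) == 1L) panel_r2 <- rep(panel_r2, ncol(dosages))
  if (!is.null(names(panel_r2))) panel_r2 <- panel_r2[colnames(dosages)]
  if (length(panel_r2) != ncol(dosages))
    stopf("panel_r2 must cover every dosage column")
  if (any(!is.finite(panel_r2)) || any(panel_r2 <= 0 | panel_r2 > 1))
    stopf("imputation R^2 must lie in (0, 1]")
  set.seed(seed)
  out <- unclass(dosages)
  for (j in seq_len(ncol(out))) {
    r2 <- panel_r2[j]
    if (r2 == 1) next
    p <- mean(out[, j]) / 2
    v <- 2 * p * (1 - p)
    sd_e <- sqrt(v * (1 - r2) / r2)
    out[, j] <- pmin(2, pmax(0, out[, j] + stats::rnorm(nrow(out), 0, sd_e)))
  }
  new_dosage_matrix(out, snp_info(dosages))
}

# Intercept c solving mean(plogis(c + eta)) = prevalence; monotone in c, so
# uniroot on a wide bracket always succeeds for prevalence in (0,1).
calibrate_prevalence_intercept <- function(eta, prevalence) {
  assert_prob(prevalence, "baseline_prevalence")
  f <- function(c0) mean(stats::plogis(c0 + eta)) - prevalence
  out <- tryCatch(
    stats::uniroot(f, lower = -50, upper = 50, tol = 1e-10),
    error = function(e) stopf(
      "prevalence calibration failed (target %.4f, linear-predictor range [%.2f, %.2f]): %s",
      prevalence, min(eta), max(eta), conditionMessage(e))
  )
  out$root
}

#' Simulate large-CDR status under an additive logistic model
#'
#' Each sample's large-CDR probability is
#' `plogis(intercept + sum(true_log_or[i] * G[i]) + covariate terms)`, with
#' the intercept calibrated by root finding so the cohort-average probability
#' equals `baseline_prevalence` exactly.
#'
#' @param dosages Dosage matrix (or plain numeric matrix).
#' @param true_log_ors Per-SNP log odds ratios, named by SNP key or in column
#'   order.
#' @param baseline_prevalence Target expected prevalence in (0, 1).
#' @param covariates Optional numeric matrix/data.frame of covariate columns.
#' @param covariate_coefs Named log odds ratios for `covariates` columns.
#' @param seed Integer seed.
#' @return Integer 0/1 vector with attributes `probability` (per-sample risk),
#'   `intercept` (calibrated), and `linear_predictor`.
#' @export
simulate_cdr_status <- function(dosages, true_log_ors, baseline_prevalence,
                                covariates = NULL, covariate_coefs = NULL,
                                seed = 1L) {
  mat <- unclass(dosages)
  if (!is.null(names(true_log_ors))) {
    miss <- setdiff(colnames(mat), names(true_log_ors))
    if (length(miss))
      stopf("true_log_ors missing for SNP(s): %s", paste(miss, collapse = ", "))
    true_log_ors <- true_log_ors[colnames(mat)]
  }
  if (length(true_log_ors) != ncol(mat))
    stopf("true_log_ors must cover every dosage column")
  eta <- drop(mat %*% true_log_ors)
  if (!is.null(covariate_coefs)) {
    cv <- as.matrix(as.data.frame(covariates)[, names(covariate_coefs),
                                              drop = FALSE])
    eta <- eta + drop(cv %*% covariate_coefs)
  }
  c0 <- calibrate_prevalence_intercept(eta, baseline_prevalence)
  pr <- stats::plogis(c0 + eta)
  set.seed(seed)
  y <- stats::rbinom(length(pr), 1L, pr)
  structure(as.integer(y), probability = pr, intercept = c0,
            linear_predictor = eta + c0)
}

#' Simulate 3MSE cognitive scores
#'
#' Draws the working-scale value `u = linear predictor + N(0, noise_sd)` on
#' the log(102 - 3MSE) scale and returns `3MSE = 102 - exp(u)`, clipped into
#' `[0, 100]`. A positive `large_cdr` coefficient therefore lowers mean 3MSE.
#' Values pushed below 0 (exp(u) > 102) trigger a clip-rate warning; the
#' fraction clipped at the ceiling of 100 is recorded in the
#' `"ceiling_rate"` attribute.
#'
#' @param cdr_status 0/1 large-CDR indicator.
#' @param covariates `data.frame` of covariate columns referenced by
#'   `outcome_coefs` (e.g. `age_c`, age in years centred at 70).
#' @param outcome_coefs Named coefficients on the log scale; `intercept` and
#'   `large_cdr` are recognised directly, all other names must be covariate
#'   columns.
#' @param noise_sd Residual SD on the log scale.
#' @param seed Integer seed.
#' @param round_scores Round to the integer 3MSE grid.
#' @return Numeric vector of 3MSE scores in `[0, 100]`.
#' @export
simulate_3mse <- function(cdr_status, covariates = NULL,
                          outcome_coefs = c(intercept = 1.488,
                                            large_cdr = 0.15, age_c = 0.03),
                          noise_sd = 0.45, seed = 1L, round_scores = FALSE) {
  n <- length(cdr_status)
  u <- rep(unname(outcome_coefs["intercept"]) %|NA|% 0, n)
  if ("large_cdr" %in% names(outcome_coefs))
    u <- u + outcome_coefs[["large_cdr"]] * as.numeric(cdr_status)
  rest <- setdiff(names(outcome_coefs), c("intercept", "large_cdr"))
  if (length(rest)) {
    cv <- as.data.frame(covariates)
    miss <- setdiff(rest, names(cv))
    if (length(miss))
      stopf("outcome_coefs name covariate(s) absent from `covariates`: %s",
            paste(miss, collapse = ", "))
    u <- u + drop(as.matrix(cv[, rest, drop = FALSE]) %*%
                    outcome_coefs[rest])
  }
  set.seed(seed)
  if (noise_sd > 0) u <- u + stats::rnorm(n, 0, noise_sd)
  score <- 102 - exp(u)
  n_floor <- sum(score < 0)
  n_ceil <- sum(score > 100)
  if (n_floor > 0)
    warnf("%d of %d scores (%.2f%%) fell below 0 and were clipped",
          n_floor, n, 100 * n_floor / n)
  score <- pmin(100, pmax(0, score))
  if (round_scores) score <- round(score)
  structure(score, ceiling_rate = n_ceil / n)
}

`%|NA|%` <- function(a, b) if (is.na(a)) b else a

# Baseline covariate margins of the analysis cohort (no-large-CDR column of
# the published characteristics table).
covariate_margins <- function() {
  list(
    education = c("No High School" = 0.0397, "High School" = 0.2462,
                  "Post High School" = 0.3895, "College Graduate" = 0.3246),
    smoking = c("Never Smoked" = 0.5744, "Former Smoker" = 0.3697,
                "Current Smoker" = 0.0559),
    bmi_class = c("Underweight" = 0.0081, "Normal" = 0.2904,
                  "Overweight" = 0.3436, "Obesity Class 1" = 0.2417,
                  "Obesity Class 2" = 0.0821, "Extreme Obesity" = 0.0343),
    diabetes = 0.0821, cvd = 0.1605, retinopathy = 0.0243,
    ht_arm = c("E-alone intervention" = 0.1704, "E-alone control" = 0.2020,
               "E+P intervention" = 0.3093, "E+P control" = 0.3183)
  )
}

#' Simulate baseline covariates
#'
#' Ages are truncated normal (mean 69.6, SD 3.62, range 63-79); categorical
#' covariates are drawn from the analysis cohort's published margins; PC-1
#' and PC-2 are standard normal ancestry axes.
#'
#' @param n Number of samples.
#' @param seed Integer seed.
#' @return `data.frame` with `age`, `age_c` (age - 70), factor covariates,
#'   `pc1`, `pc2`.
#' @export
simulate_covariates <- function(n, seed = 1L) {
  set.seed(seed)
  age <- stats::rnorm(n, 69.6, 3.62)
  while (any(bad <- age < 63 | age > 79))
    age[bad] <- stats::rnorm(sum(bad), 69.6, 3.62)
  m <- covariate_margins()
  draw <- function(p) factor(sample(names(p), n, replace = TRUE, prob = p),
                             levels = names(p))
  data.frame(
    age = age, age_c = age - 70,
    education = draw(m$education), smoking = draw(m$smoking),
    bmi_class = draw(m$bmi_class),
    diabetes = stats::rbinom(n, 1L, m$diabetes),
    cvd = stats::rbinom(n, 1L, m$cvd),
    retinopathy = stats::rbinom(n, 1L, m$retinopathy),
    ht_arm = draw(m$ht_arm),
    pc1 = stats::rnorm(n), pc2 = stats::rnorm(n),
    stringsAsFactors = FALSE
  )
}

#' Simulate a full analysis cohort
#'
#' Runs the generator end to end: Hardy-Weinberg genotypes, optional
#' imputation-quality noise, large-CDR status from the additive logistic
#' model (calibrated to the target prevalence), covariates, 3MSE scores on
#' the log working scale, and injected QC artifacts.
#'
#' @param config A [simulation_config()].
#' @return A list of class `simulated_cohort`: `dosages`, `phenotypes`,
#'   `samples` (QC sample records), `relative_pairs`, `qc_truth`, `config`.
#' @export
simulate_cohort <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  seeds <- child_seeds(config$seed, 6L)
  dos <- simulate_genotypes(config$panel, config$risk_allele_freqs,
                            config$n_samples, seed = seeds[1])
  if (isTRUE(config$apply_imputation_noise)) {
    r2 <- stats::setNames(config$panel$imputation_r2, config$panel$chr_pos)
    dos <- apply_imputation_noise(dos, r2, seed = seeds[2])
  }
  covs <- simulate_covariates(config$n_samples, seed = seeds[3])

  if (!is.null(config$grs_log_or)) {
    w <- cdr_grs_weights()
    grs_true <- drop(unclass(dos)[, w$snp, drop = FALSE] %*% w$weight)
    cdr <- simulate_cdr_status(matrix(grs_true, ncol = 1,
                                      dimnames = list(rownames(dos), "GRS")),
                               config$grs_log_or,
                               config$baseline_prevalence, seed = seeds[4])
  } else {
    cdr <- simulate_cdr_status(dos, config$true_log_ors,
                               config$baseline_prevalence, seed = seeds[4])
  }
  mse3 <- simulate_3mse(cdr, covs, config$outcome_coefs, config$noise_sd,
                        seed = seeds[5], round_scores = config$round_3mse)
  ph <- data.frame(
    sample_id = rownames(dos),
    participant_id = sub("^S", "P", rownames(dos)),
    large_cdr = as.integer(cdr), mse3 = as.numeric(mse3), covs,
    stringsAsFactors = FALSE
  )
  samples <- data.frame(
    sample_id = ph$sample_id, participant_id = ph$participant_id,
    platform_id = "GWAS_A", platform_snp_count = 900000L,
    has_pca = TRUE, has_cdr = TRUE,
    self_reported_ethnicity = "White", pca_ethnicity_consistent = TRUE,
    stringsAsFactors = FALSE
  )
  cohort <- structure(list(
    dosages = dos, phenotypes = ph, samples = samples,
    relative_pairs = data.frame(sample_a = character(), sample_b = character(),
                                stringsAsFactors = FALSE),
    qc_truth = list(duplicates = character(), relative_removed = character(),
                    missing_pca = character(), missing_cdr = character(),
                    expected_retained = ph$sample_id),
    config = config
  ), class = "simulated_cohort")
  inject_qc_artifacts(cohort, config, seed = seeds[6])
}

#' @export
print.simulated_cohort <- function(x, ...) {
  cat(sprintf(paste0("<simulated_cohort: %d samples, %d SNPs, prevalence ",
                     "%.3f, %d QC artifacts>\n"),
              nrow(x$phenotypes), ncol(x$dosages),
              mean(x$phenotypes$large_cdr, na.rm = TRUE),
              length(x$qc_truth$duplicates) +
                length(x$qc_truth$relative_removed) +
                length(x$qc_truth$missing_pca) +
                length(x$qc_truth$missing_cdr)))
  invisible(x)
}

#' Inject QC artifacts into a simulated cohort
#'
#' Adds duplicate genetic samples (copies of a participant's genotypes on a
#' smaller platform), flags first-degree-relative pairs (one member assigned
#' the smaller platform), and blanks PCA or CDR fields for the configured
#' numbers of samples. Artifact groups are disjoint and every injection is
#' recorded in `qc_truth`.
#'
#' @param cohort A `simulated_cohort`.
#' @param config A [simulation_config()] (its `n_*` artifact counts are
#'   used).
#' @param seed Integer seed.
#' @return The modified `simulated_cohort`.
#' @export
inject_qc_artifacts <- function(cohort, config, seed = 1L) {
  n_dup <- config$n_duplicate_samples
  n_rel <- config$n_relative_pairs
  n_mpca <- config$n_missing_pca
  n_mcdr <- config$n_missing_cdr
  n <- nrow(cohort$phenotypes)
  if (n_dup + 2L * n_rel + n_mpca + n_mcdr > n)
    stopf("QC artifact counts exceed cohort size")
  if (n_dup + n_rel + n_mpca + n_mcdr == 0L) return(cohort)
  set.seed(seed)
  picks <- sample(cohort$phenotypes$sample_id,
                  n_dup + 2L * n_rel + n_mpca + n_mcdr)
  dup_ids <- picks[seq_len(n_dup)]
  rel_ids <- picks[n_dup + seq_len(2L * n_rel)]
  mpca_ids <- picks[n_dup + 2L * n_rel + seq_len(n_mpca)]
  mcdr_ids <- picks[n_dup + 2L * n_rel + n_mpca + seq_len(n_mcdr)]

  ph <- cohort$phenotypes
  samples <- cohort$samples
  dos <- unclass(cohort$dosages)

  if (n_dup > 0L) {
    idx <- match(dup_ids, ph$sample_id)
    new_ids <- paste0(dup_ids, "_b")
    dup_ph <- ph[idx, , drop = FALSE]
    dup_ph$sample_id <- new_ids
    ph <- rbind(ph, dup_ph)
    dup_sm <- samples[idx, , drop = FALSE]
    dup_sm$sample_id <- new_ids
    dup_sm$platform_id <- "GWAS_B"
    dup_sm$platform_snp_count <- 550000L
    samples <- rbind(samples, dup_sm)
    dup_rows <- dos[idx, , drop = FALSE]
    rownames(dup_rows) <- new_ids
    dos <- rbind(dos, dup_rows)
  }
  rel_pairs <- cohort$relative_pairs
  rel_removed <- character()
  if (n_rel > 0L) {
    a <- rel_ids[seq_len(n_rel)]
    b <- rel_ids[n_rel + seq_len(n_rel)]
    # the second member moves to the smaller platform, making the
    # platform-based removal rule deterministic
    samples$platform_id[samples$sample_id %in% b] <- "GWAS_B"
    samples$platform_snp_count[samples$sample_id %in% b] <- 550000L
    rel_pairs <- rbind(rel_pairs,
                       data.frame(sample_a = a, sample_b = b,
                                  stringsAsFactors = FALSE))
    rel_removed <- b
  }
  if (n_mpca > 0L) {
    ph$pc1[ph$sample_id %in% mpca_ids] <- NA_real_
    ph$pc2[ph$sample_id %in% mpca_ids] <- NA_real_
    samples$has_pca[samples$sample_id %in% mpca_ids] <- FALSE
  }
  if (n_mcdr > 0L) {
    ph$large_cdr[ph$sample_id %in% mcdr_ids] <- NA_integer_
    samples$has_cdr[samples$sample_id %in% mcdr_ids] <- FALSE
  }
  rownames(ph) <- NULL
  rownames(samples) <- NULL
  cohort$phenotypes <- ph
  cohort$samples <- samples
  cohort$dosages <- new_dosage_matrix(dos, snp_info(cohort$dosages))
  cohort$relative_pairs <- rel_pairs
  cohort$qc_truth <- list(
    duplicates = if (n_dup) paste0(dup_ids, "_b") else character(),
    relative_removed = rel_removed,
    missing_pca = mpca_ids, missing_cdr = mcdr_ids,
    expected_retained = setdiff(ph$sample_id,
                                c(if (n_dup) paste0(dup_ids, "_b"),
                                  rel_removed, mpca_ids, mcdr_ids))
  )
  cohort
}
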
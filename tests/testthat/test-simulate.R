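panel <- cdr_candidate_panel()

test_that("genotypes follow Hardy-Weinberg proportions and the binomial mean", {
  g <- simulate_genotypes(panel[1, ], 0.3, 50000, seed = 11)
  d <- unclass(g)[, 1]
  se <- sqrt(2 * 0.3 * 0.7 / 50000)
  expect_lt(abs(mean(d) - 0.6), 3 * se)
  # HWE chi-square goodness of fit (1 df) across many seeds and columns
  hwe_p <- function(d) {
    obs <- tabulate(d + 1, 3)
    p <- mean(d) / 2
    expctd <- length(d) * c((1 - p)^2, 2 * p * (1 - p), p^2)
    stats::pchisq(sum((obs - expctd)^2 / expctd), df = 1, lower.tail = FALSE)
  }
  pass <- unlist(lapply(1:20, function(s) {
    g <- simulate_genotypes(panel, seq(0.2, 0.6, length.out = 18), 10000,
                            seed = s)
    apply(unclass(g), 2, hwe_p) > 0.001
  }))
  expect_gte(mean(pass), 0.99)
  expect_error(simulate_genotypes(panel, 0, 10), "risk_allele_freqs")
  expect_error(simulate_genotypes(panel, 1, 10), "risk_allele_freqs")
})

test_that("generation is bit-identical under an identical seed and config", {
  cfg <- simulation_config(n_samples = 400, n_duplicate_samples = 2,
                           n_relative_pairs = 3, n_missing_pca = 4,
                           n_missing_cdr = 5, seed = 42)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$phenotypes, b$phenotypes)
  expect_identical(unclass(a$dosages), unclass(b$dosages))
  expect_identical(a$qc_truth, b$qc_truth)
})

test_that("imputation noise hits the target R2 and respects the no-noise limit", {
  g <- simulate_genotypes(panel[1:2, ], 0.3, 20000, seed = 5)
  same <- apply_imputation_noise(g, c(1, 1), seed = 9)
  expect_identical(unclass(same), unclass(g))
  noisy <- apply_imputation_noise(g, 0.56, seed = 9)
  r2 <- cor(unclass(noisy)[, 1], unclass(g)[, 1])^2
  expect_gt(r2, 0.50)
  expect_lt(r2, 0.62)
  expect_true(all(unclass(noisy) >= 0 & unclass(noisy) <= 2))
  again <- apply_imputation_noise(g, 0.56, seed = 9)
  expect_identical(unclass(noisy), unclass(again))
  expect_error(apply_imputation_noise(g, 0), "R\\^2")
})

test_that("prevalence intercept calibration reproduces the target", {
  g <- simulate_genotypes(panel, 0.52, 100000, seed = 3)
  cdr <- simulate_cdr_status(g, default_true_log_ors(panel), 0.0727, seed = 3)
  expect_lt(abs(mean(attr(cdr, "probability")) - 0.0727), 1e-6)
  # null effects: observed prevalence within 3 SE of the target
  cdr0 <- simulate_cdr_status(g, setNames(rep(0, 18), panel$chr_pos), 0.0727,
                              seed = 4)
  se <- sqrt(0.0727 * (1 - 0.0727) / 100000)
  expect_lt(abs(mean(cdr0) - 0.0727), 3 * se)
})

test_that("risk is additive on the logit scale", {
  g <- make_dosages(matrix(c(0, 1, 2), ncol = 1))
  cdr <- simulate_cdr_status(g, log(2), 0.2, seed = 1)
  pr <- attr(cdr, "probability")
  odds <- pr / (1 - pr)
  expect_equal(unname(odds[3] / odds[1]), 4, tolerance = 1e-10)
  expect_equal(unname(odds[2] / odds[1]), 2, tolerance = 1e-10)
})

test_that("3MSE generation inverts the log working scale", {
  s <- simulate_3mse(rep(0, 5), outcome_coefs = c(intercept = 1.5),
                     noise_sd = 0, seed = 1)
  expect_equal(as.numeric(s), rep(102 - exp(1.5), 5))
  # a positive large-CDR coefficient lowers the mean score
  cdr <- rep(c(0L, 1L), each = 20000)
  s2 <- simulate_3mse(cdr, outcome_coefs = c(intercept = 1.488,
                                             large_cdr = 0.15),
                      noise_sd = 0.45, seed = 2)
  expect_lt(mean(s2[cdr == 1]), mean(s2[cdr == 0]))
  # the deficit scale 102 - 3MSE is right-skewed under the defaults
  deficit <- 102 - s2
  skew <- mean((deficit - mean(deficit))^3) / stats::sd(deficit)^3
  expect_gt(skew, 0)
  expect_true(all(s2 >= 0 & s2 <= 100))
  # extreme coefficients clip at zero with a warning
  expect_warning(
    simulate_3mse(rep(1, 50), outcome_coefs = c(intercept = 5, large_cdr = 1),
                  noise_sd = 0.1, seed = 3),
    "clipped")
})

test_that("refitting the generating outcome model recovers its coefficients", {
  cfg <- simulation_config(n_samples = 200000, seed = 77)
  ch <- simulate_cohort(cfg)
  dat <- ch$phenotypes
  dat$grs <- compute_grs(ch$dosages, cdr_grs_weights())
  fit <- fit_3mse_linear(dat)
  co <- fit$coefficients
  expect_lt(abs(co$estimate[co$term == "large_cdr"] - 0.15), 0.02)
  expect_lt(abs(co$estimate[co$term == "age"] - 0.03), 0.005)
})

test_that("QC artifact injection matches the requested counts exactly", {
  cfg0 <- simulation_config(n_samples = 300, seed = 5)
  ch0 <- simulate_cohort(cfg0)
  expect_equal(nrow(ch0$phenotypes), 300L)
  expect_equal(length(ch0$qc_truth$missing_pca), 0L)
  expect_equal(ch0$qc_truth$expected_retained, ch0$phenotypes$sample_id)

  cfg <- simulation_config(n_samples = 300, n_duplicate_samples = 2,
                           n_relative_pairs = 3, n_missing_pca = 14,
                           n_missing_cdr = 14, seed = 5)
  ch <- simulate_cohort(cfg)
  expect_equal(nrow(ch$phenotypes), 302L)  # duplicates add rows
  expect_equal(nrow(ch$relative_pairs), 3L)
  expect_equal(length(unique(unlist(ch$relative_pairs))), 6L)
  flagged <- c(ch$qc_truth$missing_pca, ch$qc_truth$missing_cdr)
  expect_equal(length(flagged), 28L)
  expect_equal(anyDuplicated(flagged), 0L)
  expect_equal(sum(is.na(ch$phenotypes$pc1)), 14L)
  expect_equal(sum(is.na(ch$phenotypes$large_cdr)), 14L)
  expect_error(
    simulation_config(n_samples = 10, n_missing_pca = 11),
    "exceed")
})

test_that("dosage values stay in range through the pipeline stages", {
  cfg <- simulation_config(n_samples = 500, apply_imputation_noise = TRUE,
                           seed = 8)
  ch <- simulate_cohort(cfg)
  d <- unclass(ch$dosages)
  expect_true(all(d >= 0 & d <= 2))
  # hard calls before noise are integers
  g <- simulate_genotypes(panel, 0.52, 500, seed = 8)
  expect_true(all(unclass(g) %in% c(0, 1, 2)))
})
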
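test_that("the 3MSE working-scale transform round-trips and hits its bounds", {
  expect_equal(transform_3mse(100), log(2))
  expect_equal(transform_3mse(0), log(102))
  x <- seq(0, 100, by = 0.25)
  expect_equal(inverse_transform_3mse(transform_3mse(x)), x,
               tolerance = 1e-12)
  expect_true(all(diff(transform_3mse(x)) < 0))  # monotone decreasing
  expect_error(transform_3mse(-1), "0, 100")
  expect_error(transform_3mse(101), "0, 100")
})

test_that("unadjusted logistic fit equals the 2x2 closed-form odds ratio", {
  x <- rep(c(1, 0), c(50, 60))
  y <- c(rep(c(1L, 0L), c(20, 30)), rep(c(1L, 0L), c(15, 45)))
  fit <- fit_grs_cdr_logistic(x, y)
  or <- fit$coefficients$or[fit$coefficients$term == "grs"]
  expect_equal(or, (20 * 45) / (30 * 15), tolerance = 1e-6)
})

test_that("logistic fits agree with a hand-rolled IRLS oracle", {
  set.seed(33)
  for (rep in 1:5) {
    n <- 150
    grs <- rnorm(n, 1.4, 0.35)
    age <- rnorm(n, 70, 3.5)
    pc1 <- rnorm(n)
    pc2 <- rnorm(n)
    y <- rbinom(n, 1, plogis(-2 + 0.8 * grs))
    if (length(unique(y)) < 2) next
    fit <- fit_grs_cdr_logistic(grs, y, age, pc1, pc2)
    X <- cbind(1, grs, age, pc1, pc2)
    expect_equal(fit$coefficients$estimate,
                 unname(irls_logistic(X, y)), tolerance = 1e-6)
  }
})

test_that("OLS coefficients agree with the normal-equations solution", {
  cfg <- simulation_config(n_samples = 800, seed = 12)
  ch <- simulate_cohort(cfg)
  dat <- ch$phenotypes
  dat$grs <- compute_grs(ch$dosages, cdr_grs_weights())
  fit <- fit_3mse_linear(dat)
  X <- model.matrix(fit$fit)
  y <- transform_3mse(dat$mse3)
  expect_equal(unname(coef(fit$fit)), normal_eq_ols(X, y), tolerance = 1e-8)
  # Wald CI reproduces estimate +/- 1.95996 SE
  co <- fit$coefficients
  expect_equal(co$ci_lo, co$estimate - qnorm(0.975) * co$se)
  expect_equal(co$ci_hi, co$estimate + qnorm(0.975) * co$se)
})

test_that("row duplication keeps OLS estimates and shrinks SEs by sqrt(2)", {
  cfg <- simulation_config(n_samples = 600, seed = 14)
  ch <- simulate_cohort(cfg)
  dat <- ch$phenotypes
  dat$grs <- compute_grs(ch$dosages, cdr_grs_weights())
  fit1 <- fit_3mse_linear(dat, covariates = "age")
  fit2 <- fit_3mse_linear(rbind(dat, dat), covariates = "age")
  expect_equal(fit2$coefficients$estimate, fit1$coefficients$estimate,
               tolerance = 1e-10)
  n <- nrow(dat)
  p <- length(coef(fit1$fit))
  ratio <- fit1$coefficients$se / fit2$coefficients$se
  # exact finite-sample ratio, which converges to sqrt(2)
  expect_equal(ratio, rep(sqrt((2 * n - p) / (n - p)), p), tolerance = 1e-10)
  expect_equal(ratio, rep(sqrt(2), p), tolerance = 0.01)
})

test_that("rank-deficient designs fail loudly, naming the collinear term", {
  cfg <- simulation_config(n_samples = 200, seed = 15)
  ch <- simulate_cohort(cfg)
  dat <- ch$phenotypes
  dat$grs <- compute_grs(ch$dosages, cdr_grs_weights())
  dat$age2 <- dat$age  # exact copy
  expect_error(fit_3mse_linear(dat, covariates = c("age", "age2")),
               "collinear.*age2")
})

test_that("G-computation mean difference matches a closed form and nulls", {
  cfg <- simulation_config(n_samples = 2000, seed = 16)
  ch <- simulate_cohort(cfg)
  dat <- ch$phenotypes
  dat$grs <- compute_grs(ch$dosages, cdr_grs_weights())
  fit <- fit_3mse_linear(dat)
  # zero out the contrast coefficient -> difference is exactly 0
  fit0 <- fit
  fit0$fit$coefficients["large_cdr"] <- 0
  expect_equal(predicted_mean_difference(fit0, dat), 0, tolerance = 1e-12)
  # closed form: with coefficient b, diff = (exp(b) - 1) * mean(exp(pred0))
  b <- coef(fit$fit)[["large_cdr"]]
  d0 <- dat
  d0$large_cdr <- 0
  p0 <- predict(fit$fit, newdata = d0)
  expect_equal(predicted_mean_difference(fit, dat),
               (exp(b) - 1) * mean(exp(p0)), tolerance = 1e-6)
  expect_error(predicted_mean_difference(fit, dat, contrast_term = "nope"),
               "not in the fitted model")
  # smearing scales both counterfactual means by the same Duan factor
  sm <- predicted_mean_difference(fit, dat, smearing = TRUE)
  expect_equal(sm, (exp(b) - 1) * mean(exp(p0)) *
                 mean(exp(residuals(fit$fit))), tolerance = 1e-6)
})

test_that("noise-free generation reproduces the population contrast exactly", {
  n <- 5000
  set.seed(17)
  cdr <- rbinom(n, 1, 0.3)
  age_c <- rnorm(n, 0, 3.6)
  s <- simulate_3mse(cdr, data.frame(age_c = age_c),
                     outcome_coefs = c(intercept = 1.4, large_cdr = 0.15,
                                       age_c = 0.03),
                     noise_sd = 0, seed = 18)
  dat <- data.frame(mse3 = as.numeric(s), large_cdr = cdr, age = age_c + 70)
  fit <- fit_3mse_linear(dat, include_grs = FALSE, covariates = "age")
  got <- predicted_mean_difference(fit, dat)
  want <- mean((exp(1.4 + 0.03 * age_c) * (exp(0.15) - 1)))
  expect_equal(got, want, tolerance = 1e-6)
})
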
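#' Log working-scale transform of 3MSE scores
#'
#' The 3MSE distribution is highly left-skewed (ceiling at 100), so models
#' are fitted on `log(102 - 3MSE)`, a monotone decreasing transform defined
#' on the whole 0-100 range (values in `[log 2, log 102]`).
#'
#' @param score 3MSE scores in `[0, 100]`.
#' @return `log(102 - score)`.
#' @examples
#' transform_3mse(100)  # log(2)
#' @export
transform_3mse <- function(score) {
  if (any(!is.finite(score) | score < 0 | score > 100))
    stopf("3MSE scores must lie in [0, 100]")
  log(102 - score)
}

#' @rdname transform_3mse
#' @param value Transformed values in `[log 2, log 102]`.
#' @export
inverse_transform_3mse <- function(value) 102 - exp(value)

model_fit <- function(fit, outcome_scale, exponentiate = FALSE) {
  sm <- stats::coef(summary(fit))
  est <- sm[, 1]
  se <- sm[, 2]
  p <- sm[, 4]
  tab <- data.frame(
    term = rownames(sm), estimate = est, se = se,
    ci_lo = est - z975 * se, ci_hi = est + z975 * se, p = p,
    stringsAsFactors = FALSE, row.names = NULL
  )
  if (exponentiate) {
    tab$or <- exp(tab$estimate)
    tab$or_lo <- exp(tab$ci_lo)
    tab$or_hi <- exp(tab$ci_hi)
  }
  structure(list(
    coefficients = tab, n = stats::nobs(fit), outcome_scale = outcome_scale,
    covariates = attr(stats::terms(fit), "term.labels"), fit = fit
  ), class = "model_fit")
}

#' @export
print.model_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Model fit (n = %d, outcome scale: %s)\n", x$n, x$outcome_scale))
  tab <- x$coefficients
  num <- vapply(tab, is.numeric, TRUE)
  tab[num] <- lapply(tab[num], round, digits = digits)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Logistic model of large CDR on the genetic risk score
#'
#' Cross-sectional logistic regression of large-CDR status on the weighted
#' GRS, adjusted for age and the first two ancestry principal components.
#' Reports the odds ratio per one-unit GRS with a Wald 95% CI.
#'
#' @param grs Per-sample GRS.
#' @param cdr_status 0/1 outcome with both classes present.
#' @param age,pc1,pc2 Adjustment covariates; `NULL` omits the term.
#' @return A `model_fit`; the `grs` row's `or` column is the odds of large
#'   CDR per unit GRS.
#' @export
fit_grs_cdr_logistic <- function(grs, cdr_status, age = NULL, pc1 = NULL,
                                 pc2 = NULL) {
  y <- as.integer(cdr_status)
  if (length(unique(y)) < 2L)
    stopf("cdr_status must contain both classes")
  dat <- data.frame(y = y, grs = grs)
  for (v in c("age", "pc1", "pc2")) if (!is.null(get(v))) dat[[v]] <- get(v)
  fit <- withCallingHandlers(
    stats::glm(stats::reformulate(setdiff(names(dat), "y"), response = "y"),
               family = stats::binomial(), data = dat),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        stopf("separation detected in the GRS logistic model")
      invokeRestart("muffleWarning")
    }
  )
  if (!fit$converged) stopf("GRS logistic model did not converge")
  b <- stats::coef(summary(fit))
  if (abs(b["grs", 1]) > 15)
    stopf("separation detected in the GRS logistic model (|log OR| > 15)")
  model_fit(fit, "log-odds of large CDR", exponentiate = TRUE)
}

default_adjustment <- c("age", "education", "smoking", "diabetes",
                        "bmi_class", "cvd", "retinopathy", "ht_arm")

#' Linear model of transformed 3MSE scores
#'
#' Ordinary least squares of `log(102 - 3MSE)` on the GRS and/or large-CDR
#' status, adjusted for age, education, smoking, diabetes, BMI class,
#' cardiovascular disease, diabetic retinopathy, and hormone-therapy arm.
#' Categorical covariates are reference-coded on their first level. Because
#' the outcome is the log of a deficit (102 minus the score), positive
#' coefficients correspond to lower 3MSE.
#'
#' @param data `data.frame` with `mse3` (or a precomputed `log_deficit`
#'   column), `large_cdr`, optional `grs`, and the adjustment covariates.
#' @param include_grs Include the GRS term.
#' @param include_cdr Include the large-CDR term.
#' @param include_interaction Include the GRS-by-CDR interaction (forces both
#'   main effects in).
#' @param covariates Adjustment covariates (character); defaults to the full
#'   published set, intersected with the columns present.
#' @return A `model_fit` on the log working scale.
#' @export
fit_3mse_linear <- function(data, include_grs = TRUE, include_cdr = TRUE,
                            include_interaction = FALSE,
                            covariates = default_adjustment) {
  if (!"log_deficit" %in% names(data)) {
    if (!"mse3" %in% names(data))
      stopf("data needs an `mse3` (or `log_deficit`) column")
    data$log_deficit <- transform_3mse(data$mse3)
  }
  covariates <- intersect(covariates, names(data))
  rhs <- character()
  if (include_interaction) {
    include_grs <- TRUE
    include_cdr <- TRUE
  }
  if (include_grs) rhs <- c(rhs, "grs")
  if (include_cdr) rhs <- c(rhs, "large_cdr")
  if (include_interaction) rhs <- c(rhs, "grs:large_cdr")
  rhs <- c(rhs, covariates)
  if (!length(rhs)) stopf("model has no terms")
  used <- unique(c("log_deficit", intersect(all.vars(
    stats::reformulate(rhs)), names(data))))
  if (anyNA(data[used]))
    stopf("missing values among analysed rows; complete the covariate table first")
  form <- stats::reformulate(rhs, response = "log_deficit")
  fit <- stats::lm(form, data = data)
  alias <- stats::alias(fit)$Complete
  if (!is.null(alias))
    stopf("rank-deficient design; collinear term(s): %s",
          paste(rownames(alias), collapse = ", "))
  model_fit(fit, "log(102 - 3MSE)")
}

#' Adjusted mean 3MSE difference by G-computation
#'
#' For every sample, predicts the transformed outcome under both settings of
#' a binary contrast term, back-transforms each prediction to the 3MSE scale
#' via `102 - exp(.)`, averages the two counterfactual means, and returns
#' (mean without) minus (mean with): the 3MSE-point deficit attributable to
#' the contrast. An optional Duan smearing correction multiplies the
#' back-transformed deficits by the mean exponentiated residual.
#'
#' @param fit A `model_fit` from [fit_3mse_linear()].
#' @param data The cohort rows to average over (defaults to the fitted data).
#' @param contrast_term Name of the binary model term (default
#'   `"large_cdr"`).
#' @param smearing Apply Duan's nonparametric retransformation factor.
#' @return The predicted mean 3MSE difference (positive = lower scores with
#'   the contrast).
#' @export
predicted_mean_difference <- function(fit, data = NULL,
                                      contrast_term = "large_cdr",
                                      smearing = FALSE) {
  stopifnot(inherits(fit, "model_fit"))
  lmfit <- fit$fit
  if (!contrast_term %in% all.vars(stats::formula(lmfit)))
    stopf("contrast term `%s` is not in the fitted model", contrast_term)
  if (is.null(data)) data <- stats::model.frame(lmfit)
  d1 <- d0 <- as.data.frame(data)
  d1[[contrast_term]] <- 1
  d0[[contrast_term]] <- 0
  p1 <- stats::predict(lmfit, newdata = d1)
  p0 <- stats::predict(lmfit, newdata = d0)
  smear <- if (smearing) mean(exp(stats::residuals(lmfit))) else 1
  m1 <- mean(102 - exp(p1) * smear)
  m0 <- mean(102 - exp(p0) * smear)
  m0 - m1
}
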
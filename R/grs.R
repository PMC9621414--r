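#' Estimate per-SNP logistic weights
#'
#' Fits one logistic regression per SNP — large-CDR status on the allele
#' dosage under an additive model, adjusted for age and the first two
#' ancestry principal components. The dosage coefficient is the log odds
#' ratio used as the SNP's weight; its sign implies the local risk allele
#' (the counted allele when positive, the other allele when negative).
#' SNPs with a degenerate dosage column or a non-converged/separated fit are
#' flagged inestimable with a reason, not silently zeroed.
#'
#' @param dosages Dosage matrix ([new_dosage_matrix()]); the counted allele
#'   is taken from its metadata.
#' @param cdr_status 0/1 large-CDR outcome (both classes must be present).
#' @param age,pc1,pc2 Adjustment covariates, one value per sample; `NULL`
#'   omits the term (unadjusted fit).
#' @return `data.frame` with one row per SNP: `snp`, `counted_allele`,
#'   `other_allele`, `log_or`, `se`, `p`, `implied_risk_allele`, `estimable`,
#'   `note`.
#' @export
estimate_snp_weights <- function(dosages, cdr_status, age = NULL, pc1 = NULL,
                                 pc2 = NULL) {
  mat <- unclass(dosages)
  info <- snp_info(dosages)
  if (is.null(info))
    info <- data.frame(snp = colnames(mat),
                       counted_allele = NA_character_,
                       other_allele = NA_character_, stringsAsFactors = FALSE)
  y <- as.integer(cdr_status)
  if (length(unique(y[!is.na(y)])) < 2L)
    stopf("cdr_status must contain at least one case and one control")
  covs <- do.call(cbind, Filter(Negate(is.null),
                                list(age = age, pc1 = pc1, pc2 = pc2)))
  if (!is.null(covs) && anyNA(covs))
    stopf("missing covariate values among analysed samples")
  out <- info
  out$log_or <- NA_real_
  out$se <- NA_real_
  out$p <- NA_real_
  out$implied_risk_allele <- NA_character_
  out$estimable <- FALSE
  out$note <- ""
  pal <- paste(info$counted_allele, info$other_allele) %in%
    c("A T", "T A", "C G", "G C")
  if (any(pal, na.rm = TRUE))
    warnf("strand-ambiguous (A/T or C/G) SNP(s): %s — alleles are compared literally",
          paste(info$snp[which(pal)], collapse = ", "))
  for (j in seq_len(ncol(mat))) {
    g <- mat[, j]
    if (stats::var(g) == 0) {
      out$note[j] <- "constant dosage column"
      next
    }
    fit <- withCallingHandlers(
      if (is.null(covs)) stats::glm(y ~ g, family = stats::binomial()) else
        stats::glm(y ~ g + covs, family = stats::binomial()),
      warning = function(w) invokeRestart("muffleWarning")
    )
    b <- stats::coef(summary(fit))
    if (!fit$converged || !"g" %in% rownames(b) || abs(b["g", 1]) > 10 ||
        b["g", 2] > 100) {
      out$note[j] <- if (!fit$converged) "did not converge" else
        "quasi-separation (unstable estimate)"
      next
    }
    out$log_or[j] <- b["g", 1]
    out$se[j] <- b["g", 2]
    out$p[j] <- b["g", 4]
    out$implied_risk_allele[j] <- if (b["g", 1] > 0) info$counted_allele[j] else
      info$other_allele[j]
    out$estimable[j] <- TRUE
  }
  rownames(out) <- NULL
  out
}

#' Compute the weighted genetic risk score
#'
#' Per-sample score `sum(weight_i * dosage_i)` over the weight table's SNPs.
#' Dosage columns coded on the opposite allele are re-oriented (`G -> 2 - G`)
#' using the dosage matrix's allele metadata. SNP order is irrelevant.
#'
#' @param dosages Dosage matrix covering every weight-table SNP.
#' @param weight_table `data.frame` with `snp`, `effect_allele`, `weight`
#'   (see [cdr_grs_weights()]).
#' @param missing Policy for missing dosage values: `"fail"` (default) or
#'   `"mean"` (per-SNP mean imputation, logged via a message).
#' @return Numeric vector of scores, named by sample.
#' @examples
#' w <- cdr_grs_weights()
#' g <- simulate_genotypes(cdr_candidate_panel(), 0.5, 5, seed = 1)
#' compute_grs(g, w)
#' @export
compute_grs <- function(dosages, weight_table, missing = c("fail", "mean")) {
  missing <- match.arg(missing)
  weight_table <- validate_weight_table(weight_table)
  mat <- unclass(dosages)
  info <- snp_info(dosages)
  absent <- setdiff(weight_table$snp, colnames(mat))
  if (length(absent))
    stopf("dosage matrix lacks weight-table SNP(s): %s",
          paste(absent, collapse = ", "))
  mat <- mat[, weight_table$snp, drop = FALSE]
  if (anyNA(mat)) {
    if (missing == "fail")
      stopf("missing dosages for %d value(s); set missing = \"mean\" to impute",
            sum(is.na(mat)))
    for (j in seq_len(ncol(mat))) {
      nas <- is.na(mat[, j])
      if (any(nas)) {
        mat[nas, j] <- mean(mat[, j], na.rm = TRUE)
        message(sprintf("mean-imputed %d missing dosage(s) at %s", sum(nas),
                        colnames(mat)[j]))
      }
    }
  }
  if (!is.null(info)) {
    idx <- match(weight_table$snp, info$snp)
    counted <- info$counted_allele[idx]
    other <- info$other_allele[idx]
    flip <- !is.na(counted) & counted != weight_table$effect_allele
    mismatch <- flip & (is.na(other) | other != weight_table$effect_allele)
    if (any(mismatch))
      stopf("effect allele does not match either coded allele at: %s",
            paste(weight_table$snp[mismatch], collapse = ", "))
    if (any(flip)) mat[, flip] <- 2 - mat[, flip]
  }
  drop(mat %*% weight_table$weight)
}
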
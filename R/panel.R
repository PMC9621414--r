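#' Candidate SNP panel for vertical cup-to-disc ratio
#'
#' The 18 candidate SNPs associated with vertical cup-to-disc ratio (CDR) in
#' discovery meta-analyses of European-ancestry cohorts, as used to build the
#' CDR genetic risk score. Each record carries the discovery (meta-analysis)
#' risk allele, the locally estimated risk allele in the analysis cohort, and
#' the imputation quality R-squared. Only the low-quality SNP's R-squared
#' (0.56 at 11:65337251) is individually published; the remaining 17 are
#' recorded at 0.90, the published lower bound for their quality.
#'
#' @param path Optional path to a panel TSV; defaults to the panel shipped
#'   with the package.
#' @return A `data.frame` with columns `rsid`, `chr_pos` (1-based
#'   chromosome:position), `gene`, `discovery_risk_allele`,
#'   `local_risk_allele`, `imputation_r2`, `discovery_effect_size`.
#' @examples
#' panel <- cdr_candidate_panel()
#' nrow(panel)  # 18
#' @export
cdr_candidate_panel <- function(path = NULL) {
  path <- path %||% system.file("extdata", "candidate_panel.tsv",
                                package = "cdrgrs", mustWork = TRUE)
  panel <- utils::read.delim(path, stringsAsFactors = FALSE,
                             colClasses = c(discovery_effect_size = "numeric"))
  validate_panel(panel)
}

#' Published genetic risk score weights
#'
#' The 13 SNPs retained after imputation-quality and risk-allele concordance
#' filtering, with their per-allele log odds-ratio weights estimated by
#' single-SNP logistic regression of large-CDR status (adjusted for age and
#' two ancestry principal components).
#'
#' @param path Optional path to a weight TSV; defaults to the table shipped
#'   with the package.
#' @return A `data.frame` with columns `snp` (chromosome:position), `gene`,
#'   `effect_allele`, `weight` (log odds ratio per effect allele).
#' @examples
#' w <- cdr_grs_weights()
#' sum(w$weight)
#' @export
cdr_grs_weights <- function(path = NULL) {
  path <- path %||% system.file("extdata", "grs_weights.tsv",
                                package = "cdrgrs", mustWork = TRUE)
  w <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_weight_table(w)
}

#' Published sample-selection counts
#'
#' Stage counts from the analysis cohort's selection flow: genetic samples
#' available, participants, self-identified White participants, participants
#' after duplicate/relative resolution, and the final merged analysis cohort,
#' together with the large-CDR case count. Useful for reproducing the
#' published selection percentages.
#'
#' @return A named list of integer counts.
#' @export
whi_selection_counts <- function() {
  list(
    genetic_samples   = 3111L,
    participants      = 2708L,
    white             = 2339L,
    after_dedup       = 2336L,
    final_analysis    = 1196L,
    large_cdr_cases   = 87L
  )
}

validate_panel <- function(panel) {
  need <- c("rsid", "chr_pos", "gene", "discovery_risk_allele",
            "local_risk_allele", "imputation_r2")
  miss <- setdiff(need, names(panel))
  if (length(miss))
    stopf("panel is missing required column(s): %s", paste(miss, collapse = ", "))
  if (anyDuplicated(panel$rsid))
    stopf("panel rsid values must be unique")
  if (anyDuplicated(panel$chr_pos))
    stopf("panel chr_pos values must be unique")
  ok_allele <- function(a) a %in% c("A", "C", "G", "T") | is.na(a)
  if (!all(ok_allele(panel$discovery_risk_allele)) ||
      !all(ok_allele(panel$local_risk_allele)))
    stopf("panel alleles must be one of A, C, G, T")
  if (any(!is.finite(panel$imputation_r2)) ||
      any(panel$imputation_r2 <= 0 | panel$imputation_r2 > 1))
    stopf("imputation_r2 must lie in (0, 1]")
  if (!"discovery_effect_size" %in% names(panel))
    panel$discovery_effect_size <- NA_real_
  panel
}

validate_weight_table <- function(w) {
  need <- c("snp", "effect_allele", "weight")
  miss <- setdiff(need, names(w))
  if (length(miss))
    stopf("weight table is missing required column(s): %s",
          paste(miss, collapse = ", "))
  if (anyDuplicated(w$snp)) stopf("weight table snp values must be unique")
  if (any(!is.finite(w$weight))) stopf("weights must be finite")
  w
}

#' Filter a candidate panel on imputation quality
#'
#' Removes SNPs whose imputation R-squared (the estimated squared correlation
#' between imputed and true genotypes) falls below a threshold. The removals
#' are recorded, with their R-squared values, in the `"removed"` attribute of
#' the result.
#'
#' @param panel A candidate panel (`data.frame`, see [cdr_candidate_panel()]).
#' @param r2_threshold Minimum acceptable R-squared, strictly inside (0, 1).
#'   Default 0.8, which separates the published low-quality value (0.56) from
#'   the published lower bound for the rest of the panel (0.89).
#' @return The filtered panel; attribute `"removed"` holds a `data.frame` of
#'   dropped SNPs and their R-squared values.
#' @examples
#' nrow(filter_imputation_quality(cdr_candidate_panel()))  # 17
#' @export
filter_imputation_quality <- function(panel, r2_threshold = 0.8) {
  panel <- validate_panel(panel)
  if (!is.numeric(r2_threshold) || length(r2_threshold) != 1 ||
      !is.finite(r2_threshold) || r2_threshold <= 0 || r2_threshold >= 1)
    stopf("r2_threshold must be a single value in (0, 1)")
  drop <- panel$imputation_r2 < r2_threshold
  if (all(drop))
    stopf("no SNP survives the imputation-quality filter at R^2 >= %g",
          r2_threshold)
  kept <- panel[!drop, , drop = FALSE]
  rownames(kept) <- NULL
  attr(kept, "removed") <- data.frame(
    rsid = panel$rsid[drop], chr_pos = panel$chr_pos[drop],
    imputation_r2 = panel$imputation_r2[drop], stringsAsFactors = FALSE
  )
  kept
}

#' Risk-allele concordance filter
#'
#' Retains a SNP if and only if the locally implied risk allele agrees with
#' the discovery risk allele. With `estimated_weights` from
#' [estimate_snp_weights()], the implied allele is read off the sign of the
#' fitted log odds ratio (the counted allele if positive, the other allele
#' otherwise). Without weights, the panel's own `local_risk_allele` column is
#' compared against `discovery_risk_allele` (the published-table route).
#'
#' @param panel A candidate panel.
#' @param estimated_weights Optional per-SNP estimate table from
#'   [estimate_snp_weights()]; rows flagged inestimable are dropped and
#'   logged.
#' @return The retained panel rows; attribute `"discordant"` lists dropped
#'   SNPs with both alleles, attribute `"weights"` (when estimates were
#'   supplied) holds the corresponding weight table (effect allele = the
#'   concordant risk allele, weight = |log OR|).
#' @examples
#' p17 <- filter_imputation_quality(cdr_candidate_panel())
#' nrow(check_concordance(p17))  # 13
#' @export
check_concordance <- function(panel, estimated_weights = NULL) {
  panel <- validate_panel(panel)
  if (is.null(estimated_weights)) {
    implied <- panel$local_risk_allele
    keep_idx <- seq_len(nrow(panel))
  } else {
    need <- c("snp", "counted_allele", "other_allele", "log_or", "estimable")
    miss <- setdiff(need, names(estimated_weights))
    if (length(miss))
      stopf("estimated_weights is missing column(s): %s",
            paste(miss, collapse = ", "))
    unknown <- setdiff(estimated_weights$snp, panel$chr_pos)
    if (length(unknown))
      stopf("estimated weights refer to SNP(s) absent from the panel: %s",
            paste(unknown, collapse = ", "))
    ew <- estimated_weights[estimated_weights$estimable, , drop = FALSE]
    keep_idx <- match(ew$snp, panel$chr_pos)
    implied <- rep(NA_character_, nrow(panel))
    implied[keep_idx] <- ifelse(ew$log_or > 0, ew$counted_allele,
                                ew$other_allele)
    panel <- panel[keep_idx, , drop = FALSE]
    implied <- implied[keep_idx]
  }
  concordant <- !is.na(implied) & implied == panel$discovery_risk_allele
  kept <- panel[concordant, , drop = FALSE]
  rownames(kept) <- NULL
  attr(kept, "discordant") <- data.frame(
    rsid = panel$rsid[!concordant], chr_pos = panel$chr_pos[!concordant],
    gene = panel$gene[!concordant],
    discovery_risk_allele = panel$discovery_risk_allele[!concordant],
    implied_risk_allele = implied[!concordant], stringsAsFactors = FALSE
  )
  if (!is.null(estimated_weights)) {
    ew <- estimated_weights[estimated_weights$estimable, , drop = FALSE]
    ew <- ew[match(kept$chr_pos, ew$snp), , drop = FALSE]
    attr(kept, "weights") <- data.frame(
      snp = kept$chr_pos, gene = kept$gene,
      effect_allele = ifelse(ew$log_or > 0, ew$counted_allele, ew$other_allele),
      weight = abs(ew$log_or), stringsAsFactors = FALSE
    )
  }
  kept
}
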
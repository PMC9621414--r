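#' Run the full analysis pipeline
#'
#' Executes the stages in the published order — sample QC, imputation-quality
#' filtering, per-SNP weight estimation, risk-allele concordance filtering,
#' GRS scoring, descriptive table, and association models — and writes every
#' declared output (QC report JSON, weight TSV, score CSV, descriptive TSV,
#' coefficient TSVs, results JSON) together with an echoed copy of the
#' configuration for provenance.
#'
#' @param config A [pipeline_config()].
#' @param cohort Optional in-memory `simulated_cohort`; when supplied, the
#'   file inputs in `config` are ignored (the synthetic route).
#' @return (Invisibly) a list with `qc`, `panel`, `weights`, `grs`,
#'   `descriptive`, `fit_logistic`, `fit_linear`, `fit_interaction`,
#'   `mean_difference`, and `outputs` (paths written).
#' @export
run_pipeline <- function(config = pipeline_config(), cohort = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- "input"
  result <- tryCatch({
    if (is.null(cohort)) {
      panel <- if (is.null(config$panel_path)) cdr_candidate_panel() else
        cdr_candidate_panel(config$panel_path)
      dosages <- read_genotypes(config$genotypes_path, panel = panel)
      phenotypes <- read_phenotypes(config$phenotypes_path)
      samples <- if (!is.null(config$samples_path))
        utils::read.csv(config$samples_path, stringsAsFactors = FALSE)
      else NULL
      pairs <- if (!is.null(config$pairs_path))
        utils::read.csv(config$pairs_path, stringsAsFactors = FALSE)
      else NULL
    } else {
      panel <- cohort$config$panel
      dosages <- cohort$dosages
      phenotypes <- cohort$phenotypes
      samples <- cohort$samples
      pairs <- cohort$relative_pairs
    }

    stage <- "qc"
    if (!is.null(samples)) {
      qc <- run_qc(samples, phenotypes = phenotypes, relative_pairs = pairs)
      keep <- qc$retained$sample_id
    } else {
      qc <- NULL
      keep <- phenotypes$sample_id[!is.na(phenotypes$large_cdr) &
                                     !is.na(phenotypes$pc1) &
                                     !is.na(phenotypes$pc2)]
    }
    phenotypes <- phenotypes[match(keep, phenotypes$sample_id), , drop = FALSE]
    dosages <- new_dosage_matrix(
      unclass(dosages)[keep, , drop = FALSE], snp_info(dosages))

    stage <- "imputation_quality_filter"
    panel_hq <- filter_imputation_quality(panel, config$r2_threshold)

    stage <- "weight_estimation"
    dos_hq <- new_dosage_matrix(
      unclass(dosages)[, panel_hq$chr_pos, drop = FALSE],
      snp_info(dosages)[match(panel_hq$chr_pos, snp_info(dosages)$snp), ])
    est <- estimate_snp_weights(dos_hq, phenotypes$large_cdr,
                                phenotypes$age, phenotypes$pc1,
                                phenotypes$pc2)

    stage <- "concordance_filter"
    kept <- check_concordance(panel_hq, est)
    weights <- if (config$weight_source == "internal") {
      attr(kept, "weights")
    } else {
      if (anyNA(kept$discovery_effect_size))
        stopf("external weight mode needs discovery_effect_size for every retained SNP")
      data.frame(snp = kept$chr_pos, gene = kept$gene,
                 effect_allele = kept$discovery_risk_allele,
                 weight = kept$discovery_effect_size, stringsAsFactors = FALSE)
    }

    stage <- "scoring"
    grs <- compute_grs(dosages, weights, missing = config$missing_dosage)

    stage <- "descriptive_table"
    desc <- build_descriptive_table(phenotypes, grs = grs,
                                    normality_rule = config$normality_rule,
                                    cell_rule = config$cell_rule)

    stage <- "association_models"
    fit_log <- fit_grs_cdr_logistic(grs, phenotypes$large_cdr,
                                    phenotypes$age, phenotypes$pc1,
                                    phenotypes$pc2)
    dat <- phenotypes
    dat$grs <- grs
    fit_lin <- fit_3mse_linear(dat)
    fit_int <- fit_3mse_linear(dat, include_interaction = TRUE)
    mdiff <- predicted_mean_difference(fit_lin, dat)

    list(qc = qc, panel = kept, weights = weights, grs = grs,
         descriptive = desc, fit_logistic = fit_log, fit_linear = fit_lin,
         fit_interaction = fit_int, mean_difference = mdiff)
  }, error = function(e) {
    stopf("pipeline failed at stage `%s`: %s", stage, conditionMessage(e))
  })

  result$outputs <- write_pipeline_outputs(result, config)
  invisible(result)
}

write_coef_tsv <- function(fit, path) {
  tab <- fit$coefficients
  tab$ci95 <- sprintf("(%.4f, %.4f)", tab$ci_lo, tab$ci_hi)
  cols <- c("term", "estimate", "ci95", "p",
            intersect("or", names(tab)))
  utils::write.table(tab[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}

write_pipeline_outputs <- function(result, config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(config$out_dir, f)
  outputs <- character()

  if (!is.null(result$qc)) {
    jsonlite::write_json(unclass(result$qc$report), p("qc_report.json"),
                         auto_unbox = TRUE, dataframe = "rows", digits = NA)
    outputs <- c(outputs, p("qc_report.json"))
  }
  utils::write.table(result$weights, p("grs_weights.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.csv(data.frame(sample_id = names(result$grs),
                              grs = as.numeric(result$grs)),
                   p("grs_scores.csv"), row.names = FALSE, quote = FALSE)
  utils::write.table(as.data.frame(result$descriptive),
                     p("descriptive_table.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  outputs <- c(outputs, p("grs_weights.tsv"), p("grs_scores.csv"),
               p("descriptive_table.tsv"))
  for (nm in c("fit_logistic", "fit_linear", "fit_interaction")) {
    f <- p(paste0(nm, ".tsv"))
    write_coef_tsv(result[[nm]], f)
    outputs <- c(outputs, f)
  }
  jsonlite::write_json(list(
    seed = config$seed,
    n = result$fit_linear$n,
    or_per_unit_grs = result$fit_logistic$coefficients$or[
      result$fit_logistic$coefficients$term == "grs"],
    predicted_mean_difference_3mse = result$mean_difference
  ), p("results.json"), auto_unbox = TRUE, digits = NA)
  write_pipeline_config(config, p("config_echo.yaml"))
  outputs <- c(outputs, p("results.json"), p("config_echo.yaml"))
  outputs
}
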
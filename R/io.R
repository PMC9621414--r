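#' Read a dosage matrix
#'
#' Accepts either a CSV dosage matrix (first column `sample_id`, one column
#' per SNP; optional `#counted_allele=`/`#other_allele=` header comments) or
#' a VCF. From a VCF, per-sample dosages come from the `DS` FORMAT field when
#' present, otherwise from hard `GT` calls as the alternate-allele count; the
#' counted allele is the ALT allele. Multi-allelic records at panel positions
#' are rejected.
#'
#' @param path Input file.
#' @param format `"auto"` (by extension), `"csv"`, or `"vcf"`.
#' @param panel Optional candidate panel; if given, every panel SNP must be
#'   present, and missing positions are reported.
#' @return A [new_dosage_matrix()].
#' @export
read_genotypes <- function(path, format = c("auto", "csv", "vcf"),
                           panel = NULL) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) "vcf"
      else "csv"
  dos <- if (format == "vcf") read_vcf_dosages(path) else
    read_dosage_csv(path)
  if (!is.null(panel)) {
    panel <- validate_panel(panel)
    absent <- setdiff(panel$chr_pos, colnames(dos))
    if (length(absent))
      stopf("genotype file lacks panel position(s): %s",
            paste(absent, collapse = ", "))
  }
  dos
}

read_dosage_csv <- function(path) {
  hdr <- readLines(path, n = 10L)
  meta <- hdr[startsWith(hdr, "#")]
  get_meta <- function(key) {
    ln <- meta[startsWith(meta, paste0("#", key, "="))]
    if (!length(ln)) return(NULL)
    strsplit(sub(paste0("#", key, "="), "", ln[1]), ",", fixed = TRUE)[[1]]
  }
  df <- utils::read.csv(path, comment.char = "#", check.names = FALSE,
                        stringsAsFactors = FALSE)
  if (names(df)[1] != "sample_id")
    stopf("dosage CSV must start with a sample_id column")
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df$sample_id
  counted <- get_meta("counted_allele") %||% rep(NA_character_, ncol(mat))
  other <- get_meta("other_allele") %||% rep(NA_character_, ncol(mat))
  new_dosage_matrix(mat, data.frame(snp = colnames(mat),
                                    counted_allele = counted,
                                    other_allele = other,
                                    stringsAsFactors = FALSE))
}

#' Write a dosage matrix as CSV
#'
#' Writes the sample-by-SNP matrix with allele coding recorded in
#' `#counted_allele=` / `#other_allele=` comment lines, so a write-read
#' round trip reproduces the object.
#'
#' @param dosages A dosage matrix.
#' @param path Output file.
#' @export
write_dosage_csv <- function(dosages, path) {
  info <- snp_info(dosages)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("#counted_allele=", paste(info$counted_allele, collapse = ",")),
    paste0("#other_allele=", paste(info$other_allele, collapse = ","))
  ), con)
  df <- data.frame(sample_id = rownames(dosages),
                   unclass(dosages), check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

read_vcf_dosages <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stopf("reading VCF requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fx <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  multi <- grepl(",", fx$ALT, fixed = TRUE)
  if (any(multi))
    stopf("multi-allelic record(s) at %s; split or exclude them first",
          paste(fx$CHROM[multi], fx$POS[multi], sep = ":", collapse = ", "))
  keys <- paste(fx$CHROM, fx$POS, sep = ":")
  fmt <- tryCatch(vcfR::extract.gt(v, element = "DS", as.numeric = TRUE),
                  error = function(e) NULL)
  if (is.null(fmt) || all(is.na(fmt))) {
    gt <- vcfR::extract.gt(v, element = "GT")
    fmt <- apply(gt, c(1, 2), function(g) {
      if (is.na(g)) return(NA_real_)
      sum(as.integer(strsplit(g, "[/|]")[[1]]))
    })
  }
  mat <- t(fmt)
  colnames(mat) <- keys
  new_dosage_matrix(mat, data.frame(snp = keys, counted_allele = fx$ALT,
                                    other_allele = fx$REF,
                                    stringsAsFactors = FALSE))
}

#' Write a dosage matrix as VCF
#'
#' Emits one biallelic record per SNP with `GT` (rounded hard call) and `DS`
#' (dosage) per sample. REF is the non-counted allele, ALT the counted
#' (effect) allele, so ALT dosage equals the stored dosage.
#'
#' @param dosages A dosage matrix with allele metadata.
#' @param path Output file (plain-text `.vcf`).
#' @export
write_vcf <- function(dosages, path) {
  info <- snp_info(dosages)
  if (anyNA(info$counted_allele) || anyNA(info$other_allele))
    stopf("VCF output requires complete allele metadata")
  chr_pos <- strsplit(info$snp, ":", fixed = TRUE)
  gt_of <- function(d) c("0/0", "0/1", "1/1")[pmin(2, pmax(0, round(d))) + 1L]
  lines <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Estimated alternate allele dosage\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(dosages)), collapse = "\t")
  )
  body <- vapply(seq_len(ncol(dosages)), function(j) {
    d <- unclass(dosages)[, j]
    paste(c(chr_pos[[j]][1], chr_pos[[j]][2], info$snp[j],
            info$other_allele[j], info$counted_allele[j], ".", "PASS", ".",
            "GT:DS", paste0(gt_of(d), ":", format(d, trim = TRUE))),
          collapse = "\t")
  }, character(1))
  writeLines(c(lines, body), path)
  invisible(path)
}

#' Read / write phenotype tables
#'
#' Phenotype CSVs carry one row per sample with the documented header:
#' `sample_id`, `participant_id`, `large_cdr`, `mse3`, `age`, `education`,
#' `smoking`, `bmi_class`, `diabetes`, `cvd`, `retinopathy`, `ht_arm`,
#' `pc1`, `pc2` (missing values empty).
#'
#' @param path CSV file.
#' @return `data.frame` with factor covariates releveled to the standard
#'   baseline order.
#' @export
read_phenotypes <- function(path) {
  ph <- utils::read.csv(path, stringsAsFactors = FALSE)
  m <- covariate_margins()
  for (v in c("education", "smoking", "bmi_class", "ht_arm"))
    if (v %in% names(ph)) ph[[v]] <- factor(ph[[v]], levels = names(m[[v]]))
  if (!"age_c" %in% names(ph) && "age" %in% names(ph)) ph$age_c <- ph$age - 70
  ph
}

#' @rdname read_phenotypes
#' @param phenotypes Phenotype `data.frame`.
#' @export
write_phenotypes <- function(phenotypes, path) {
  utils::write.csv(phenotypes, path, row.names = FALSE, quote = FALSE,
                   na = "")
  invisible(path)
}

#' Pipeline configuration
#'
#' @param panel_path,genotypes_path,phenotypes_path,samples_path,pairs_path
#'   Input files (`NULL` entries fall back to packaged defaults or are
#'   skipped).
#' @param out_dir Output directory.
#' @param r2_threshold Imputation-quality threshold.
#' @param weight_source `"internal"` (fit weights in-cohort) or `"external"`
#'   (use the panel's `discovery_effect_size`).
#' @param missing_dosage `"fail"` or `"mean"`.
#' @param normality_rule,cell_rule Descriptive-table test-selection rules.
#' @param seed Integer seed recorded with every output.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(panel_path = NULL, genotypes_path = NULL,
                            phenotypes_path = NULL, samples_path = NULL,
                            pairs_path = NULL, out_dir = "cdrgrs_out",
                            r2_threshold = 0.8,
                            weight_source = c("internal", "external"),
                            missing_dosage = c("fail", "mean"),
                            normality_rule = "shapiro",
                            cell_rule = "observed", seed = 1L) {
  structure(list(
    panel_path = panel_path, genotypes_path = genotypes_path,
    phenotypes_path = phenotypes_path, samples_path = samples_path,
    pairs_path = pairs_path, out_dir = out_dir,
    r2_threshold = r2_threshold,
    weight_source = match.arg(weight_source),
    missing_dosage = match.arg(missing_dosage),
    normality_rule = normality_rule, cell_rule = cell_rule,
    seed = as.integer(seed)
  ), class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals)
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(lapply(unclass(config), function(x) x %||% ""), path)
  invisible(path)
}
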
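#' @title Sample-selection quality control
#' @name cohort_qc
#' @description
#' The selection flow applied before analysis: one genetic sample per
#' participant (keeping the sample from the GWAS platform with more SNPs),
#' removal of one member of each first-degree-relative pair (the member on
#' the smaller platform), and exclusion of samples missing PCA coordinates
#' or CDR status. Every removal is reason-coded in an auditable report.
NULL

validate_samples <- function(samples) {
  need <- c("sample_id", "participant_id", "platform_id", "platform_snp_count")
  miss <- setdiff(need, names(samples))
  if (length(miss))
    stopf("sample table is missing column(s): %s", paste(miss, collapse = ", "))
  if (anyDuplicated(samples$sample_id))
    stopf("sample_id values must be unique")
  if (any(!is.finite(samples$platform_snp_count) |
          samples$platform_snp_count <= 0))
    stopf("platform_snp_count must be a positive number on every record")
  samples
}

qc_fragment <- function(stage, n_in, removed) {
  list(stage = stage, n_in = n_in, n_removed = nrow(removed),
       n_out = n_in - nrow(removed), removed = removed)
}

empty_removals <- function() {
  data.frame(sample_id = character(), reason = character(),
             detail = character(), stringsAsFactors = FALSE)
}

#' Resolve duplicate genetic samples
#'
#' Keeps exactly one sample per participant: the one from the platform with
#' the larger SNP count; ties are broken deterministically in favour of the
#' lexicographically smallest `platform_id`, and logged as ties.
#'
#' @param samples Sample-record `data.frame` (columns `sample_id`,
#'   `participant_id`, `platform_id`, `platform_snp_count`, ...).
#' @return Retained samples; attribute `"qc"` holds the report fragment.
#' @export
resolve_duplicates <- function(samples) {
  samples <- validate_samples(samples)
  removed <- empty_removals()
  keep <- rep(TRUE, nrow(samples))
  for (pid in unique(samples$participant_id[duplicated(samples$participant_id)])) {
    idx <- which(samples$participant_id == pid)
    grp <- samples[idx, ]
    ord <- order(-grp$platform_snp_count, grp$platform_id, grp$sample_id)
    tie <- sum(grp$platform_snp_count == max(grp$platform_snp_count)) > 1L
    losers <- idx[ord[-1L]]
    keep[losers] <- FALSE
    removed <- rbind(removed, data.frame(
      sample_id = samples$sample_id[losers], reason = "duplicate_sample",
      detail = sprintf("participant %s kept %s (%s, %d SNPs)%s", pid,
                       grp$sample_id[ord[1L]], grp$platform_id[ord[1L]],
                       grp$platform_snp_count[ord[1L]],
                       if (tie) "; tie on SNP count broken by platform_id" else ""),
      stringsAsFactors = FALSE))
  }
  out <- samples[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, qc = qc_fragment("duplicate_resolution", nrow(samples),
                                  removed))
}

#' Remove first-degree relatives
#'
#' For each listed relative pair with both members still present, removes the
#' member with the smaller platform SNP count (ties broken by `platform_id`,
#' then `sample_id`). Pairs are processed in input order.
#'
#' @param samples Sample-record `data.frame`.
#' @param relative_pairs `data.frame` with columns `sample_a`, `sample_b`.
#' @return Retained samples; attribute `"qc"` holds the report fragment.
#' @export
remove_relatives <- function(samples, relative_pairs) {
  samples <- validate_samples(samples)
  removed <- empty_removals()
  if (is.null(relative_pairs) || nrow(relative_pairs) == 0L)
    return(structure(samples,
                     qc = qc_fragment("relative_removal", nrow(samples),
                                      removed)))
  unknown <- setdiff(c(relative_pairs$sample_a, relative_pairs$sample_b),
                     samples$sample_id)
  if (length(unknown))
    stopf("relative pair references unknown sample(s): %s",
          paste(unknown, collapse = ", "))
  keep <- stats::setNames(rep(TRUE, nrow(samples)), samples$sample_id)
  for (k in seq_len(nrow(relative_pairs))) {
    a <- relative_pairs$sample_a[k]
    b <- relative_pairs$sample_b[k]
    if (!keep[a] || !keep[b]) next
    grp <- samples[match(c(a, b), samples$sample_id), ]
    ord <- order(-grp$platform_snp_count, grp$platform_id, grp$sample_id)
    loser <- grp$sample_id[ord[2L]]
    keep[loser] <- FALSE
    removed <- rbind(removed, data.frame(
      sample_id = loser, reason = "first_degree_relative",
      detail = sprintf("pair (%s, %s); kept %s (larger platform)", a, b,
                       grp$sample_id[ord[1L]]),
      stringsAsFactors = FALSE))
  }
  out <- samples[keep[samples$sample_id], , drop = FALSE]
  rownames(out) <- NULL
  structure(out, qc = qc_fragment("relative_removal", nrow(samples), removed))
}

#' Exclude samples with missing PCA or CDR data
#'
#' @param samples Sample-record `data.frame` with logical `has_pca` and
#'   `has_cdr` columns (or a `phenotypes` table supplying them by
#'   `sample_id`).
#' @param phenotypes Optional phenotype table; if given, `has_pca` is derived
#'   from non-missing `pc1`/`pc2` and `has_cdr` from non-missing `large_cdr`.
#' @return Retained samples; attribute `"qc"` holds the report fragment with
#'   reasons `missing_pca` / `missing_cdr`.
#' @export
filter_missing <- function(samples, phenotypes = NULL) {
  samples <- validate_samples(samples)
  if (!is.null(phenotypes)) {
    idx <- match(samples$sample_id, phenotypes$sample_id)
    if (anyNA(idx))
      stopf("phenotype table lacks sample(s): %s",
            paste(samples$sample_id[is.na(idx)], collapse = ", "))
    samples$has_pca <- !(is.na(phenotypes$pc1[idx]) |
                           is.na(phenotypes$pc2[idx]))
    samples$has_cdr <- !is.na(phenotypes$large_cdr[idx])
  }
  if (!all(c("has_pca", "has_cdr") %in% names(samples)))
    stopf("samples need has_pca and has_cdr columns (or pass `phenotypes`)")
  drop_pca <- !samples$has_pca
  drop_cdr <- samples$has_pca & !samples$has_cdr
  removed <- rbind(
    data.frame(sample_id = samples$sample_id[drop_pca],
               reason = rep("missing_pca", sum(drop_pca)),
               detail = rep("no PCA coordinates", sum(drop_pca)),
               stringsAsFactors = FALSE),
    data.frame(sample_id = samples$sample_id[drop_cdr],
               reason = rep("missing_cdr", sum(drop_cdr)),
               detail = rep("no CDR status", sum(drop_cdr)),
               stringsAsFactors = FALSE)
  )
  out <- samples[!(drop_pca | drop_cdr), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, qc = qc_fragment("missingness_exclusion", nrow(samples),
                                  removed))
}

#' Run the full sample-selection chain
#'
#' Duplicate resolution, then relative removal, then missing-data exclusion,
#' returning the retained samples and a `qc_report` with counts at every
#' stage and one reason-coded row per removal.
#'
#' @param samples Sample-record `data.frame`.
#' @param phenotypes Optional phenotype table (see [filter_missing()]).
#' @param relative_pairs Optional `data.frame` of first-degree pairs.
#' @return A list of class `qc_result`: `retained` (sample records) and
#'   `report` (class `qc_report`).
#' @export
run_qc <- function(samples, phenotypes = NULL, relative_pairs = NULL) {
  s1 <- resolve_duplicates(samples)
  f1 <- attr(s1, "qc")
  # pairs may reference duplicate-resolved samples that are already gone
  if (!is.null(relative_pairs) && nrow(relative_pairs)) {
    ok <- relative_pairs$sample_a %in% s1$sample_id &
      relative_pairs$sample_b %in% s1$sample_id
    relative_pairs <- relative_pairs[ok, , drop = FALSE]
  }
  s2 <- remove_relatives(s1, relative_pairs)
  f2 <- attr(s2, "qc")
  s3 <- filter_missing(s2, phenotypes)
  f3 <- attr(s3, "qc")
  stages <- list(f1, f2, f3)
  report <- structure(list(
    counts = data.frame(
      stage = c("input", vapply(stages, `[[`, "", "stage")),
      n = c(nrow(samples), vapply(stages, `[[`, 0L, "n_out")),
      stringsAsFactors = FALSE
    ),
    removed = do.call(rbind, c(lapply(stages, function(f) {
      if (nrow(f$removed))
        cbind(stage = f$stage, f$removed, stringsAsFactors = FALSE)
      else NULL
    }), list(make.row.names = FALSE)))
  ), class = "qc_report")
  if (is.null(report$removed))
    report$removed <- cbind(stage = character(), empty_removals())
  attr(s3, "qc") <- NULL
  list(retained = s3, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("Sample-selection QC report\n")
  print(x$counts, row.names = FALSE)
  if (nrow(x$removed)) {
    cat("Removals by reason:\n")
    print(table(x$removed$reason))
  } else cat("No removals.\n")
  invisible(x)
}
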
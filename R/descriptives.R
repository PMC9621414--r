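#' Compare a continuous variable between two groups
#'
#' Applies the test-selection rule: Shapiro-Wilk normality at alpha = 0.05 in
#' each group (on an evenly spaced subsample of at most 5000 values when a
#' group is larger); if both groups look normal a Welch two-sample t-test is
#' used, otherwise a Wilcoxon rank-sum test (exact where R's implementation
#' permits, normal approximation with tie correction otherwise).
#'
#' @param values_a,values_b Numeric vectors (both non-empty).
#' @param normality_rule `"shapiro"` (default), or `"force_t"` /
#'   `"force_wilcoxon"` to bypass the rule.
#' @param alpha Normality-test level.
#' @return List with `test` (name), `p`, `statistic`, and `normality_p`
#'   (per-group Shapiro p-values, when assessed).
#' @export
compare_continuous <- function(values_a, values_b,
                               normality_rule = c("shapiro", "force_t",
                                                  "force_wilcoxon"),
                               alpha = 0.05) {
  normality_rule <- match.arg(normality_rule)
  values_a <- values_a[!is.na(values_a)]
  values_b <- values_b[!is.na(values_b)]
  if (!length(values_a) || !length(values_b))
    stopf("both groups must be non-empty")
  norm_p <- c(a = NA_real_, b = NA_real_)
  use_t <- switch(normality_rule, force_t = TRUE, force_wilcoxon = FALSE, {
    shapiro_sub <- function(x) {
      if (length(x) < 3 || stats::var(x) == 0) return(0)  # not testably normal
      if (length(x) > 5000)
        x <- x[round(seq(1, length(x), length.out = 5000))]
      stats::shapiro.test(x)$p.value
    }
    norm_p <- c(a = shapiro_sub(values_a), b = shapiro_sub(values_b))
    all(norm_p > alpha)
  })
  if (use_t) {
    ht <- stats::t.test(values_a, values_b)  # Welch by default
    list(test = "welch_t", p = ht$p.value,
         statistic = unname(ht$statistic), normality_p = norm_p)
  } else {
    ht <- suppressWarnings(stats::wilcox.test(values_a, values_b))
    list(test = "wilcoxon", p = ht$p.value,
         statistic = unname(ht$statistic), normality_p = norm_p)
  }
}

#' Welch t-test from summary statistics
#'
#' Two-sided Welch test computed from group means, SDs, and sizes —
#' the route for checking published group comparisons when raw data are
#' unavailable.
#'
#' @param mean_a,sd_a,n_a,mean_b,sd_b,n_b Group summaries.
#' @return List with `t`, `df` (Welch-Satterthwaite), `p`.
#' @examples
#' welch_from_summary(97.14, 3.19, 1109, 96.24, 3.43, 87)$p  # ~0.02
#' @export
welch_from_summary <- function(mean_a, sd_a, n_a, mean_b, sd_b, n_b) {
  va <- sd_a^2 / n_a
  vb <- sd_b^2 / n_b
  t <- (mean_a - mean_b) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (n_a - 1) + vb^2 / (n_b - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Compare a categorical variable between groups
#'
#' Applies the cell-size rule: Fisher's exact test when any cell count is
#' at or below 5, Pearson chi-square (no continuity correction) otherwise.
#' `cell_rule = "expected"` switches the rule to expected counts.
#'
#' @param tab Contingency table (matrix of non-negative integer counts;
#'   levels x strata).
#' @param cell_rule `"observed"` (default, published wording) or
#'   `"expected"`.
#' @param threshold Cell-size cut-off (default 5).
#' @return List with `test` (name), `p`, `statistic` (chi-square statistic or
#'   `NA` for Fisher), `min_cell`.
#' @export
compare_categorical <- function(tab, cell_rule = c("observed", "expected"),
                                threshold = 5) {
  cell_rule <- match.arg(cell_rule)
  tab <- as.matrix(tab)
  if (any(tab < 0) || any(tab != round(tab)))
    stopf("contingency table must hold non-negative integer counts")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stopf("contingency table has an all-zero margin")
  cells <- if (cell_rule == "observed") tab else
    outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (min(cells) <= threshold) {
    ht <- stats::fisher.test(tab)
    list(test = "fisher_exact", p = ht$p.value, statistic = NA_real_,
         min_cell = min(cells))
  } else {
    # the rule keys on observed cells, so small *expected* counts can still
    # reach this path; the approximation warning is part of the design
    ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    list(test = "pearson_chisq", p = ht$p.value,
         statistic = unname(ht$statistic), min_cell = min(cells))
  }
}

#' Baseline characteristics table stratified by large-CDR status
#'
#' One row block per variable: mean (SD) [min, max] and the rule-selected
#' continuous test for numeric variables; per-level counts (column percent)
#' and the rule-selected categorical test otherwise. The GRS is included as a
#' continuous row when supplied.
#'
#' @param phenotypes Phenotype `data.frame` including `large_cdr`.
#' @param grs Optional per-sample GRS (same order as `phenotypes`).
#' @param variables Variables to summarise; defaults to the standard baseline
#'   set intersected with available columns.
#' @param normality_rule,cell_rule Passed to [compare_continuous()] /
#'   [compare_categorical()].
#' @return A `descriptive_table`: `data.frame` with columns `variable`,
#'   `level`, one summary column per stratum, `test`, `p`.
#' @export
build_descriptive_table <- function(phenotypes, grs = NULL,
                                    variables = NULL,
                                    normality_rule = "shapiro",
                                    cell_rule = "observed") {
  ph <- as.data.frame(phenotypes)
  if (!"large_cdr" %in% names(ph)) stopf("phenotypes must contain large_cdr")
  ph <- ph[!is.na(ph$large_cdr), , drop = FALSE]
  if (!is.null(grs)) {
    grs <- grs[!is.na(phenotypes$large_cdr)]
    ph$grs <- grs
  }
  strata <- factor(ifelse(ph$large_cdr == 1, "large_cdr", "no_large_cdr"),
                   levels = c("no_large_cdr", "large_cdr"))
  if (any(table(strata) == 0))
    stopf("a stratum has zero samples; cannot stratify by large_cdr")
  variables <- variables %||% intersect(
    c("age", "education", "smoking", "bmi_class", "diabetes", "cvd",
      "retinopathy", "ht_arm", "grs", "mse3"), names(ph))
  rows <- list()
  for (v in variables) {
    x <- ph[[v]]
    if (is.numeric(x) && length(unique(x)) > 2) {
      cmp <- compare_continuous(x[strata == "no_large_cdr"],
                                x[strata == "large_cdr"],
                                normality_rule = normality_rule)
      fmt <- function(z) sprintf("%.2f (%.2f) [%.2f, %.2f]", mean(z),
                                 stats::sd(z), min(z), max(z))
      rows[[v]] <- data.frame(
        variable = v, level = "",
        no_large_cdr = fmt(x[strata == "no_large_cdr"]),
        large_cdr = fmt(x[strata == "large_cdr"]),
        test = cmp$test, p = cmp$p, stringsAsFactors = FALSE
      )
    } else {
      f <- factor(x)
      tab <- table(f, strata)
      cmp <- compare_categorical(tab, cell_rule = cell_rule)
      pct <- prop.table(tab, margin = 2) * 100
      rows[[v]] <- data.frame(
        variable = v, level = rownames(tab),
        no_large_cdr = sprintf("%d (%.2f)", tab[, 1], pct[, 1]),
        large_cdr = sprintf("%d (%.2f)", tab[, 2], pct[, 2]),
        test = c(cmp$test, rep("", nrow(tab) - 1L)),
        p = c(cmp$p, rep(NA_real_, nrow(tab) - 1L)),
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  class(out) <- c("descriptive_table", class(out))
  out
}

#' Render a descriptive table as Markdown
#'
#' @param x A `descriptive_table`.
#' @return Character vector of Markdown lines.
#' @export
format_descriptive_markdown <- function(x) {
  hdr <- c("| Variable | Level | CDR < 0.6 | CDR >= 0.6 | Test | P |",
           "|---|---|---|---|---|---|")
  body <- sprintf("| %s | %s | %s | %s | %s | %s |",
                  x$variable, x$level, x$no_large_cdr, x$large_cdr, x$test,
                  ifelse(is.na(x$p), "", sprintf("%.3g", x$p)))
  c(hdr, body)
}
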
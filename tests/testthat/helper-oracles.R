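# Independent oracle implementations used to cross-check the package's
# model-fitting routes. These deliberately avoid glm()/lm().

# Logistic regression by hand-rolled iteratively reweighted least squares.
irls_logistic <- function(X, y, tol = 1e-12, maxit = 50) {
  beta <- rep(0, ncol(X))
  for (i in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    W <- mu * (1 - mu)
    z <- eta + (y - mu) / W
    beta_new <- solve(crossprod(X, X * W), crossprod(X, W * z))
    if (max(abs(beta_new - beta)) < tol) {
      beta <- drop(beta_new)
      break
    }
    beta <- drop(beta_new)
  }
  beta
}

# OLS via the normal equations.
normal_eq_ols <- function(X, y)
  unname(drop(solve(crossprod(X), crossprod(X, y))))

# Two-sided Fisher exact p for a 2x2 table by full hypergeometric
# enumeration (sum of outcome probabilities <= observed probability).
fisher_2x2_enum <- function(tab) {
  a <- tab[1, 1]
  m <- sum(tab[1, ])
  n <- sum(tab[2, ])
  k <- sum(tab[, 1])
  lo <- max(0, k - n)
  hi <- min(k, m)
  pr <- stats::dhyper(lo:hi, m, n, k)
  obs <- stats::dhyper(a, m, n, k)
  sum(pr[pr <= obs * (1 + 1e-7)])
}

# Two-sample exact Wilcoxon p by enumerating all group assignments.
wilcoxon_enum <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled)
  na <- length(a)
  obs <- sum(rank(pooled)[seq_len(na)])
  combs <- utils::combn(n, na)
  stats <- apply(combs, 2, function(idx) sum(rank(pooled)[idx]))
  mu <- na * (n + 1) / 2
  mean(abs(stats - mu) >= abs(obs - mu) - 1e-9)
}

# Tiny sample-record table builder for QC tests.
make_samples <- function(sample_id, participant_id = sample_id,
                         platform_id = "GWAS_A",
                         platform_snp_count = 900000L,
                         has_pca = TRUE, has_cdr = TRUE) {
  data.frame(sample_id = sample_id, participant_id = participant_id,
             platform_id = platform_id,
             platform_snp_count = platform_snp_count,
             has_pca = has_pca, has_cdr = has_cdr,
             stringsAsFactors = FALSE)
}

# Dosage matrix from a plain matrix with default allele coding.
make_dosages <- function(mat, counted = NULL, other = NULL) {
  if (is.null(colnames(mat)))
    colnames(mat) <- paste0("1:", seq_len(ncol(mat)))
  if (is.null(rownames(mat)))
    rownames(mat) <- paste0("S", seq_len(nrow(mat)))
  new_dosage_matrix(mat, data.frame(
    snp = colnames(mat),
    counted_allele = counted %||% rep("A", ncol(mat)),
    other_allele = other %||% rep("G", ncol(mat)),
    stringsAsFactors = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
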
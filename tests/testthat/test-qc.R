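test_that("duplicate resolution keeps the larger-platform sample", {
  s <- make_samples(c("a1", "a2", "b1"),
                    participant_id = c("A", "A", "B"),
                    platform_id = c("P500", "P900", "P900"),
                    platform_snp_count = c(500000L, 900000L, 900000L))
  out <- resolve_duplicates(s)
  expect_setequal(out$sample_id, c("a2", "b1"))
  frag <- attr(out, "qc")
  expect_equal(frag$removed$sample_id, "a1")
  expect_equal(frag$removed$reason, "duplicate_sample")
  expect_equal(frag$n_in - frag$n_removed, frag$n_out)
})

test_that("no duplicated participant means identity", {
  s <- make_samples(c("a", "b", "c"))
  out <- resolve_duplicates(s)
  expect_equal(out$sample_id, s$sample_id)
  expect_equal(nrow(attr(out, "qc")$removed), 0L)
})

test_that("equal SNP counts break ties on the smaller platform_id and log it", {
  s <- make_samples(c("x1", "x2"), participant_id = c("X", "X"),
                    platform_id = c("P_B", "P_A"),
                    platform_snp_count = c(700000L, 700000L))
  out <- resolve_duplicates(s)
  expect_equal(out$sample_id, "x2")  # platform P_A sorts first
  expect_match(attr(out, "qc")$removed$detail, "tie")
  # exhaustive 2-sample check: winner = larger count, else smaller platform_id
  for (cnt in list(c(1L, 2L), c(2L, 1L), c(2L, 2L))) {
    s2 <- make_samples(c("s1", "s2"), participant_id = c("P", "P"),
                       platform_id = c("PB", "PA"),
                       platform_snp_count = cnt * 100000L)
    kept <- resolve_duplicates(s2)$sample_id
    want <- if (cnt[1] > cnt[2]) "s1" else if (cnt[2] > cnt[1]) "s2" else "s2"
    expect_equal(kept, want)
  }
})

test_that("relative removal drops the smaller-platform member of each pair", {
  s <- make_samples(paste0("s", 1:6),
                    platform_snp_count = c(900000L, 550000L, 900000L,
                                           550000L, 900000L, 550000L))
  pairs <- data.frame(sample_a = c("s1", "s3", "s5"),
                      sample_b = c("s2", "s4", "s6"),
                      stringsAsFactors = FALSE)
  out <- remove_relatives(s, pairs)
  expect_setequal(out$sample_id, c("s1", "s3", "s5"))
  expect_equal(nrow(attr(out, "qc")$removed), 3L)
  # empty pair list is the identity
  out2 <- remove_relatives(s, NULL)
  expect_equal(out2$sample_id, s$sample_id)
  expect_error(remove_relatives(s, data.frame(sample_a = "s1",
                                              sample_b = "zz")),
               "unknown sample")
})

test_that("chained relative pairs leave no listed pair fully retained", {
  s <- make_samples(c("A", "B", "C"),
                    platform_snp_count = c(900000L, 550000L, 700000L))
  pairs <- data.frame(sample_a = c("A", "B"), sample_b = c("B", "C"),
                      stringsAsFactors = FALSE)
  out <- remove_relatives(s, pairs)
  for (k in seq_len(nrow(pairs)))
    expect_false(all(c(pairs$sample_a[k], pairs$sample_b[k]) %in%
                       out$sample_id))
})

test_that("missingness exclusion reason-codes PCA before CDR", {
  s <- make_samples(c("p", "q", "r"),
                    has_pca = c(FALSE, TRUE, TRUE),
                    has_cdr = c(TRUE, FALSE, TRUE))
  out <- filter_missing(s)
  expect_equal(out$sample_id, "r")
  rem <- attr(out, "qc")$removed
  expect_equal(rem$reason[rem$sample_id == "p"], "missing_pca")
  expect_equal(rem$reason[rem$sample_id == "q"], "missing_cdr")
  # fully observed cohort is the identity
  full <- make_samples(c("u", "v"))
  expect_equal(filter_missing(full)$sample_id, c("u", "v"))
})

test_that("the QC chain is idempotent and accounts for every sample", {
  cfg <- simulation_config(n_samples = 500, n_duplicate_samples = 4,
                           n_relative_pairs = 3, n_missing_pca = 14,
                           n_missing_cdr = 14, seed = 21)
  ch <- simulate_cohort(cfg)
  res <- run_qc(ch$samples, ch$phenotypes, ch$relative_pairs)
  counts <- res$report$counts$n
  expect_true(all(diff(counts) <= 0))
  # removed + retained = input at every stage
  removed_per_stage <- table(factor(res$report$removed$stage,
                                    levels = res$report$counts$stage[-1]))
  expect_equal(counts[-1] + as.integer(removed_per_stage), counts[-length(counts)])
  # every removal appears exactly once
  expect_equal(anyDuplicated(res$report$removed$sample_id), 0L)
  # retained set equals the generator's truth
  expect_setequal(res$retained$sample_id, ch$qc_truth$expected_retained)
  # 3 pairs -> 3 removals; 28 missing-data removals
  expect_equal(sum(res$report$removed$reason == "first_degree_relative"), 3L)
  expect_equal(sum(res$report$removed$reason %in%
                     c("missing_pca", "missing_cdr")), 28L)
  # idempotence: rerunning on the retained set changes nothing
  res2 <- run_qc(res$retained, ch$phenotypes, ch$relative_pairs)
  expect_equal(res2$retained$sample_id, res$retained$sample_id)
})
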
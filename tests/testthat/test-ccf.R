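test_that("SNV filters apply the four depth/VAF rules", {
  base <- tibble::tibble(
    sample_id = "S1", gene = "G", chromosome = "1", position = 1L,
    ref_allele = "C", alt_allele = "T", effect = "non_silent",
    context_5p = "A", context_3p = "G"
  )
  recs <- dplyr::bind_rows(
    dplyr::mutate(base, tumor_alt_count = 5L, tumor_depth = 9L,
                  normal_alt_count = 0L, normal_depth = 50L),   # tumor depth
    dplyr::mutate(base, tumor_alt_count = 20L, tumor_depth = 100L,
                  normal_alt_count = 0L, normal_depth = 9L),    # normal depth
    dplyr::mutate(base, tumor_alt_count = 20L, tumor_depth = 100L,
                  normal_alt_count = 3L, normal_depth = 50L),   # normal alt reads
    dplyr::mutate(base, tumor_alt_count = 9L, tumor_depth = 100L,
                  normal_alt_count = 0L, normal_depth = 50L),   # tumor VAF < 10%
    dplyr::mutate(base, tumor_alt_count = 20L, tumor_depth = 100L,
                  normal_alt_count = 2L, normal_depth = 50L),   # normal VAF 4%
    dplyr::mutate(base, tumor_alt_count = 12L, tumor_depth = 100L,
                  normal_alt_count = 0L, normal_depth = 50L)    # passes all
  )
  kept <- filter_snvs(recs)
  expect_equal(nrow(kept), 1)
  expect_equal(kept$tumor_alt_count, 12L)
  rep <- snv_filter_report(kept)
  expect_equal(rep$n_rejected[rep$rule == "min_depth"], 2L)
  expect_equal(rep$n_rejected[rep$rule == "max_normal_alt"], 1L)
  expect_equal(rep$n_rejected[rep$rule == "min_tumor_vaf"], 1L)
  expect_equal(rep$n_rejected[rep$rule == "max_normal_vaf"], 2L)
  # boundary values are kept: depth 10, normal alt 2, VAF exactly 10% / 2%
  edge <- dplyr::mutate(base, tumor_alt_count = 1L, tumor_depth = 10L,
                        normal_alt_count = 2L, normal_depth = 100L)
  expect_equal(nrow(filter_snvs(edge)), 1)
})

test_that("multiplicity point estimate follows the clamped rounding rule", {
  expect_equal(estimate_multiplicity(0.5, 1, 2), 1L)
  expect_equal(estimate_multiplicity(1.0, 1, 2), 2L)
  expect_equal(estimate_multiplicity(0.33, 0.6, 3), 1L)  # round(1.43) = 1
  # clamping to [1, q_t]
  expect_equal(estimate_multiplicity(0.01, 1, 2), 1L)
  expect_equal(estimate_multiplicity(0.99, 1, 1), 1L)
  expect_error(estimate_multiplicity(0.5, 0, 2), "purity")
  expect_error(estimate_multiplicity(0.5, 1, 0), "q_t")
})

test_that("grid posterior matches the independent dense-grid oracle", {
  # spec'd reference points, frozen from the oracle
  p1 <- ccf_posterior(50, 100, 1, 2, m = 1)
  o1 <- oracle_ccf(50, 100, 1, 2, 1)
  expect_equal(p1$prob_ge_095, o1$p95, tolerance = 1e-9)
  expect_equal(p1$prob_ge_095, 0.4433193, tolerance = 1e-6)
  # posterior mass at CCF >= 0.95 is below 1/2 here, so the call is subclonal
  expect_equal(call_clonality(p1), "subclonal")

  p2 <- ccf_posterior(20, 100, 1, 2, m = 1)
  expect_equal(p2$point_estimate, oracle_ccf(20, 100, 1, 2, 1)$point,
               tolerance = 1e-9)
  expect_equal(p2$point_estimate, 0.41, tolerance = 0.01)
  expect_equal(call_clonality(p2), "subclonal")

  p3 <- ccf_posterior(1000, 1000, 1, 2, m = 2)
  expect_gt(p3$prob_ge_095, 0.99)
  expect_equal(call_clonality(p3), "clonal")

  expect_equal(sum(p1$probabilities), 1, tolerance = 1e-9)
  expect_error(ccf_posterior(10, 100, 1, 1, m = 2), "multiplicity")
})

test_that("posterior oracle equivalence holds over random inputs", {
  set.seed(424)
  n <- 300
  depth <- sample(20:400, n, replace = TRUE)
  alt <- rbinom(n, depth, runif(n, 0.05, 0.6))
  purity <- runif(n, 0.2, 1)
  q_t <- sample(1:4, n, replace = TRUE)
  m <- pmin(sample(1:2, n, replace = TRUE), q_t)
  stats <- clonarch:::ccf_posterior_stats(alt, depth, purity, q_t, m)
  tv <- vapply(seq_len(n), function(i) {
    o <- oracle_ccf(alt[i], depth[i], purity[i], q_t[i], m[i])
    p <- ccf_posterior(alt[i], depth[i], purity[i], q_t[i], m = m[i])
    max(0.5 * sum(abs(p$probabilities - o$probs)),
        abs(stats$prob_ge_095[i] - o$p95))
  }, numeric(1))
  expect_lt(max(tv), 1e-6)
})

test_that("prob_ge_095 is non-decreasing in alt at fixed depth", {
  for (setting in list(c(100, 1, 2, 1), c(60, 0.5, 2, 1), c(200, 0.8, 3, 2))) {
    depth <- setting[1]
    stats <- clonarch:::ccf_posterior_stats(
      0:depth, rep(depth, depth + 1), rep(setting[2], depth + 1),
      rep(setting[3], depth + 1), rep(setting[4], depth + 1))
    expect_true(all(diff(stats$prob_ge_095) >= -1e-12))
  }
})

test_that("clonality rule is strict at probability 0.5", {
  expect_equal(call_clonality(c(0.51, 0.50, 0.0)),
               c("clonal", "subclonal", "subclonal"))
})

test_that("multi-hit genes are excluded only on non-silent counts", {
  calls <- tibble::tibble(
    sample_id = c("S1", "S1", "S1", "S1", "S2", "S2", "S2"),
    gene = c("VHL", "VHL", "SETD2", "SETD2", "VHL", "AAA", "BBB"),
    effect = c("non_silent", "non_silent", "non_silent", "silent",
               "non_silent", "non_silent", "non_silent")
  )
  out <- exclude_multihit_genes(calls)
  # both non-silent VHL SNVs of S1 removed; SETD2 keeps both rows (1 non-silent)
  expect_equal(sum(out$sample_id == "S1" & out$gene == "VHL"), 0)
  expect_equal(sum(out$sample_id == "S1" & out$gene == "SETD2"), 2)
  # one SNV per gene elsewhere is untouched
  expect_equal(sum(out$sample_id == "S2"), 3)
})

test_that("pipeline calls respect copy number lookup and skip q_t = 0 sites", {
  co <- small_cohort()
  filt <- filter_snvs(co$mutations)
  calls <- snv_clonality(filt, co$purity, co$segments)
  expect_true(all(calls$clonality %in% c("clonal", "subclonal")))
  expect_true(all(calls$q_t >= 1))
  expect_true(all(calls$ccf >= 0 & calls$ccf <= 1))
  # q_t = 0 sites are dropped with a warning
  seg0 <- co$segments
  idx <- which(seg0$sample_id == calls$sample_id[1] &
                 seg0$chromosome == calls$chromosome[1] &
                 seg0$start <= calls$position[1] & seg0$end >= calls$position[1])
  seg0$total_copy_number[idx] <- 0L
  expect_warning(calls0 <- snv_clonality(filt, co$purity, seg0),
                 "homozygously deleted")
  expect_lt(nrow(calls0), nrow(calls))
  # a sub-cohort can be excluded from gene-level clonality analysis
  drop <- unique(calls$sample_id)[1:3]
  calls_ex <- snv_clonality(filt, co$purity, co$segments,
                            exclude_samples = drop)
  expect_false(any(calls_ex$sample_id %in% drop))
})
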
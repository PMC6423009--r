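test_that("channel folding maps the 192 raw combinations onto 96 channels, 2 each", {
  expect_equal(context_channel("C", "T", "A", "G"), "A[C>T]G")
  expect_equal(context_channel("G", "A", "C", "T"), "A[C>T]G")
  bases <- c("A", "C", "G", "T")
  raw <- tidyr::expand_grid(ref = bases, alt = bases, fp = bases, tp = bases) |>
    dplyr::filter(ref != alt)
  lab <- context_channel(raw$ref, raw$alt, raw$fp, raw$tp)
  expect_equal(length(lab), 192 * 16 / 16)  # 12 substitutions x 16 flank pairs
  tab <- table(lab)
  expect_equal(length(tab), 96)
  expect_true(all(tab == 2))
  expect_setequal(names(tab), sig_channels())
  # ambiguous bases are dropped with a warning
  expect_warning(out <- context_channel(c("C", "N"), c("T", "A"), "A", "G"),
                 "dropped")
  expect_equal(is.na(out), c(FALSE, TRUE))
})

test_that("context matrix counts per channel and sample, with strata", {
  co <- small_cohort()
  calls <- snv_clonality(filter_snvs(co$mutations), co$purity, co$segments)
  m <- build_context_matrix(calls)
  expect_equal(nrow(m), 96)
  expect_equal(sum(m), nrow(calls))
  mc <- build_context_matrix(calls, stratum = "clonal")
  ms <- build_context_matrix(calls, stratum = "subclonal")
  expect_equal(sum(mc) + sum(ms), nrow(calls))
  # counts agree with the planted channel of each mutation
  truth <- dplyr::inner_join(calls, co$truth$mutations, by = "mutation_id")
  planted_lab <- context_channel(truth$ref_allele, truth$alt_allele,
                                 truth$context_5p, truth$context_3p)
  expect_equal(unname(rowSums(m)),
               as.vector(table(factor(planted_lab, levels = sig_channels()))))
})

test_that("NMF factorizes a rank-1 matrix exactly and stays nonnegative and monotone", {
  set.seed(11)
  w <- runif(96); h <- runif(30, 1, 50)
  V <- outer(w, h)
  rownames(V) <- sig_channels()
  fit <- extract_signatures(V, 1, n_restarts = 3, seed = 2)
  expect_lt(fit$relative_error, 1e-6)
  expect_true(all(fit$signatures >= 0))
  expect_true(all(fit$exposures >= 0))
  expect_equal(unname(colSums(fit$signatures)), 1, tolerance = 1e-9)
  expect_equal(cosine_similarity(fit$signatures[, 1], w), 1, tolerance = 1e-6)
  # objective trace never increases
  expect_true(all(diff(fit$objective) <= 1e-8 * pmax(head(fit$objective, -1), 1)))
  # reconstruction conserves sample totals approximately
  expect_equal(colSums(fit$signatures %*% fit$exposures), colSums(V),
               tolerance = 1e-4)
})

test_that("planted signatures are recovered from a synthetic cohort", {
  co <- cached_cohort("sig100", cohort_config(n_samples = 100, seed = 11,
                                              mean_mutations_per_sample = 100))
  m <- build_context_matrix(co$mutations)
  fit <- extract_signatures(m, 3, n_restarts = 8, seed = 5)
  cs <- cosine_matrix(fit$signatures, example_signatures())
  expect_true(all(apply(cs, 2, max) >= 0.90))
  mr <- match_reference(fit, example_signatures())
  expect_setequal(mr$best_match, c("CpG", "AA", "Broad"))
  expect_true(all(mr$matched))
})

test_that("reference matching reports cosine and Pearson without reordering", {
  ref <- example_signatures()
  mr <- match_reference(ref, ref)
  expect_equal(mr$best_match, colnames(ref))
  expect_equal(mr$cosine, rep(1, 3), tolerance = 1e-12)
  # orthogonal signature has cosine 0 to a disjoint reference
  a <- matrix(0, 96, 1, dimnames = list(sig_channels(), "x"))
  a[1, 1] <- 1
  b <- matrix(0, 96, 1, dimnames = list(sig_channels(), "y"))
  b[2, 1] <- 1
  expect_equal(match_reference(a, b / sum(b))$cosine, 0)
  # hand-computed cosine: v = e1 + e3, u = e1 + e2 -> 0.5
  v <- matrix(0, 96, 1, dimnames = list(sig_channels(), NULL)); v[c(1, 3)] <- 1
  u <- matrix(0, 96, 1, dimnames = list(sig_channels(), "u")); u[c(1, 2)] <- 0.5
  expect_equal(match_reference(v, u)$cosine, 0.5)
  # channel-order mismatch is an error, never silently reordered
  bad <- ref[rev(seq_len(96)), , drop = FALSE]
  expect_error(match_reference(ref, bad), "channel order")
})

test_that("rank selection recovers the planted number of processes", {
  co <- cached_cohort("sig100", cohort_config(n_samples = 100, seed = 11,
                                              mean_mutations_per_sample = 100))
  m <- build_context_matrix(co$mutations)
  sel <- select_n_processes(m, k_range = 1:4, n_boot = 8, n_restarts = 3,
                            max_iter = 300, tol = 1e-6, seed = 9)
  expect_equal(sel$best_k, 3L)
  # single-signature data selects k = 1
  ref <- example_signatures()
  cfg1 <- cohort_config(n_samples = 60, seed = 31, mean_mutations_per_sample = 100,
                        planted_signatures = ref[, 1, drop = FALSE],
                        signature_weights = c(CpG = 1))
  co1 <- cached_cohort("sig1", cfg1)
  sel1 <- select_n_processes(build_context_matrix(co1$mutations), 1:3,
                             n_boot = 8, n_restarts = 3, max_iter = 300,
                             tol = 1e-6, seed = 9)
  expect_equal(sel1$best_k, 1L)
  # a k_range of length one returns that k with its report
  sel_one <- select_n_processes(m, k_range = 3, n_boot = 4, n_restarts = 2,
                                max_iter = 250, tol = 1e-6, seed = 1)
  expect_equal(sel_one$best_k, 3L)
  expect_equal(nrow(sel_one$report), 1)
})

test_that("clonal/subclonal signature enrichment flags a stratum-specific process", {
  ref <- example_signatures()
  set.seed(77)
  # clonal stratum: CpG + Broad; subclonal stratum: dominated by AA
  clonal <- matrix(rmultinom(40, 150, 0.6 * ref[, "CpG"] + 0.4 * ref[, "Broad"]),
                   nrow = 96, dimnames = list(sig_channels(), NULL))
  subclonal <- matrix(rmultinom(40, 80, 0.7 * ref[, "AA"] + 0.3 * ref[, "Broad"]),
                      nrow = 96, dimnames = list(sig_channels(), NULL))
  fit <- extract_signatures(cbind(clonal, subclonal), 3, n_restarts = 6, seed = 3)
  enr <- signature_clonality_enrichment(clonal, subclonal, fit)
  mr <- match_reference(fit, ref)
  aa_sig <- mr$signature[mr$best_match == "AA"][1]
  row <- enr[enr$signature == aa_sig, ]
  expect_equal(row$direction, "subclonal")
  expect_lt(row$fdr, 0.05)
  # an empty stratum yields NA with a warning
  expect_warning(
    na_enr <- signature_clonality_enrichment(clonal * 0, subclonal, fit),
    "zero mutations")
  expect_true(all(is.na(na_enr$p_value)))
})

test_that("enrichment p-values equal the exact conditional enumeration", {
  # a signature set whose columns are indicator-like profiles lets the
  # attributed 2x2 tables be controlled exactly
  W <- matrix(0, 96, 2, dimnames = list(sig_channels(), c("S1", "S2")))
  W[1, 1] <- 1
  W[2, 2] <- 1
  fake <- structure(list(signatures = W, k = 2), class = "signature_set")
  clonal <- matrix(0, 96, 1, dimnames = list(sig_channels(), "c"))
  subclonal <- matrix(0, 96, 1, dimnames = list(sig_channels(), "s"))
  clonal[1, 1] <- 10    # all clonal mutations from S1
  subclonal[2, 1] <- 10 # all subclonal mutations from S2
  enr <- signature_clonality_enrichment(clonal, subclonal, fake)
  # enumeration oracle: sum of hypergeometric point masses <= observed,
  # conditioning on margins (10, 10) x (10, 10)
  support <- 0:10
  pm <- dhyper(support, 10, 10, 10)
  p_exact <- sum(pm[pm <= pm[support == 10] * (1 + 1e-7)])
  expect_equal(p_exact, 2 / choose(20, 10), tolerance = 1e-12)
  expect_equal(enr$p_value, rep(p_exact, 2), tolerance = 1e-9)
  # balanced table carries no association
  clonal[1:2, 1] <- 5
  subclonal[1:2, 1] <- 5
  expect_equal(signature_clonality_enrichment(clonal, subclonal, fake)$p_value,
               c(1, 1))
})
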
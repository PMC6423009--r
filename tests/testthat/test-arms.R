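test_that("segment direction follows rounded ploidy", {
  expect_equal(classify_segment_direction(c(3, 1, 2), 2.1),
               c("amp", "del", "neutral"))
  expect_equal(classify_segment_direction(2, 3.6), "del")
})

test_that("arm CCF is the median with the even-count midpoint convention", {
  expect_equal(arm_ccf(c(0.9, 1.0, 0.8)), 0.9)
  expect_equal(arm_ccf(c(0.4, 0.6)), 0.5)
  expect_equal(arm_ccf(1.0), 1.0)
  expect_error(arm_ccf(numeric()), "no contributing")
})

test_that("arm aggregation applies the >50% cumulative length rule", {
  arm <- tibble::tibble(arm_id = "1p", chromosome = "1", start = 1, end = 100)
  seg <- function(start, end, cn, ccf) {
    tibble::tibble(sample_id = "S1", chromosome = "1", start = start, end = end,
                   total_copy_number = cn, segment_ccf = ccf)
  }
  # clonal deletions covering 60% -> clonal del
  s <- dplyr::bind_rows(seg(1, 40, 1L, 0.99), seg(41, 60, 1L, 0.97),
                        seg(61, 100, 2L, NA))
  ev <- aggregate_arm(s, arm, "del")
  expect_equal(ev$clonality, "clonal")
  expect_equal(ev$clonal_length_fraction, 0.6)
  expect_equal(ev$ccf, 0.98)
  # subclonal deletions covering 70% -> subclonal del
  s2 <- dplyr::bind_rows(seg(1, 70, 1L, 0.4), seg(71, 100, 2L, NA))
  ev2 <- aggregate_arm(s2, arm, "del")
  expect_equal(ev2$clonality, "subclonal")
  expect_equal(ev2$ccf, 0.4)
  # clonal 40% + subclonal 40% -> neither exceeds 0.5 -> none
  s3 <- dplyr::bind_rows(seg(1, 40, 1L, 0.99), seg(41, 80, 1L, 0.3),
                         seg(81, 100, 2L, NA))
  ev3 <- aggregate_arm(s3, arm, "del")
  expect_equal(ev3$clonality, "none")
  expect_true(is.na(ev3$ccf))
  expect_lte(ev3$clonal_length_fraction + ev3$subclonal_length_fraction, 1)
  # no altered overlap -> zero-row event
  expect_equal(nrow(aggregate_arm(seg(1, 100, 2L, NA), arm, "del")), 0)
  # overlap lengths are clipped to the arm span
  s4 <- seg(-50, 200, 1L, 0.99)
  ev4 <- aggregate_arm(s4, arm, "del")
  expect_equal(ev4$clonal_length_fraction, 1)
})

test_that("planted arm events are recovered with direction and clonality", {
  co <- small_cohort()
  ev <- arm_events(co$segments, co$purity, co$arms)
  truth <- co$truth$arm_events
  joined <- dplyr::inner_join(ev, truth, by = c("sample_id", "arm_id"),
                              suffix = c("", ".true"))
  expect_equal(nrow(joined), nrow(truth))
  expect_gte(mean(joined$direction == joined$direction.true), 0.95)
  expect_gte(mean(joined$clonality == joined$clonality.true), 0.95)
  # subclonal arm CCFs track the planted CCF
  sub <- dplyr::filter(joined, clonality.true == "subclonal")
  expect_lt(max(abs(sub$ccf - sub$ccf.true)), 0.1)
})

test_that("whole-chromosome labels appear only when both arms agree", {
  arms <- tibble::tibble(arm_id = c("9p", "9q", "14q"),
                         chromosome = c("9", "9", "14"),
                         start = c(1, 41, 1), end = c(40, 140, 100))
  ev <- tibble::tibble(
    sample_id = c("S1", "S1", "S1", "S2", "S2"),
    arm_id = c("9p", "9q", "14q", "9p", "9q"),
    event_id = c("del(9p)", "del(9q)", "del(14q)", "del(9p)", "amp(9q)"),
    direction = c("del", "del", "del", "del", "amp"),
    clonality = c("clonal", "clonal", "subclonal", "clonal", "clonal"),
    ccf = c(1, 0.9, 0.4, 1, 1),
    clonal_length_fraction = c(0.9, 0.8, 0, 0.9, 0.9),
    subclonal_length_fraction = c(0, 0, 0.8, 0, 0),
    altered_fraction = c(0.9, 0.8, 0.8, 0.9, 0.9)
  )
  out <- collapse_chromosome_events(ev, arms)
  expect_true("del(9)" %in% out$event_id[out$sample_id == "S1"])
  expect_equal(out$ccf[out$event_id == "del(9)"], 0.95)
  expect_true("del(14q)" %in% out$event_id[out$sample_id == "S1"])
  # discordant directions on S2 keep their arm labels
  expect_setequal(out$event_id[out$sample_id == "S2"], c("del(9p)", "amp(9q)"))
})

test_that("frequency filter keeps genes at 3% and arms at 10%, inclusive", {
  gene_calls <- tibble::tibble(
    sample_id = c(sprintf("S%03d", 1:3), sprintf("S%03d", 1:2), "S001"),
    gene = c(rep("G3", 3), rep("G2", 2), "GSIL"),
    effect = c(rep("non_silent", 5), "silent")
  )
  arm_calls <- tibble::tibble(
    sample_id = sprintf("S%03d", 1:19),
    event_id = c(rep("del(1p)", 10), rep("amp(2q)", 9)),
    clonality = "clonal"
  )
  out <- frequency_filter(gene_calls, arm_calls, n_samples = 100)
  expect_setequal(out$event_id, c("G3", "del(1p)"))  # 3/100 and 10/100 kept
  expect_false("G2" %in% out$event_id)               # 2/100 dropped
  expect_false("amp(2q)" %in% out$event_id)          # 9/100 dropped
  expect_false("GSIL" %in% out$event_id)             # silent never counts
  expect_error(frequency_filter(gene_calls, arm_calls, 0), "positive")
})
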
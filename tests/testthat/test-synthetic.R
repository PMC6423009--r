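test_that("identical seeds give identical cohorts and seeds differ otherwise", {
  a <- generate_cohort(cohort_config(n_samples = 15, seed = 7))
  b <- generate_cohort(cohort_config(n_samples = 15, seed = 7))
  expect_identical(a$mutations, b$mutations)
  expect_identical(a$segments, b$segments)
  expect_identical(a$clinical, b$clinical)
  expect_identical(a$truth, b$truth)
  c <- generate_cohort(cohort_config(n_samples = 15, seed = 8))
  expect_false(identical(a$mutations, c$mutations))
})

test_that("clonal_fraction = 1 plants no subclonal mutation", {
  co <- generate_cohort(cohort_config(n_samples = 20, seed = 5,
                                      clonal_fraction = 1))
  expect_true(all(co$truth$mutations$clonality == "clonal"))
  expect_true(all(co$truth$mutations$ccf == 1))
})

test_that("planted event counts match the truth set exactly", {
  co <- small_cohort()
  # every emitted mutation has exactly one truth entry and vice versa
  expect_setequal(co$mutations$mutation_id, co$truth$mutations$mutation_id)
  expect_equal(nrow(co$mutations), nrow(co$truth$mutations))
  # arm truth maps one-to-one onto planted altered arms in the segments
  seg_altered <- co$segments |>
    dplyr::filter(total_copy_number != 2) |>
    dplyr::distinct(sample_id, chromosome)
  arm_chrom <- sub("[pq]$", "", co$truth$arm_events$arm_id)
  expect_true(all(paste(co$truth$arm_events$sample_id, arm_chrom) %in%
                    paste(seg_altered$sample_id, seg_altered$chromosome)))
})

test_that("clonal VAFs concentrate around purity/2 in copy-neutral regions", {
  co <- cached_cohort("vaf", cohort_config(n_samples = 50, seed = 17,
                                           purity_range = c(0.6, 0.6),
                                           mean_mutations_per_sample = 120))
  tr <- dplyr::inner_join(co$mutations, co$truth$mutations, by = "mutation_id",
                          suffix = c("", ".t"))
  q <- clonarch:::lookup_q_t(co$mutations, co$segments)
  cn2_clonal <- tr$ccf == 1 & q == 2
  vaf <- tr$tumor_alt_count[cn2_clonal] / tr$tumor_depth[cn2_clonal]
  # 3 binomial SDs around p/2 = 0.30 at the mean depth
  expect_lt(abs(mean(vaf) - 0.30), 3 * sqrt(0.3 * 0.7 / 100) / sqrt(sum(cn2_clonal)))
  expect_gt(mean(abs(vaf - 0.30) <= 3 * sqrt(0.3 * 0.7 / 100)), 0.95)
})

test_that("planted signature mixtures are reproduced channel-wise", {
  ref <- example_signatures()
  set.seed(3)
  # a signature concentrated on one channel yields only that channel
  one <- matrix(0, 96, 1, dimnames = list(sig_channels(), "only"))
  one[42, 1] <- 1
  lab <- plant_signature_mutations(one, 1, 100)
  expect_equal(unique(lab), sig_channels()[42])
  # two equal signatures on disjoint channels split within 3 binomial SDs
  two <- matrix(0, 96, 2, dimnames = list(sig_channels(), c("a", "b")))
  two[1, 1] <- 1; two[96, 2] <- 1
  lab2 <- plant_signature_mutations(two, c(0.5, 0.5), 10000)
  n_a <- sum(lab2 == sig_channels()[1])
  expect_lt(abs(n_a - 5000), 3 * sqrt(10000 * 0.25))
  expect_equal(plant_signature_mutations(ref, c(0.4, 0.25, 0.35), 0),
               character())
  expect_error(plant_signature_mutations(ref, c(-0.1, 0.6, 0.5), 10),
               "nonnegative")
})

test_that("infeasible or invalid configs are rejected", {
  expect_error(cohort_config(clonal_fraction = 1.2), "clonal_fraction")
  expect_error(cohort_config(purity_range = c(0, 0.9)), "purity_range")
  ev <- synthetic_driver_events()
  ev$frequency[ev$event_id == "VHL"] <- 1.5
  expect_error(cohort_config(driver_events = ev), "frequencies")
  # an early event too rare to ever co-occur with later events
  ev2 <- abc_driver_events()
  ev2$frequency <- c(0.01, 0.8, 0.02)
  expect_error(cohort_config(n_samples = 50, driver_events = ev2),
               "infeasible")
  st <- synthetic_subtypes(); st$proportion <- c(0.5, 0.2, 0.2)
  expect_error(cohort_config(subtypes = st), "sum to 1")
})

test_that("timing enforcement makes early events clonal alongside later ones", {
  co <- cached_cohort("abc", cohort_config(n_samples = 150, seed = 13,
                                           driver_events = abc_driver_events(),
                                           subtypes = neutral_subtypes()))
  tr_arm <- co$truth$arm_events
  tr_mut <- dplyr::filter(co$truth$mutations, !is.na(timing))
  per_sample <- dplyr::bind_rows(
    dplyr::select(tr_arm, sample_id, timing, clonality),
    dplyr::select(tr_mut, sample_id, timing, clonality)
  )
  rank <- c(early = 1, intermediate = 2, late = 3)
  bad <- per_sample |>
    dplyr::group_by(sample_id) |>
    dplyr::filter(any(rank[timing] < max(rank[timing]) &
                        clonality == "subclonal" &
                        rank[timing] != max(rank[timing])))
  expect_equal(nrow(bad), 0)
})

test_that("YAML configs round-trip into the generator", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "n_samples: 12",
    "seed: 3",
    "mean_mutations_per_sample: 25",
    "driver_events:",
    "  - event_id: del(3p)",
    "    kind: arm_del",
    "    arm: 3p",
    "    frequency: 0.8",
    "    timing: early",
    "  - event_id: VHL",
    "    kind: gene",
    "    gene: VHL",
    "    arm: 3p",
    "    position: 10",
    "    frequency: 0.5",
    "    timing: late"
  ), path)
  cfg <- read_cohort_config(path)
  expect_s3_class(cfg, "cohort_config")
  expect_equal(cfg$n_samples, 12L)
  expect_equal(nrow(cfg$driver_events), 2)
  co <- generate_cohort(cfg)
  expect_equal(nrow(co$purity), 12)
})
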
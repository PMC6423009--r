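toy_clinical <- function(n, time, event, seed = NULL) {
  tibble::tibble(
    sample_id = sprintf("P%03d", seq_len(n)),
    survival_time = time, event_observed = event,
    age = 60, sex = rep(c("male", "female"), length.out = n),
    t_stage = "T1", fuhrman_grade = "G2"
  )
}

test_that("the product-limit estimator matches the hand computation", {
  cl <- toy_clinical(3, c(1, 2, 3), c(TRUE, TRUE, FALSE))
  km <- km_logrank(cl, tibble::tibble(sample_id = cl$sample_id, group = "all"))
  cur <- tidy(km)
  # S(1) = 2/3, S(2) = (2/3) * (1/2) = 1/3
  expect_equal(cur$estimate[cur$time == 1], 2 / 3)
  expect_equal(cur$estimate[cur$time == 2], 1 / 3)
  expect_true(is.na(km$chisq))
  # with no censoring the estimator equals the empirical survival function
  cl2 <- toy_clinical(4, c(1, 2, 3, 4), TRUE)
  cur2 <- tidy(km_logrank(cl2, tibble::tibble(sample_id = cl2$sample_id,
                                              group = "all")))
  expect_equal(cur2$estimate, c(0.75, 0.5, 0.25, 0))
})

test_that("identical groups give a log-rank chi-square of exactly zero", {
  cl <- toy_clinical(6, rep(c(5, 10, 15), 2), rep(c(TRUE, TRUE, FALSE), 2))
  km <- km_logrank(cl, tibble::tibble(sample_id = cl$sample_id,
                                      group = rep(c("a", "b"), each = 3)))
  expect_identical(km$chisq, 0)
  expect_equal(km$p_value, 1)
  expect_error(km_logrank(cl, tibble::tibble(sample_id = "none", group = "a")),
               "no samples shared")
})

test_that("Cox fits recover a planted hazard ratio and reject constant terms", {
  co <- cached_cohort("surv", cohort_config(n_samples = 400, seed = 2))
  grp <- dplyr::transmute(co$truth$samples, sample_id,
                          high_risk = subtype %in% c("A", "C"))
  fit <- cox_model(co$clinical, grp)
  expect_equal(fit$model, "cox_univariate")
  expect_gt(fit$hazard_ratio, 2.0)
  expect_lt(fit$hazard_ratio, 3.6)
  expect_true(fit$ci_low <= fit$hazard_ratio & fit$hazard_ratio <= fit$ci_high)
  adj <- cox_model(co$clinical, grp, adjusted = TRUE)
  expect_equal(unique(adj$model), "cox_multivariate")
  expect_true(any(grepl("high_risk", adj$term)))
  expect_error(cox_model(co$clinical,
                         dplyr::mutate(grp, high_risk = TRUE)), "constant")
  ph <- cox_model(co$clinical, grp, check_ph = TRUE)
  expect_true(ph$ph_p_value >= 0 && ph$ph_p_value <= 1)
})

test_that("the Cox score test at beta = 0 agrees with the log-rank statistic", {
  cl <- toy_clinical(12, c(2, 4, 5, 7, 9, 12, 1, 3, 6, 8, 10, 11),
                     rep(TRUE, 12))
  g <- rep(c(0, 1), each = 6)
  df <- dplyr::mutate(cl, g = g)
  fit <- survival::coxph(survival::Surv(survival_time, event_observed) ~ g,
                         data = df, ties = "efron")
  sc <- summary(fit)$sctest[["test"]]
  km <- km_logrank(cl, tibble::tibble(sample_id = cl$sample_id,
                                      group = as.character(g)))
  expect_equal(sc, km$chisq, tolerance = 1e-8)
})

test_that("the univariate screen selects planted prognostic events", {
  co <- cached_cohort("surv", cohort_config(n_samples = 400, seed = 2))
  truth <- co$truth$arm_events
  calls <- dplyr::select(truth, event_id, sample_id, clonality)
  res <- univariate_screen(calls, co$clinical)
  # amp(12p) and del(9p) are enriched in the poor-prognosis cluster A,
  # del(1p)/del(10q) in C; VHL-cluster B is protective
  sel <- res$event_id[res$selected]
  expect_true(length(intersect(
    c("amp(12p)", "del(9p)", "del(1p)", "del(10q)", "del(6q)"), sel)) >= 3)
  # ubiquitous del(3p) carries no prognostic signal
  expect_false("del(3p)" %in% sel)
  # stratified mode reports separate clonal/subclonal strata
  res_s <- suppressWarnings(univariate_screen(calls, co$clinical,
                                              stratify_clonality = TRUE))
  expect_setequal(unique(res_s$stratum), c("clonal", "subclonal"))
  # events with too few carriers are skipped with a warning
  rare <- dplyr::bind_rows(calls,
                           tibble::tibble(event_id = "rare", sample_id = "S0001",
                                          clonality = "clonal"))
  expect_warning(res_r <- univariate_screen(rare, co$clinical), "fewer than")
  expect_true(is.na(res_r$p_value[res_r$event_id == "rare"]))
})

test_that("group comparisons run the chosen test with panel FDR", {
  df <- tibble::tibble(
    g = rep(c("x", "y"), each = 3),
    a = c(1, 2, 3, 101, 102, 103),
    b = c(1, 2, 3, 1, 2, 3),
    cat = c("m", "m", "m", "n", "n", "n")
  )
  tt <- compare_groups(df, c("a", "b"), "g", test = "t_test")
  expect_lt(tt$p_value[tt$variable == "a"], 0.001)
  expect_equal(tt$p_value[tt$variable == "b"], 1)
  expect_equal(tt$fdr, fdr_adjust(tt$p_value))
  mw <- compare_groups(df, "b", "g", test = "mann_whitney")
  expect_equal(mw$p_value, 1)
  fi <- compare_groups(df, "cat", "g", test = "fisher")
  expect_equal(fi$p_value, 2 / choose(6, 3), tolerance = 1e-12)
  expect_error(compare_groups(df[c(1, 4), ], "a", "g", test = "t_test"),
               "n >= 2")
  expect_error(compare_groups(dplyr::mutate(df, g = c("x", "y", "z", "x", "y", "z")),
                              "a", "g", test = "t_test"), "two groups")
})
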
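# Survival analysis and group comparisons.

surv_object <- function(clinical) {
  survival::Surv(clinical$survival_time, clinical$event_observed)
}

#' Kaplan-Meier curves and log-rank test
#'
#' Fits the product-limit estimator per group and, when two or more groups are
#' present, compares them with the log-rank test.
#'
#' @param clinical Clinical table (`sample_id, survival_time, event_observed`,
#'   ...).
#' @param groups Tibble with `sample_id` and `group`, or a vector of group
#'   labels named by sample id. Every group must contain at least one subject.
#' @return Object of class `"km_result"`: the `survfit` object, `chisq` and
#'   `p_value` of the log-rank test (`NA` for a single group), the number of
#'   groups, and the joined data.
#' @export
km_logrank <- function(clinical, groups) {
  if (!is.data.frame(groups)) {
    groups <- tibble(sample_id = names(groups), group = unname(groups))
  }
  check_columns(groups, c("sample_id", "group"), "groups")
  df <- inner_join(clinical, groups, by = "sample_id")
  if (nrow(df) == 0) abort("no samples shared between clinical table and groups")
  counts <- table(df$group)
  if (any(counts == 0)) abort("every group must contain at least one subject")
  df$group <- factor(df$group)
  fit <- survival::survfit(surv_object(df) ~ group, data = df)
  chisq <- NA_real_
  p <- NA_real_
  if (nlevels(df$group) >= 2) {
    sd <- survival::survdiff(surv_object(df) ~ group, data = df)
    chisq <- unname(sd$chisq)
    p <- stats::pchisq(chisq, df = nlevels(df$group) - 1, lower.tail = FALSE)
  }
  structure(list(fit = fit, chisq = chisq, p_value = p,
                 n_groups = nlevels(df$group), data = df),
            class = "km_result")
}

#' @export
print.km_result <- function(x, ...) {
  cat(sprintf("km_result: %d group(s), %d subjects", x$n_groups, nrow(x$data)))
  if (!is.na(x$chisq)) {
    cat(sprintf("; log-rank chisq %.3f, p = %.3g", x$chisq, x$p_value))
  }
  cat("\n")
  invisible(x)
}

#' Cox proportional-hazards regression
#'
#' Fits a partial-likelihood Cox model (Efron tie handling) for the supplied
#' terms; with `adjusted = TRUE` the model additionally includes age, sex,
#' T stage and Fuhrman grade as covariates.
#'
#' @param clinical Clinical table.
#' @param terms Tibble with `sample_id` and one or more term columns (numeric,
#'   logical or factor). Constant terms are an error.
#' @param adjusted Add the four clinical covariates.
#' @param check_ph Also run the Schoenfeld-residual test of the
#'   proportional-hazards assumption and report its global p-value.
#' @return Tibble with one row per fitted coefficient: `term, hazard_ratio,
#'   ci_low, ci_high, p_value, model, flagged` (`flagged` marks possible
#'   separation / non-convergence warnings from the fitter), plus
#'   `ph_p_value` when `check_ph = TRUE`.
#' @export
cox_model <- function(clinical, terms, adjusted = FALSE, check_ph = FALSE) {
  check_columns(terms, "sample_id", "terms")
  term_cols <- setdiff(names(terms), "sample_id")
  if (length(term_cols) == 0) abort("terms must contain at least one term column")
  df <- inner_join(clinical, terms, by = "sample_id")
  for (tc in term_cols) {
    if (length(unique(df[[tc]])) < 2) {
      abort(sprintf("term '%s' is constant across subjects", tc))
    }
  }
  covariates <- if (adjusted) c("age", "sex", "t_stage", "fuhrman_grade") else character()
  rhs <- paste(c(sprintf("`%s`", term_cols), covariates), collapse = " + ")
  f <- stats::as.formula(paste("surv_object(df) ~", rhs))
  n_events <- sum(df$event_observed)
  flagged <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(f, data = df, ties = "efron"),
    warning = function(w) {
      flagged <<- TRUE
      invokeRestart("muffleWarning")
    }
  )
  if (n_events < length(stats::coef(fit))) {
    abort("fewer observed events than model parameters")
  }
  s <- summary(fit)
  ci <- s$conf.int
  out <- tibble(
    term = rownames(s$coefficients),
    hazard_ratio = unname(s$coefficients[, "exp(coef)"]),
    ci_low = unname(ci[, "lower .95"]),
    ci_high = unname(ci[, "upper .95"]),
    p_value = unname(s$coefficients[, "Pr(>|z|)"]),
    model = if (adjusted) "cox_multivariate" else "cox_univariate",
    flagged = flagged
  )
  if (check_ph) {
    zp <- survival::cox.zph(fit)
    out$ph_p_value <- zp$table["GLOBAL", "p"]
  }
  out
}

#' Univariate survival screen of somatic events
#'
#' For every event, compares carriers against non-carriers with the log-rank
#' test; with `stratify_clonality = TRUE` the clonal and subclonal carriers
#' are each compared against the event-free samples separately. Events (or
#' strata) with fewer than `min_carriers` carriers are skipped with a warning.
#' The events passing the significance level are the selection fed to
#' [build_ccf_matrix()].
#'
#' @param calls Event calls: `event_id, sample_id, clonality`.
#' @param clinical Clinical table covering the cohort (its sample set defines
#'   the non-carriers).
#' @param stratify_clonality Test clonal/subclonal carriers separately.
#' @param alpha Selection level on the unadjusted p-value (default 0.05); the
#'   FDR-adjusted column is always reported.
#' @param min_carriers Minimum carriers per tested group (default 5).
#' @return Tibble: `event_id, stratum, n_carriers, chisq, p_value, fdr,
#'   selected`.
#' @export
univariate_screen <- function(calls, clinical, stratify_clonality = FALSE,
                              alpha = 0.05, min_carriers = 5) {
  events <- unique(calls$event_id)
  all_samples <- unique(clinical$sample_id)
  strata <- if (stratify_clonality) c("clonal", "subclonal") else "any"
  grid <- tidyr::expand_grid(event_id = events, stratum = strata)
  skipped <- character()
  res <- purrr::pmap_dfr(grid, function(event_id, stratum) {
    ev <- filter(calls, .data$event_id == !!event_id)
    carriers <- if (stratum == "any") unique(ev$sample_id)
    else unique(ev$sample_id[ev$clonality == stratum])
    non_carriers <- setdiff(all_samples, unique(ev$sample_id))
    carriers <- intersect(carriers, all_samples)
    if (length(carriers) < min_carriers) {
      skipped <<- c(skipped, sprintf("%s (%s)", event_id, stratum))
      return(tibble(event_id = event_id, stratum = stratum,
                    n_carriers = length(carriers), chisq = NA_real_,
                    p_value = NA_real_))
    }
    groups <- tibble(
      sample_id = c(carriers, non_carriers),
      group = rep(c("carrier", "non_carrier"),
                  c(length(carriers), length(non_carriers)))
    )
    km <- km_logrank(clinical, groups)
    tibble(event_id = event_id, stratum = stratum,
           n_carriers = length(carriers), chisq = km$chisq,
           p_value = km$p_value)
  })
  if (length(skipped) > 0) {
    warn(sprintf("skipped %d event stratum(s) with fewer than %d carriers: %s",
                 length(skipped), min_carriers,
                 paste(utils::head(skipped, 5), collapse = ", ")))
  }
  fdr <- rep(NA_real_, nrow(res))
  ok <- !is.na(res$p_value)
  fdr[ok] <- fdr_adjust(res$p_value[ok])
  res %>%
    mutate(fdr = fdr,
           selected = !is.na(.data$p_value) & .data$p_value < alpha)
}

#' Two-group comparisons over a panel of variables
#'
#' Applies the chosen two-sided test to each variable and FDR-adjusts the
#' p-values across the panel.
#'
#' @param data Data frame holding the variables and the grouping column.
#' @param values Character vector of variable column names. For
#'   `test = "fisher"` the variables must be categorical (the test runs on the
#'   variable x group contingency table).
#' @param group Name of the grouping column (exactly two groups for
#'   `mann_whitney` and `t_test`).
#' @param test One of `"mann_whitney"`, `"t_test"`, `"fisher"`.
#' @return Tibble: `variable, statistic, p_value, fdr`.
#' @export
compare_groups <- function(data, values, group,
                           test = c("mann_whitney", "t_test", "fisher")) {
  test <- match.arg(test)
  g <- data[[group]]
  if (is.null(g)) abort(sprintf("grouping column '%s' not found", group))
  lv <- unique(stats::na.omit(g))
  if (test %in% c("mann_whitney", "t_test") && length(lv) != 2) {
    abort(sprintf("%s requires exactly two groups", test))
  }
  res <- purrr::map_dfr(values, function(v) {
    x <- data[[v]]
    if (is.null(x)) abort(sprintf("value column '%s' not found", v))
    if (test == "fisher") {
      ft <- fisher.test(table(x, g), alternative = "two.sided")
      tibble(variable = v, statistic = NA_real_, p_value = ft$p.value)
    } else if (test == "mann_whitney") {
      a <- x[g == lv[1]]; b <- x[g == lv[2]]
      wt <- suppressWarnings(wilcox.test(a, b, alternative = "two.sided", exact = FALSE))
      tibble(variable = v, statistic = unname(wt$statistic), p_value = wt$p.value)
    } else {
      a <- x[g == lv[1]]; b <- x[g == lv[2]]
      if (length(a) < 2 || length(b) < 2) abort("t-test requires n >= 2 per group")
      tt <- t.test(a, b, alternative = "two.sided")
      tibble(variable = v, statistic = unname(tt$statistic), p_value = tt$p.value)
    }
  })
  mutate(res, fdr = fdr_adjust(.data$p_value))
}
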
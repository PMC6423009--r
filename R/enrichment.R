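# Permutation test for clonal / subclonal enrichment of an event.

#' Permutation test for clonal or subclonal enrichment
#'
#' Tests whether an event carrying `n_clonal` clonal and `n_subclonal`
#' subclonal alterations is enriched for either state relative to a cohort
#' pool of clonality labels. Each permutation draws
#' `n = n_clonal + n_subclonal` labels from the pool *without replacement*;
#' the clonal tail p-value is the fraction of permutations whose clonal count
#' reaches the observed one (counts are order-isomorphic to clonal/subclonal
#' ratios at fixed n, and avoid zero denominators). The subclonal tail is
#' computed symmetrically.
#'
#' By default the tail uses `>=` with an add-one correction,
#' `p = (b + 1) / (B + 1)`, which yields valid p-values; `tail = "gt"`
#' reproduces the plain `>` convention without the correction.
#'
#' @param n_clonal,n_subclonal Observed clonal and subclonal counts (their sum
#'   must be >= 1).
#' @param pool Logical vector of cohort clonality labels (`TRUE` = clonal) or
#'   a character vector of `"clonal"`/`"subclonal"`.
#' @param n_permutations Number of permutations (default 10,000).
#' @param tail `"ge"` (default, add-one corrected) or `"gt"`.
#' @param seed Optional integer seed.
#' @return One-row tibble: `n_clonal, n_subclonal, p_clonal, p_subclonal,
#'   n_permutations`.
#' @export
permutation_enrichment <- function(n_clonal, n_subclonal, pool,
                                   n_permutations = 10000,
                                   tail = c("ge", "gt"), seed = NULL) {
  tail <- match.arg(tail)
  if (is.character(pool)) pool <- pool == "clonal"
  n <- n_clonal + n_subclonal
  if (n < 1) abort("event must carry at least one alteration")
  if (length(pool) < n) abort("pool must be at least as large as the event count")
  if (n_permutations < 1) abort("n_permutations must be >= 1")
  if (!is.null(seed)) set.seed(seed)

  single_class <- length(unique(pool)) == 1
  if (single_class) {
    warn("cohort pool contains a single clonality class; matching tail reported as 1")
  }
  k <- vapply(seq_len(n_permutations), function(b) sum(sample(pool, n)),
              numeric(1))
  p_of <- function(exceed) {
    if (tail == "ge") (exceed + 1) / (n_permutations + 1)
    else exceed / n_permutations
  }
  p_clonal <- p_of(if (tail == "ge") sum(k >= n_clonal) else sum(k > n_clonal))
  p_subclonal <- p_of(if (tail == "ge") sum((n - k) >= n_subclonal)
                      else sum((n - k) > n_subclonal))
  tibble(n_clonal = n_clonal, n_subclonal = n_subclonal,
         p_clonal = p_clonal, p_subclonal = p_subclonal,
         n_permutations = n_permutations)
}

#' Cohort-wide clonal/subclonal enrichment of events
#'
#' Runs [permutation_enrichment()] for every frequency-filtered event against
#' the pool of all retained non-silent mutation labels (genes) or all arm
#' event labels (arms), then FDR-adjusts both tails across events.
#'
#' @param calls Per-event clonality calls: columns `event_id, sample_id,
#'   clonality`. For genes these are per-SNV calls (one per sample/gene);
#'   for arms, arm events with clonality `"clonal"`/`"subclonal"`.
#' @param events Character vector of event ids to test (default: all).
#' @param n_permutations,tail,seed Passed to [permutation_enrichment()].
#' @return Tibble per event with both tail p-values and `fdr_clonal`,
#'   `fdr_subclonal`.
#' @export
clonality_enrichment <- function(calls, events = NULL, n_permutations = 10000,
                                 tail = c("ge", "gt"), seed = NULL) {
  tail <- match.arg(tail)
  if (!is.null(seed)) set.seed(seed)
  calls <- filter(calls, .data$clonality %in% c("clonal", "subclonal"))
  events <- events %||% unique(calls$event_id)
  pool <- calls$clonality == "clonal"
  res <- purrr::map_dfr(events, function(ev) {
    sub <- filter(calls, .data$event_id == ev)
    out <- permutation_enrichment(sum(sub$clonality == "clonal"),
                                  sum(sub$clonality == "subclonal"),
                                  pool, n_permutations, tail)
    mutate(out, event_id = ev, .before = 1)
  })
  res %>%
    mutate(fdr_clonal = fdr_adjust(.data$p_clonal),
           fdr_subclonal = fdr_adjust(.data$p_subclonal))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Thin wrapper over `p.adjust(..., method = "fdr")` so the adjustment used
#' across the package is explicit and testable.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted q-values.
#' @examples
#' fdr_adjust(c(0.01, 0.02, 0.03))
#' @export
fdr_adjust <- function(p_values) {
  if (length(p_values) == 0) return(numeric(0))
  check_range(p_values[!is.na(p_values)], 0, 1, "p_values")
  p.adjust(p_values, method = "fdr")
}
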
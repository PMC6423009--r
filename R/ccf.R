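# Cancer-cell-fraction estimation and clonal/subclonal classification.
#
# Model: for a mutation with multiplicity m at a site of tumor total copy
# number q_t in a sample of purity p, the expected variant allele frequency at
# cancer cell fraction c is
#     vaf(c) = c * p * m / (p * q_t + (1 - p) * 2).
# The CCF posterior is the binomial likelihood of the observed alt/depth
# evaluated on a uniform grid over [0.01, 1] and normalized. An event is
# clonal when the posterior mass on CCF >= 0.95 exceeds 0.5.

ccf_grid <- function(grid_size = 100) seq(0.01, 1, length.out = grid_size)

expected_vaf_coef <- function(purity, q_t, m) {
  purity * m / (purity * q_t + (1 - purity) * 2)
}

#' Filter somatic SNVs by depth and allele-frequency rules
#'
#' Keeps records satisfying all four rules: tumor and germline read depth of
#' at least `min_depth` (default 10x); at most `max_normal_alt` variant
#' supporting reads in the germline (default 2); tumor variant allele
#' frequency of at least `min_tumor_vaf` (default 10%); germline variant
#' allele frequency of at most `max_normal_vaf` (default 2%).
#'
#' @param mutations Tibble of validated mutation records.
#' @param min_depth,max_normal_alt,min_tumor_vaf,max_normal_vaf Filter
#'   thresholds (see above).
#' @return The kept records, with a `"filter_report"` attribute counting
#'   rejections per rule (see [snv_filter_report()]). A record failing several
#'   rules is counted once per rule it fails.
#' @export
filter_snvs <- function(mutations, min_depth = 10, max_normal_alt = 2,
                        min_tumor_vaf = 0.10, max_normal_vaf = 0.02) {
  tumor_vaf <- mutations$tumor_alt_count / mutations$tumor_depth
  normal_vaf <- mutations$normal_alt_count / mutations$normal_depth
  fail <- tibble(
    depth = mutations$tumor_depth < min_depth | mutations$normal_depth < min_depth,
    normal_alt = mutations$normal_alt_count > max_normal_alt,
    tumor_vaf = tumor_vaf < min_tumor_vaf,
    normal_vaf = normal_vaf > max_normal_vaf
  )
  keep <- !Reduce(`|`, fail)
  report <- tibble(
    rule = c("min_depth", "max_normal_alt", "min_tumor_vaf", "max_normal_vaf"),
    n_rejected = c(sum(fail$depth), sum(fail$normal_alt),
                   sum(fail$tumor_vaf), sum(fail$normal_vaf))
  )
  kept <- mutations[keep, , drop = FALSE]
  attr(kept, "filter_report") <- report
  attr(kept, "n_input") <- nrow(mutations)
  kept
}

#' Per-rule rejection counts from [filter_snvs()]
#' @param filtered Output of [filter_snvs()].
#' @return Tibble with columns `rule` and `n_rejected`.
#' @export
snv_filter_report <- function(filtered) {
  attr(filtered, "filter_report") %||%
    tibble(rule = character(), n_rejected = integer())
}

#' Exclude low-purity samples
#'
#' Samples with tumor cell purity below `min_purity` (default 20%) are
#' removed; the boundary value is kept.
#'
#' @param purity Tibble with `sample_id, purity, ploidy`.
#' @param min_purity Inclusive lower bound on purity.
#' @return The retained rows of `purity`.
#' @export
exclude_low_purity <- function(purity, min_purity = 0.20) {
  filter(purity, .data$purity >= min_purity)
}

#' Estimate mutation multiplicity from observed VAF
#'
#' Point estimate of the number of mutant-allele copies per tumor cell:
#' `m = clamp(round(vaf * (purity * q_t + (1 - purity) * 2) / purity), 1, q_t)`.
#'
#' @param vaf Observed tumor variant allele frequency (vectorized).
#' @param purity Sample purity in (0, 1].
#' @param q_t Tumor total copy number at the site (>= 1).
#' @return Integer multiplicity in `[1, q_t]`.
#' @examples
#' estimate_multiplicity(0.5, 1, 2)   # 1: heterozygous diploid
#' estimate_multiplicity(1.0, 1, 2)   # 2: both copies mutated
#' @export
estimate_multiplicity <- function(vaf, purity, q_t) {
  if (any(purity <= 0 | purity > 1)) abort("purity must be in (0, 1]")
  if (any(q_t < 1)) abort("q_t must be >= 1 (homozygous-deleted sites carry no SNV)")
  m <- round(vaf * (purity * q_t + (1 - purity) * 2) / purity)
  as.integer(pmin(pmax(m, 1), q_t))
}

# Vectorized posterior summaries. Returns tibble(ccf, prob_ge_095).
ccf_posterior_stats <- function(alt, depth, purity, q_t, m, grid_size = 100) {
  n <- length(alt)
  grid <- ccf_grid(grid_size)
  coef <- expected_vaf_coef(purity, q_t, m)
  if (any(coef > 1 + 1e-12)) {
    abort("expected VAF exceeds 1 at CCF = 1: multiplicity inconsistent with copy number")
  }
  P <- matrix(grid, grid_size, n) * matrix(coef, grid_size, n, byrow = TRUE)
  ll <- dbinom(matrix(alt, grid_size, n, byrow = TRUE),
               matrix(depth, grid_size, n, byrow = TRUE), P, log = TRUE)
  ll <- ll - matrix(apply(ll, 2, max), grid_size, n, byrow = TRUE)
  W <- exp(ll)
  W <- W / matrix(colSums(W), grid_size, n, byrow = TRUE)
  tibble(
    ccf = pmin(colSums(W * grid), 1),
    prob_ge_095 = colSums(W[grid >= 0.95, , drop = FALSE])
  )
}

#' CCF posterior for a single mutation
#'
#' Evaluates the binomial likelihood of `alt` variant reads out of `depth` on
#' a uniform CCF grid over `[0.01, 1]` and normalizes it into a posterior.
#'
#' @param alt,depth Variant and total read counts (`alt <= depth`).
#' @param purity Sample purity in (0, 1].
#' @param q_t Tumor total copy number at the site.
#' @param m Mutation multiplicity; estimated with [estimate_multiplicity()]
#'   from the observed VAF when `NULL`.
#' @param grid_size Number of grid points (default 100, spacing 0.01).
#' @return Object of class `"ccf_posterior"`: a list with `grid`,
#'   `probabilities` (summing to 1), `point_estimate` (posterior mean, clamped
#'   to <= 1), `prob_ge_095` (mass on grid points >= 0.95) and `multiplicity`.
#' @examples
#' ccf_posterior(alt = 30, depth = 100, purity = 0.8, q_t = 2)
#' @export
ccf_posterior <- function(alt, depth, purity, q_t, m = NULL, grid_size = 100) {
  stopifnot(length(alt) == 1, length(depth) == 1)
  if (alt > depth) abort("alt must be <= depth")
  if (q_t < 1) {
    warn("q_t = 0: site is homozygously deleted, event skipped")
    return(NULL)
  }
  m <- m %||% estimate_multiplicity(alt / depth, purity, q_t)
  if (m < 1) abort("multiplicity must be >= 1")
  coef <- expected_vaf_coef(purity, q_t, m)
  if (coef > 1 + 1e-12) {
    abort("expected VAF exceeds 1 at CCF = 1: multiplicity inconsistent with copy number")
  }
  grid <- ccf_grid(grid_size)
  ll <- dbinom(alt, depth, grid * coef, log = TRUE)
  ll <- ll - max(ll)
  probs <- exp(ll) / sum(exp(ll))
  structure(
    list(grid = grid, probabilities = probs,
         point_estimate = min(sum(grid * probs), 1),
         prob_ge_095 = sum(probs[grid >= 0.95]),
         multiplicity = as.integer(m),
         alt = alt, depth = depth, purity = purity, q_t = q_t),
    class = "ccf_posterior"
  )
}

#' @export
print.ccf_posterior <- function(x, ...) {
  cat(sprintf(
    "CCF posterior: alt %d / depth %d, purity %.2f, q_t %d, m %d\n  point estimate %.3f, P(CCF >= 0.95) = %.3f -> %s\n",
    x$alt, x$depth, x$purity, x$q_t, x$multiplicity,
    x$point_estimate, x$prob_ge_095, call_clonality(x)))
  invisible(x)
}

#' Classify an event as clonal or subclonal
#'
#' An event is clonal when the posterior probability of CCF >= 0.95 is
#' strictly greater than 0.5, subclonal otherwise.
#'
#' @param posterior A `"ccf_posterior"` object or a numeric vector of
#'   `prob_ge_095` values.
#' @param threshold Probability cutoff (default 0.5, strict inequality).
#' @return Character vector, `"clonal"` or `"subclonal"`.
#' @export
call_clonality <- function(posterior, threshold = 0.5) {
  p <- if (inherits(posterior, "ccf_posterior")) posterior$prob_ge_095 else posterior
  if_else(p > threshold, "clonal", "subclonal")
}

# Tumor total copy number at each mutation site from the segment table.
# Sites not covered by any segment default to q_t = 2.
lookup_q_t <- function(mutations, segments) {
  if (is.null(segments) || nrow(segments) == 0) {
    return(rep(2L, nrow(mutations)))
  }
  key_m <- paste(mutations$sample_id, mutations$chromosome)
  key_s <- paste(segments$sample_id, segments$chromosome)
  q <- rep(2L, nrow(mutations))
  idx <- split(seq_len(nrow(segments)), key_s)
  for (grp in unique(key_m)) {
    si <- idx[[grp]]
    if (is.null(si)) next
    si <- si[order(segments$start[si])]
    mi <- which(key_m == grp)
    pos <- mutations$position[mi]
    hit <- findInterval(pos, segments$start[si])
    valid <- hit > 0 & pos <= segments$end[si][pmax(hit, 1)]
    q[mi[valid]] <- segments$total_copy_number[si][hit[valid]]
  }
  as.integer(q)
}

#' Per-SNV CCF and clonality calls for a cohort
#'
#' Runs the full per-mutation pipeline: joins sample purity (samples below the
#' purity cutoff are dropped; a mutated sample with no purity entry is an
#' error), looks up the tumor copy number at each site from the segment table
#' (default 2 when absent), estimates multiplicity, computes the grid
#' posterior, and classifies each SNV as clonal or subclonal. Mutations at
#' homozygously deleted sites (q_t = 0) are skipped with a warning.
#'
#' @param mutations Filtered mutation records (see [filter_snvs()]).
#' @param purity Purity table (`sample_id, purity, ploidy`).
#' @param segments Optional segment table for site copy number.
#' @param min_purity Purity cutoff applied via [exclude_low_purity()].
#' @param exclude_samples Optional sample ids dropped from the calls, e.g. a
#'   whole-genome-sequenced sub-cohort whose depth is too low for reliable
#'   subclonal detection.
#' @param grid_size CCF grid size.
#' @return Tibble with one row per retained SNV: identifiers, `vaf`,
#'   `multiplicity`, `q_t`, `ccf`, `prob_ge_095`, `clonality`.
#' @export
snv_clonality <- function(mutations, purity, segments = NULL,
                          min_purity = 0.20, exclude_samples = NULL,
                          grid_size = 100) {
  if (!is.null(exclude_samples)) {
    mutations <- filter(mutations, !.data$sample_id %in% exclude_samples)
  }
  check_purity_coverage(mutations, purity)
  purity <- exclude_low_purity(purity, min_purity)
  calls <- inner_join(mutations, select(purity, "sample_id", "purity"),
                      by = "sample_id")
  q_t <- lookup_q_t(calls, segments)
  if (any(q_t == 0)) {
    warn(sprintf("%d SNV(s) at homozygously deleted sites skipped", sum(q_t == 0)))
    calls <- calls[q_t > 0, , drop = FALSE]
    q_t <- q_t[q_t > 0]
  }
  vaf <- calls$tumor_alt_count / calls$tumor_depth
  m <- estimate_multiplicity(vaf, calls$purity, q_t)
  stats <- ccf_posterior_stats(calls$tumor_alt_count, calls$tumor_depth,
                               calls$purity, q_t, m, grid_size)
  calls %>%
    mutate(vaf = vaf, multiplicity = m, q_t = q_t,
           ccf = stats$ccf, prob_ge_095 = stats$prob_ge_095,
           clonality = call_clonality(stats$prob_ge_095))
}

#' Require purity entries for all mutated samples
#'
#' @param mutations Mutation records.
#' @param purity Purity table.
#' @return Invisibly `TRUE`; errors naming the offending samples otherwise.
#' @export
check_purity_coverage <- function(mutations, purity) {
  missing <- setdiff(unique(mutations$sample_id), purity$sample_id)
  if (length(missing) > 0) {
    abort(sprintf("sample(s) with mutations but no purity entry: %s",
                  paste(missing, collapse = ", ")))
  }
  invisible(TRUE)
}

#' Drop genes with multiple non-silent SNVs in the same patient
#'
#' When a gene harbors two or more non-silent SNVs in one patient, all SNVs of
#' that gene in that patient are excluded from gene-level clonality analysis
#' (their per-gene CCF would be ambiguous). Silent SNVs do not trigger the
#' exclusion.
#'
#' @param calls Clonality calls annotated with `gene` and `effect`.
#' @return The calls with multi-hit (sample, gene) pairs removed.
#' @export
exclude_multihit_genes <- function(calls) {
  multi <- calls %>%
    filter(.data$effect == "non_silent") %>%
    count(.data$sample_id, .data$gene) %>%
    filter(.data$n >= 2)
  anti_join(calls, multi, by = c("sample_id", "gene"))
}
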
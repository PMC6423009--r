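# Arm-level SCNA events: direction, clonality and CCF from per-segment calls.

#' Classify a segment as amplified, deleted or neutral
#'
#' A segment is amplified when its total copy number exceeds the rounded
#' sample ploidy, deleted when below, neutral otherwise.
#'
#' @param total_copy_number Integer total copy number (vectorized).
#' @param ploidy Sample average ploidy.
#' @return Character vector in `c("amp", "del", "neutral")`.
#' @examples
#' classify_segment_direction(c(3, 1, 2), 2.1)
#' @export
classify_segment_direction <- function(total_copy_number, ploidy) {
  base <- round(ploidy)
  dplyr::case_when(
    total_copy_number > base ~ "amp",
    total_copy_number < base ~ "del",
    TRUE ~ "neutral"
  )
}

# Point-threshold segment clonality: the same >= 0.95 rule applied to the
# annotated segment CCF when no posterior is available.
segment_clonality <- function(segment_ccf, cutoff = 0.95) {
  if_else(segment_ccf >= cutoff, "clonal", "subclonal")
}

#' Median CCF of the segments backing an arm-level event
#'
#' @param ccfs Numeric vector of contributing segment CCFs (non-empty).
#' @return The median; for an even count, the midpoint of the two central
#'   values.
#' @export
arm_ccf <- function(ccfs) {
  ccfs <- ccfs[!is.na(ccfs)]
  if (length(ccfs) == 0) abort("no contributing segment CCFs")
  median(ccfs)
}

#' Aggregate one sample's segments over one chromosome arm
#'
#' Intersects the segment spans with the arm span, accumulates the clonal and
#' subclonal length fractions of segments altered in `direction`, and applies
#' the majority rule: the arm event is clonal (subclonal) when the clonal
#' (subclonal) cumulative length fraction exceeds 0.5, `"none"` otherwise.
#' The event CCF is the median CCF of the segments in the winning state.
#'
#' @param segments Segment tibble for one sample (columns as in
#'   [read_segments()]).
#' @param arm One-row arm definition (`arm_id, chromosome, start, end`).
#' @param direction `"amp"` or `"del"`.
#' @param ploidy Sample ploidy used to classify segment direction.
#' @return One-row tibble (`arm_id, direction, clonality, ccf,
#'   clonal_length_fraction, subclonal_length_fraction, altered_fraction`), or
#'   a zero-row tibble when no altered segment overlaps the arm.
#' @export
aggregate_arm <- function(segments, arm, direction, ploidy = 2) {
  stopifnot(direction %in% c("amp", "del"), nrow(arm) == 1)
  seg <- segments %>%
    filter(.data$chromosome == arm$chromosome,
           .data$end >= arm$start, .data$start <= arm$end) %>%
    mutate(
      overlap = pmin(.data$end, arm$end) - pmax(.data$start, arm$start) + 1,
      dir = classify_segment_direction(.data$total_copy_number, ploidy)
    ) %>%
    filter(.data$dir == direction)
  empty <- tibble(arm_id = character(), direction = character(),
                  clonality = character(), ccf = numeric(),
                  clonal_length_fraction = numeric(),
                  subclonal_length_fraction = numeric(),
                  altered_fraction = numeric())
  if (nrow(seg) == 0) return(empty)
  arm_len <- arm$end - arm$start + 1
  seg$state <- segment_clonality(seg$segment_ccf)
  clonal_frac <- sum(seg$overlap[seg$state %in% "clonal"]) / arm_len
  subclonal_frac <- sum(seg$overlap[seg$state %in% "subclonal"]) / arm_len
  clonality <- if (clonal_frac > 0.5) "clonal"
  else if (subclonal_frac > 0.5) "subclonal"
  else "none"
  ccf <- if (clonality == "none") NA_real_
  else arm_ccf(seg$segment_ccf[seg$state %in% clonality])
  tibble(arm_id = arm$arm_id, direction = direction, clonality = clonality,
         ccf = ccf, clonal_length_fraction = clonal_frac,
         subclonal_length_fraction = subclonal_frac,
         altered_fraction = clonal_frac + subclonal_frac)
}

#' Arm-level SCNA events for a cohort
#'
#' For every sample and arm, aggregates amplified and deleted segments
#' separately ([aggregate_arm()]); when both directions alter the same arm in
#' one sample, the direction with the larger altered length fraction is
#' reported. Arms without any altered overlapping segment yield no row.
#'
#' @param segments Cohort segment table.
#' @param purity Purity/ploidy table (ploidy classifies segment direction).
#' @param arms Arm definition table.
#' @return Tibble with one row per (sample, arm) altered event: `sample_id,
#'   arm_id, event_id` (e.g. `"del(3p)"`), `direction, clonality, ccf`, and
#'   the length fractions.
#' @export
arm_events <- function(segments, purity, arms) {
  ploidy <- setNames(purity$ploidy, purity$sample_id)
  samples <- intersect(unique(segments$sample_id), purity$sample_id)
  res <- purrr::map_dfr(samples, function(s) {
    seg_s <- filter(segments, .data$sample_id == s)
    purrr::map_dfr(seq_len(nrow(arms)), function(i) {
      arm <- arms[i, ]
      both <- bind_rows(
        aggregate_arm(seg_s, arm, "amp", ploidy[[s]]),
        aggregate_arm(seg_s, arm, "del", ploidy[[s]])
      )
      if (nrow(both) == 0) return(both)
      both <- arrange(both, desc(.data$altered_fraction))
      both[1, ] %>% mutate(sample_id = s, .before = 1)
    })
  })
  if (nrow(res) == 0) {
    return(tibble(sample_id = character(), arm_id = character(),
                  event_id = character(), direction = character(),
                  clonality = character(), ccf = numeric(),
                  clonal_length_fraction = numeric(),
                  subclonal_length_fraction = numeric(),
                  altered_fraction = numeric()))
  }
  res %>%
    mutate(event_id = paste0(.data$direction, "(", .data$arm_id, ")"),
           .after = "arm_id") %>%
    dplyr::relocate("sample_id")
}

#' Collapse same-direction events on both arms into whole-chromosome labels
#'
#' When both arms of a chromosome carry an event with the same direction and
#' clonality in a sample, the two rows are merged into a single
#' whole-chromosome event (e.g. `del(9)`), with the median of the two CCFs.
#' Other events keep their arm labels.
#'
#' @param events Arm-event tibble from [arm_events()].
#' @param arms Arm definition table (to map arms to chromosomes).
#' @return Event tibble with chromosome-level labels where applicable.
#' @export
collapse_chromosome_events <- function(events, arms) {
  chrom_of <- setNames(arms$chromosome, arms$arm_id)
  events$chromosome <- chrom_of[events$arm_id]
  grouped <- events %>%
    filter(.data$clonality != "none") %>%
    group_by(.data$sample_id, .data$chromosome, .data$direction, .data$clonality) %>%
    summarise(n_arms = n(), ccf = median(.data$ccf),
              clonal_length_fraction = mean(.data$clonal_length_fraction),
              subclonal_length_fraction = mean(.data$subclonal_length_fraction),
              altered_fraction = mean(.data$altered_fraction),
              arm_id = paste(sort(.data$arm_id), collapse = "+"),
              .groups = "drop")
  whole <- grouped %>%
    filter(.data$n_arms >= 2) %>%
    mutate(event_id = paste0(.data$direction, "(", .data$chromosome, ")"))
  singles <- events %>%
    anti_join(select(whole, "sample_id", "chromosome", "direction"),
              by = c("sample_id", "chromosome", "direction")) %>%
    select(-"chromosome")
  bind_rows(singles, select(whole, -"n_arms", -"chromosome")) %>%
    arrange(.data$sample_id, .data$event_id)
}

#' Frequency filter for genes and arm-level events
#'
#' Keeps genes non-silently mutated in at least `min_gene_freq` of samples
#' (default 3%) and arm-level events (arm + direction) altered in at least
#' `min_arm_freq` of samples (default 10%).
#'
#' @param gene_calls Per-SNV clonality calls (after multi-hit exclusion).
#' @param arm_calls Arm-event tibble from [arm_events()]; rows with clonality
#'   `"none"` do not count as altered.
#' @param n_samples Cohort size used as the frequency denominator.
#' @param min_gene_freq,min_arm_freq Frequency cutoffs (inclusive).
#' @return Tibble of retained events: `event_id, kind` (`"gene"` or `"arm"`),
#'   `n_altered, frequency`.
#' @export
frequency_filter <- function(gene_calls, arm_calls, n_samples,
                             min_gene_freq = 0.03, min_arm_freq = 0.10) {
  if (n_samples <= 0) abort("n_samples must be positive")
  genes <- gene_calls %>%
    filter(.data$effect == "non_silent") %>%
    distinct(.data$sample_id, .data$gene) %>%
    count(.data$gene, name = "n_altered") %>%
    mutate(frequency = .data$n_altered / n_samples) %>%
    filter(.data$frequency >= min_gene_freq) %>%
    mutate(event_id = .data$gene, kind = "gene") %>%
    select("event_id", "kind", "n_altered", "frequency")
  arms <- arm_calls %>%
    filter(.data$clonality %in% c("clonal", "subclonal")) %>%
    distinct(.data$sample_id, .data$event_id) %>%
    count(.data$event_id, name = "n_altered") %>%
    mutate(frequency = .data$n_altered / n_samples) %>%
    filter(.data$frequency >= min_arm_freq) %>%
    mutate(kind = "arm") %>%
    select("event_id", "kind", "n_altered", "frequency")
  bind_rows(genes, arms) %>% arrange(desc(.data$frequency))
}
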
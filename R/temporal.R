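# Temporal ordering of driver acquisitions from within-patient
# clonal/subclonal co-occurrence.

#' Build the directed temporal graph
#'
#' For every sample, a directed edge X -> Y is drawn for every ordered pair of
#' frequent events with X clonal and Y subclonal in that sample (the clonal
#' event is taken to have been acquired earlier). A sample carrying c clonal
#' and s subclonal events contributes exactly c*s edges.
#'
#' @param calls One clonality call per (sample, event): columns `sample_id,
#'   event_id, clonality` restricted to the frequency-filtered events.
#'   Duplicate (sample, event) pairs are an error.
#' @return Object of class `"temporal_graph"`: `edges` (one row per edge with
#'   `from, to, sample_id`), `pair_counts` (`from, to, n`), `nodes`, and
#'   per-node `degrees` (`event_id, out_edges, in_edges`).
#' @export
build_temporal_graph <- function(calls) {
  dup <- calls %>% count(.data$sample_id, .data$event_id) %>% filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(sprintf("duplicate (sample, event) call(s), e.g. %s / %s; resolve upstream",
                  dup$sample_id[1], dup$event_id[1]))
  }
  nodes <- sort(unique(calls$event_id))
  edges <- calls %>%
    filter(.data$clonality %in% c("clonal", "subclonal")) %>%
    group_by(.data$sample_id) %>%
    dplyr::group_modify(function(df, key) {
      cl <- df$event_id[df$clonality == "clonal"]
      su <- df$event_id[df$clonality == "subclonal"]
      if (length(cl) == 0 || length(su) == 0) {
        return(tibble(from = character(), to = character()))
      }
      tidyr::expand_grid(from = cl, to = su)
    }) %>%
    ungroup() %>%
    select("from", "to", "sample_id")
  pair_counts <- edges %>% count(.data$from, .data$to, name = "n")
  degrees <- tibble(event_id = nodes) %>%
    left_join(count(edges, .data$from, name = "out_edges"),
              by = c(event_id = "from")) %>%
    left_join(count(edges, .data$to, name = "in_edges"),
              by = c(event_id = "to")) %>%
    mutate(out_edges = tidyr::replace_na(.data$out_edges, 0L),
           in_edges = tidyr::replace_na(.data$in_edges, 0L))
  structure(list(edges = edges, pair_counts = pair_counts,
                 nodes = nodes, degrees = degrees),
            class = "temporal_graph")
}

#' @export
print.temporal_graph <- function(x, ...) {
  cat(sprintf("temporal_graph: %d nodes, %d edges (%d distinct ordered pairs)\n",
              length(x$nodes), nrow(x$edges), nrow(x$pair_counts)))
  invisible(x)
}

#' Test the direction of one event pair
#'
#' Pairs connected by fewer than `min_edges` edges (both directions pooled)
#' are left untested. Otherwise the edge counts are compared by a two-sided
#' exact binomial test against 0.5, and the majority direction is reported
#' when significant.
#'
#' @param n_xy,n_yx Edge counts X -> Y and Y -> X.
#' @param min_edges Minimum total edges for a pair to be tested (default 5).
#' @param alpha Significance level for calling a direction.
#' @return One-row tibble: `n_xy, n_yx, tested, p_value, direction`
#'   (`"forward"`, `"reverse"` or `NA`).
#' @export
test_pair <- function(n_xy, n_yx, min_edges = 5, alpha = 0.05) {
  n <- n_xy + n_yx
  if (n < min_edges) {
    return(tibble(n_xy = n_xy, n_yx = n_yx, tested = FALSE,
                  p_value = NA_real_, direction = NA_character_))
  }
  p <- binom.test(n_xy, n, p = 0.5, alternative = "two.sided")$p.value
  direction <- if (p <= alpha && n_xy != n_yx) {
    if (n_xy > n_yx) "forward" else "reverse"
  } else NA_character_
  tibble(n_xy = n_xy, n_yx = n_yx, tested = TRUE, p_value = p,
         direction = direction)
}

#' Directional tests for all event pairs of a temporal graph
#'
#' Symmetrizes the pair counts (each unordered pair appears once, with
#' `from`/`to` oriented along the larger count), applies [test_pair()], and
#' checks the significant-direction subgraph for cycles (reported, not
#' suppressed: contradictory orderings can be real).
#'
#' @param graph A `"temporal_graph"`.
#' @param min_edges,alpha Passed to [test_pair()].
#' @return Tibble of unordered pairs with counts, test results, and attribute
#'   `"cycles"` (character vector describing cycles among significant
#'   directions, empty when the subgraph is acyclic).
#' @export
test_pairs <- function(graph, min_edges = 5, alpha = 0.05) {
  pc <- graph$pair_counts
  if (nrow(pc) == 0) {
    res <- tibble(from = character(), to = character(), n_xy = integer(),
                  n_yx = integer(), tested = logical(), p_value = numeric(),
                  direction = character())
    attr(res, "cycles") <- character()
    return(res)
  }
  key <- purrr::map2_chr(pc$from, pc$to, ~ paste(sort(c(.x, .y)), collapse = "\r"))
  res <- purrr::map_dfr(unique(key), function(kk) {
    ab <- strsplit(kk, "\r", fixed = TRUE)[[1]]
    n_ab <- pc$n[pc$from == ab[1] & pc$to == ab[2]]
    n_ba <- pc$n[pc$from == ab[2] & pc$to == ab[1]]
    n_ab <- if (length(n_ab)) n_ab else 0L
    n_ba <- if (length(n_ba)) n_ba else 0L
    if (n_ab >= n_ba) {
      bind_cols(tibble(from = ab[1], to = ab[2]), test_pair(n_ab, n_ba, min_edges, alpha))
    } else {
      bind_cols(tibble(from = ab[2], to = ab[1]), test_pair(n_ba, n_ab, min_edges, alpha))
    }
  })
  sig <- filter(res, !is.na(.data$direction))
  cycles <- character()
  if (nrow(sig) > 0) {
    g <- igraph::graph_from_data_frame(select(sig, "from", "to"), directed = TRUE)
    if (!igraph::is_dag(g)) {
      comp <- igraph::components(g, mode = "strong")
      cyc <- which(comp$csize > 1)
      cycles <- vapply(cyc, function(ci) {
        paste(names(comp$membership)[comp$membership == ci], collapse = " -> ")
      }, character(1))
    }
  }
  attr(res, "cycles") <- cycles
  res
}

#' Classify events as early, intermediary or late
#'
#' Per node, the out-going and in-coming edge counts are compared with a
#' two-sided exact binomial test against 0.5; p-values are FDR-adjusted across
#' nodes. An event is `early` when out-edges significantly exceed in-edges,
#' `late` in the opposite case, `intermediary` otherwise (including nodes with
#' no edges, whose p-value is `NA`).
#'
#' @param graph A `"temporal_graph"`.
#' @param alpha Significance level on the FDR-adjusted p-values.
#' @return Tibble: `event_id, out_edges, in_edges, p_value, fdr, class`.
#' @export
classify_timing <- function(graph, alpha = 0.05) {
  deg <- graph$degrees
  p <- purrr::map2_dbl(deg$out_edges, deg$in_edges, function(o, i) {
    if (o + i == 0) return(NA_real_)
    binom.test(o, o + i, p = 0.5, alternative = "two.sided")$p.value
  })
  fdr <- rep(NA_real_, length(p))
  fdr[!is.na(p)] <- fdr_adjust(p[!is.na(p)])
  deg %>%
    mutate(p_value = p, fdr = fdr,
           class = dplyr::case_when(
             is.na(fdr) ~ "intermediary",
             fdr <= alpha & .data$out_edges > .data$in_edges ~ "early",
             fdr <= alpha & .data$in_edges > .data$out_edges ~ "late",
             TRUE ~ "intermediary"
           ))
}

#' Rank events by median CCF
#'
#' Orders events by descending median CCF across carriers and attaches a
#' bootstrap percentile confidence interval for the median.
#'
#' @param calls Clonality calls with `event_id` and `ccf`.
#' @param n_boot Bootstrap resamples (default 1,000).
#' @param conf Confidence level (default 0.95).
#' @param seed Optional integer seed.
#' @return Tibble: `event_id, n, median_ccf, ci_low, ci_high`, sorted by
#'   descending median.
#' @export
rank_by_ccf <- function(calls, n_boot = 1000, conf = 0.95, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  a <- (1 - conf) / 2
  calls %>%
    filter(!is.na(.data$ccf)) %>%
    group_by(.data$event_id) %>%
    summarise(
      n = n(),
      median_ccf = median(.data$ccf),
      ci = list({
        boots <- vapply(seq_len(n_boot), function(b) {
          median(sample(.data$ccf, length(.data$ccf), replace = TRUE))
        }, numeric(1))
        quantile(boots, c(a, 1 - a), names = FALSE)
      }),
      .groups = "drop"
    ) %>%
    mutate(ci_low = purrr::map_dbl(.data$ci, 1),
           ci_high = purrr::map_dbl(.data$ci, 2)) %>%
    select(-"ci") %>%
    arrange(desc(.data$median_ccf))
}

#' Export a temporal graph in DOT format
#'
#' @param graph A `"temporal_graph"`.
#' @param path Output file path.
#' @param min_edges Only pairs with at least this many edges are written.
#' @return The path, invisibly.
#' @export
write_temporal_dot <- function(graph, path, min_edges = 5) {
  pc <- filter(graph$pair_counts, .data$n >= min_edges)
  lines <- c("digraph temporal {",
             sprintf("  \"%s\" -> \"%s\" [label=%d];", pc$from, pc$to, pc$n),
             "}")
  readr::write_lines(lines, path)
  invisible(path)
}
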
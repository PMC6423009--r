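# ggplot2 displays for the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot signature profiles over the 96 channels
#'
#' @param x A `"signature_set"` or a 96 x k signature matrix.
#' @return A ggplot: one facet per signature, bars per channel colored by
#'   substitution class.
#' @export
plot_signatures <- function(x) {
  df <- if (inherits(x, "signature_set")) tidy(x) else {
    as_tibble(as.matrix(x), rownames = "channel") %>%
      tidyr::pivot_longer(-"channel", names_to = "signature", values_to = "weight")
  }
  df$substitution <- sub("^.\\[(.>.)\\].$", "\\1", df$channel)
  df$channel <- factor(df$channel, levels = sig_channels())
  ggplot2::ggplot(df, ggplot2::aes(x = .data$channel, y = .data$weight,
                                   fill = .data$substitution)) +
    ggplot2::geom_col(width = 0.8) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$signature)) +
    ggplot2::theme_minimal(base_size = 9) +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   axis.ticks.x = ggplot2::element_blank(),
                   panel.grid.major.x = ggplot2::element_blank()) +
    ggplot2::labs(x = "trinucleotide channel", y = "weight", fill = NULL)
}

#' Plot the CCF ranking of events
#'
#' @param ranking Output of [rank_by_ccf()].
#' @return A ggplot of medians with bootstrap confidence intervals.
#' @export
plot_ccf_ranking <- function(ranking) {
  ranking$event_id <- factor(ranking$event_id, levels = rev(ranking$event_id))
  ggplot2::ggplot(ranking, ggplot2::aes(x = .data$median_ccf, y = .data$event_id)) +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_low, xmax = .data$ci_high),
                            height = 0.25, color = "grey50") +
    ggplot2::geom_point(color = "firebrick", size = 2) +
    ggplot2::xlim(0, 1) +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = "median CCF (95% bootstrap CI)", y = NULL)
}

#' Heatmap of a consensus matrix
#'
#' @param x An `"nmf_subtype"`.
#' @return A ggplot tile heatmap with samples ordered by cluster.
#' @export
plot_consensus <- function(x) {
  ord <- order(x$assignments$cluster)
  ids <- x$assignments$sample_id[ord]
  df <- as_tibble(x$consensus[ord, ord], rownames = "sample_a") %>%
    tidyr::pivot_longer(-"sample_a", names_to = "sample_b",
                        values_to = "consensus")
  df$sample_a <- factor(df$sample_a, levels = ids)
  df$sample_b <- factor(df$sample_b, levels = ids)
  ggplot2::ggplot(df, ggplot2::aes(.data$sample_a, .data$sample_b,
                                   fill = .data$consensus)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "navy", limits = c(0, 1)) +
    ggplot2::theme_void() +
    ggplot2::labs(fill = "consensus")
}

#' Kaplan-Meier curves
#'
#' @param object A `"km_result"`.
#' @param ... Unused.
#' @return A ggplot of step survival curves per group.
#' @export
autoplot.km_result <- function(object, ...) {
  df <- tidy(object)
  df <- bind_rows(
    df %>% group_by(.data$group) %>%
      summarise(time = 0, estimate = 1, .groups = "drop"),
    select(df, "group", "time", "estimate")
  )
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$estimate,
                                        color = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = "time (months)", y = "survival probability", color = NULL)
  if (!is.na(object$p_value)) {
    p <- p + ggplot2::annotate(
      "text", x = 0, y = 0.05, hjust = 0,
      label = sprintf("log-rank p = %.2g", object$p_value))
  }
  p
}

#' Temporal graph layout
#'
#' Draws the significant-direction pairs of a temporal graph, nodes arranged
#' on timing rows (early on top) when a timing classification is supplied.
#'
#' @param graph A `"temporal_graph"`.
#' @param pairs Output of [test_pairs()]; only rows with a significant
#'   direction are drawn.
#' @param timing Optional output of [classify_timing()] for vertical placement.
#' @return A ggplot.
#' @export
plot_temporal_graph <- function(graph, pairs, timing = NULL) {
  sig <- filter(pairs, !is.na(.data$direction))
  nodes <- tibble(event_id = graph$nodes)
  if (!is.null(timing)) {
    nodes <- left_join(nodes, select(timing, "event_id", "class"), by = "event_id")
    nodes$y <- c(early = 3, intermediary = 2, late = 1)[nodes$class]
  } else {
    nodes$y <- 2
  }
  nodes <- nodes %>%
    group_by(.data$y) %>%
    mutate(x = seq_len(n()) / (n() + 1)) %>%
    ungroup()
  seg <- sig %>%
    left_join(select(nodes, "event_id", from_x = "x", from_y = "y"),
              by = c(from = "event_id")) %>%
    left_join(select(nodes, "event_id", to_x = "x", to_y = "y"),
              by = c(to = "event_id"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$from_x, y = .data$from_y,
                   xend = .data$to_x, yend = .data$to_y),
      arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm")),
      color = "grey60", alpha = 0.7) +
    ggplot2::geom_label(data = nodes,
                        ggplot2::aes(.data$x, .data$y, label = .data$event_id),
                        size = 3) +
    ggplot2::theme_void()
}
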
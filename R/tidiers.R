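# broom-style tidiers for the fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a signature set into long format
#'
#' @param x A `"signature_set"`.
#' @param matrix Which component to tidy: `"signatures"` (channel weights) or
#'   `"exposures"` (per-sample attributions).
#' @param ... Unused.
#' @return A long tibble (`channel, signature, weight` or
#'   `signature, sample_id, exposure`).
#' @export
tidy.signature_set <- function(x, matrix = c("signatures", "exposures"), ...) {
  matrix <- match.arg(matrix)
  if (matrix == "signatures") {
    as_tibble(x$signatures, rownames = "channel") %>%
      tidyr::pivot_longer(-"channel", names_to = "signature",
                          values_to = "weight")
  } else {
    as_tibble(x$exposures, rownames = "signature") %>%
      tidyr::pivot_longer(-"signature", names_to = "sample_id",
                          values_to = "exposure")
  }
}

#' One-row summary of a signature set
#' @param x A `"signature_set"`.
#' @param ... Unused.
#' @return Tibble with `k`, `n_samples`, `reconstruction_error`,
#'   `relative_error`, `n_iterations`.
#' @export
glance.signature_set <- function(x, ...) {
  tibble(k = x$k, n_samples = ncol(x$exposures),
         reconstruction_error = x$reconstruction_error,
         relative_error = x$relative_error,
         n_iterations = length(x$objective))
}

#' Tidy subtype assignments
#' @param x An `"nmf_subtype"`.
#' @param ... Unused.
#' @return The assignments tibble (`sample_id, cluster`, membership weights).
#' @export
tidy.nmf_subtype <- function(x, ...) {
  x$assignments
}

#' One-row summary of a subtyping fit
#' @param x An `"nmf_subtype"`.
#' @param ... Unused.
#' @return Tibble with `k`, `n_samples`, `cophenetic`, `divergence`.
#' @export
glance.nmf_subtype <- function(x, ...) {
  tibble(k = x$k, n_samples = nrow(x$assignments),
         cophenetic = x$cophenetic, divergence = x$divergence)
}

#' Tidy a temporal graph into its pair counts
#' @param x A `"temporal_graph"`.
#' @param ... Unused.
#' @return Tibble of directed pair counts (`from, to, n`).
#' @export
tidy.temporal_graph <- function(x, ...) {
  x$pair_counts
}

#' One-row summary of a temporal graph
#' @param x A `"temporal_graph"`.
#' @param ... Unused.
#' @return Tibble with `n_nodes`, `n_edges`, `n_pairs`.
#' @export
glance.temporal_graph <- function(x, ...) {
  tibble(n_nodes = length(x$nodes), n_edges = nrow(x$edges),
         n_pairs = nrow(x$pair_counts))
}

#' Tidy Kaplan-Meier curves into plot-ready coordinates
#' @param x A `"km_result"`.
#' @param ... Unused.
#' @return Tibble with `group, time, n_risk, n_event, estimate, std_error`.
#' @export
tidy.km_result <- function(x, ...) {
  fit <- x$fit
  strata <- if (is.null(fit$strata)) {
    rep("all", length(fit$time))
  } else {
    rep(sub("^group=", "", names(fit$strata)), fit$strata)
  }
  tibble(group = strata, time = fit$time, n_risk = fit$n.risk,
         n_event = fit$n.event, estimate = fit$surv, std_error = fit$std.err)
}

#' One-row summary of a log-rank comparison
#' @param x A `"km_result"`.
#' @param ... Unused.
#' @return Tibble with `n_groups, n, chisq, p_value`.
#' @export
glance.km_result <- function(x, ...) {
  tibble(n_groups = x$n_groups, n = nrow(x$data),
         chisq = x$chisq, p_value = x$p_value)
}
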
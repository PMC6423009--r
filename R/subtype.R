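# Molecular subtyping by consensus NMF of the event-by-sample CCF matrix.
#
# Factorization follows the Brunet multiplicative-update scheme for the
# Kullback-Leibler objective (the classical default of consensus-NMF
# subtyping): many runs from random initializations, per-run hard assignment
# by the dominant basis component, a consensus matrix of co-clustering
# frequencies, and a final hierarchical clustering of the consensus matrix.

#' Build the event-by-sample CCF matrix
#'
#' One row per selected event, one column per sample; the entry is the event's
#' CCF in that sample and 0 when the event is absent. Samples without any
#' selected event are retained as zero columns.
#'
#' @param calls Clonality calls with `event_id, sample_id, ccf`.
#' @param events Character vector of selected events (the univariate-screen
#'   survivors).
#' @param samples Optional character vector fixing the sample set (defaults to
#'   the samples present in `calls`).
#' @return Numeric matrix (events x samples) with entries in `[0, 1]`.
#' @export
build_ccf_matrix <- function(calls, events, samples = NULL) {
  samples <- samples %||% sort(unique(calls$sample_id))
  sub <- calls %>%
    filter(.data$event_id %in% events, .data$sample_id %in% samples) %>%
    group_by(.data$event_id, .data$sample_id) %>%
    summarise(ccf = max(.data$ccf, na.rm = TRUE), .groups = "drop")
  if (nrow(sub) > 0 && (min(sub$ccf) < 0 || max(sub$ccf) > 1 + 1e-9)) {
    abort("CCF entries must lie in [0, 1]")
  }
  m <- matrix(0, nrow = length(events), ncol = length(samples),
              dimnames = list(events, samples))
  if (nrow(sub) > 0) {
    m[cbind(match(sub$event_id, events), match(sub$sample_id, samples))] <- sub$ccf
  }
  m
}

# One Brunet KL-NMF run. V (f x n) ~ W (f x k) H (k x n).
kl_nmf <- function(V, k, max_iter = 1000, tol = 1e-6) {
  f <- nrow(V); n <- ncol(V)
  eps <- .Machine$double.eps
  W <- matrix(runif(f * k, 0.1, 1), f, k)
  H <- matrix(runif(k * n, 0.1, 1), k, n)
  d_prev <- Inf
  for (it in seq_len(max_iter)) {
    WH <- W %*% H + eps
    H <- H * (crossprod(W, V / WH)) / pmax(colSums(W), eps)
    WH <- W %*% H + eps
    W <- W * (tcrossprod(V / WH, H)) / matrix(pmax(rowSums(H), eps), f, k, byrow = TRUE)
    if (it %% 10 == 0 || it == max_iter) {
      WH <- W %*% H + eps
      d <- sum(V * log((V + eps) / WH) - V + WH)
      if (is.finite(d_prev) && abs(d_prev - d) < tol * max(abs(d_prev), 1)) break
      d_prev <- d
    }
  }
  list(W = W, H = H, divergence = d_prev)
}

# Hard assignment by dominant basis component; ties -> lowest index.
dominant_component <- function(H) {
  apply(H, 2, which.max)
}

#' Consensus NMF subtyping of samples
#'
#' Runs `n_runs` KL-NMF factorizations from random initializations, assigns
#' each sample to its dominant basis component per run, accumulates the
#' consensus matrix (fraction of runs in which two samples co-cluster), and
#' derives the final k-group assignment by average-linkage hierarchical
#' clustering of the consensus matrix. Cluster labels are letters ordered by
#' decreasing cluster size (ties broken by first sample index).
#'
#' @param ccf_matrix Nonnegative events x samples matrix
#'   (see [build_ccf_matrix()]).
#' @param k Number of subgroups (>= 2, <= number of samples).
#' @param n_runs NMF runs entering the consensus (default 50).
#' @param max_iter,tol Per-run convergence controls.
#' @param seed Optional integer seed.
#' @return Object of class `"nmf_subtype"`: `assignments` (tibble `sample_id,
#'   cluster`, plus membership weights from the best run), `consensus`
#'   (samples x samples), `k`, `cophenetic` (cophenetic correlation of the
#'   consensus clustering), and the best run's `W`, `H`.
#' @export
nmf_subtype <- function(ccf_matrix, k, n_runs = 50, max_iter = 1000,
                        tol = 1e-6, seed = NULL) {
  V <- as.matrix(ccf_matrix)
  if (any(V < 0)) abort("CCF matrix must be nonnegative")
  n <- ncol(V)
  if (k < 2) abort("k must be >= 2")
  if (k > n) abort("k exceeds the number of samples")
  if (!is.null(seed)) set.seed(seed)
  # zero rows/columns break the multiplicative updates; add a tiny floor
  V <- V + 1e-9

  co <- matrix(0, n, n)
  best <- NULL
  for (r in seq_len(n_runs)) {
    fit <- kl_nmf(V, k, max_iter = max_iter, tol = tol)
    cl <- dominant_component(fit$H)
    co <- co + outer(cl, cl, `==`)
    if (is.null(best) || fit$divergence < best$divergence) best <- fit
  }
  consensus <- co / n_runs
  dimnames(consensus) <- list(colnames(V), colnames(V))

  hc <- hclust(as.dist(1 - consensus), method = "average")
  groups <- cutree(hc, k = k)
  coph <- cor(as.dist(1 - consensus), cophenetic(hc))

  # deterministic letter labels: by decreasing size, then first appearance
  sizes <- table(groups)
  ord <- order(-as.integer(sizes), vapply(names(sizes), function(g) {
    which(groups == as.integer(g))[1]
  }, numeric(1)))
  relabel <- setNames(LETTERS[seq_len(k)], names(sizes)[ord])
  cluster <- unname(relabel[as.character(groups)])

  Hbest <- best$H
  w <- sweep(Hbest, 2, pmax(colSums(Hbest), .Machine$double.eps), "/")
  assignments <- tibble(
    sample_id = colnames(V) %||% as.character(seq_len(n)),
    cluster = cluster
  )
  memb <- as_tibble(t(w), .name_repair = ~ paste0("w", seq_len(k)))
  assignments <- bind_cols(assignments, memb)

  structure(list(assignments = assignments, consensus = consensus, k = k,
                 cophenetic = coph, W = best$W, H = best$H,
                 divergence = best$divergence),
            class = "nmf_subtype")
}

#' @export
print.nmf_subtype <- function(x, ...) {
  cat(sprintf("nmf_subtype: k = %d, %d samples, cophenetic %.3f\n",
              x$k, nrow(x$assignments), x$cophenetic))
  print(table(x$assignments$cluster))
  invisible(x)
}

#' Select the number of subgroups by the cophenetic rule
#'
#' Computes the cophenetic correlation of the consensus clustering for each
#' candidate `k` and picks the smallest `k` whose successor shows the first
#' strict decrease (i.e. `cophenetic(k) > cophenetic(k + 1)`). If the
#' coefficient never decreases, the largest candidate is returned with a
#' warning.
#'
#' @param ccf_matrix Nonnegative events x samples matrix.
#' @param k_range Candidate subgroup numbers (default 2:6, length >= 2).
#' @param n_runs,max_iter,tol,seed Passed to [nmf_subtype()].
#' @return List with `chosen_k`, `report` (tibble `k, cophenetic`), and
#'   `fits` (the per-k `"nmf_subtype"` objects).
#' @export
select_rank <- function(ccf_matrix, k_range = 2:6, n_runs = 50,
                        max_iter = 1000, tol = 1e-6, seed = NULL) {
  k_range <- sort(unique(as.integer(k_range)))
  if (length(k_range) < 2) abort("k_range must contain at least two values")
  if (!is.null(seed)) set.seed(seed)
  fits <- lapply(k_range, function(k) {
    nmf_subtype(ccf_matrix, k, n_runs = n_runs, max_iter = max_iter, tol = tol)
  })
  coph <- vapply(fits, `[[`, numeric(1), "cophenetic")
  report <- tibble(k = k_range, cophenetic = coph)
  list(chosen_k = choose_cophenetic_k(coph, k_range), report = report,
       fits = setNames(fits, paste0("k", k_range)))
}

# The cophenetic decision rule: smallest k whose successor first strictly
# decreases; max(k_range) with a warning when the coefficient never drops.
choose_cophenetic_k <- function(cophenetic, k_range) {
  dec <- which(diff(cophenetic) < 0)
  if (length(dec) == 0) {
    warn("cophenetic coefficient never decreases over k_range; returning max(k_range)")
    return(as.integer(k_range[length(k_range)]))
  }
  as.integer(k_range[dec[1]])
}
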
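# Mutational signature extraction on the 96 trinucleotide channels.
#
# Factorizes the channels-by-samples count matrix V ~ W H with W >= 0, H >= 0
# by alternating nonnegative least squares (column/row-wise HALS updates with
# projection), which keeps the Frobenius objective non-increasing at every
# iteration. Signature columns are normalized to sum to 1 with exposures
# rescaled compensatorily.

#' Build the 96-channel mutation count matrix
#'
#' Folds each SNV onto its pyrimidine-strand trinucleotide channel and counts
#' mutations per channel and sample. Mutations with ambiguous bases are
#' dropped with a warning (via [context_channel()]).
#'
#' @param mutations Mutation records with `ref_allele, alt_allele, context_5p,
#'   context_3p, sample_id`.
#' @param clonality Optional character vector aligned with `mutations`
#'   (`"clonal"`/`"subclonal"`); when given together with `stratum`, only that
#'   stratum is counted.
#' @param stratum One of `"all"`, `"clonal"`, `"subclonal"`.
#' @return Integer 96 x n_samples matrix with channel rownames, sample
#'   colnames, and the stratum in attribute `"stratum"`.
#' @export
build_context_matrix <- function(mutations, clonality = NULL, stratum = "all") {
  stopifnot(stratum %in% c("all", "clonal", "subclonal"))
  if (stratum != "all") {
    clonality <- clonality %||% mutations$clonality
    if (is.null(clonality)) abort("stratified counts need clonality labels")
    mutations <- mutations[clonality == stratum, , drop = FALSE]
  }
  channels <- sig_channels()
  samples <- sort(unique(mutations$sample_id))
  lab <- suppressWarnings(context_channel(mutations$ref_allele, mutations$alt_allele,
                                          mutations$context_5p, mutations$context_3p))
  n_bad <- sum(is.na(lab))
  if (n_bad > 0) warn(sprintf("%d mutation(s) without a valid channel dropped", n_bad))
  keep <- !is.na(lab)
  tab <- table(factor(lab[keep], levels = channels),
               factor(mutations$sample_id[keep], levels = samples))
  m <- matrix(as.integer(tab), nrow = 96, dimnames = list(channels, samples))
  attr(m, "stratum") <- stratum
  m
}

# One HALS fit of V (96 x n) into W (96 x k), H (k x n).
# Returns list(W, H, error, objective trace). Objective: ||V - WH||_F.
hals_nmf <- function(V, k, max_iter = 2000, tol = 1e-8) {
  m <- nrow(V); n <- ncol(V)
  eps <- 1e-12
  W <- matrix(runif(m * k), m, k)
  H <- matrix(runif(k * n), k, n)
  obj <- numeric(0)
  err_prev <- Inf
  for (it in seq_len(max_iter)) {
    # update W columns
    HHt <- tcrossprod(H)           # k x k
    VHt <- tcrossprod(V, H)        # m x k
    for (j in seq_len(k)) {
      denom <- HHt[j, j]
      if (denom < eps) denom <- eps
      W[, j] <- pmax(0, W[, j] + (VHt[, j] - W %*% HHt[, j]) / denom)
      if (all(W[, j] < eps)) W[which.max(VHt[, j]), j] <- eps
    }
    # update H rows
    WtW <- crossprod(W)            # k x k
    WtV <- crossprod(W, V)         # k x n
    for (j in seq_len(k)) {
      denom <- WtW[j, j]
      if (denom < eps) denom <- eps
      H[j, ] <- pmax(0, H[j, ] + (WtV[j, ] - WtW[j, ] %*% H) / denom)
    }
    err <- sqrt(sum((V - W %*% H)^2))
    obj <- c(obj, err)
    if (is.finite(err_prev) && (err_prev - err) < tol * max(err_prev, 1)) break
    err_prev <- err
  }
  list(W = W, H = H, error = obj[length(obj)], objective = obj)
}

#' Extract mutational signatures by alternating least-squares NMF
#'
#' Runs `n_restarts` factorizations from random uniform initializations and
#' keeps the one with the smallest reconstruction error. Signature columns are
#' normalized to sum to 1; exposures absorb the scale.
#'
#' @param counts 96 x n_samples context count matrix
#'   (see [build_context_matrix()]).
#' @param k Number of signatures (>= 1, at most `min(96, n_samples)`).
#' @param n_restarts Random restarts (default 50).
#' @param max_iter,tol Convergence controls for each fit.
#' @param seed Optional integer seed for reproducibility.
#' @return Object of class `"signature_set"`: `k`, `signatures` (96 x k,
#'   columns sum to 1), `exposures` (k x n), `reconstruction_error`
#'   (Frobenius), `relative_error`, and the per-iteration `objective` trace of
#'   the best run.
#' @export
extract_signatures <- function(counts, k, n_restarts = 50, max_iter = 2000,
                               tol = 1e-8, seed = NULL) {
  V <- as.matrix(counts)
  if (k < 1 || k > min(96, ncol(V))) abort("k must be in [1, min(96, n_samples)]")
  if (all(V == 0)) abort("count matrix has no nonzero entry")
  if (!is.null(seed)) set.seed(seed)
  if (k > qr(V)$rank) {
    warn("k exceeds the numerical rank of the count matrix; result flagged")
  }
  best <- NULL
  for (r in seq_len(n_restarts)) {
    fit <- hals_nmf(V, k, max_iter = max_iter, tol = tol)
    if (is.null(best) || fit$error < best$error) best <- fit
  }
  scale <- colSums(best$W)
  scale[scale == 0] <- 1
  W <- sweep(best$W, 2, scale, "/")
  H <- sweep(best$H, 1, scale, "*")
  sig_names <- paste0("S", seq_len(k))
  dimnames(W) <- list(rownames(V), sig_names)
  dimnames(H) <- list(sig_names, colnames(V))
  structure(
    list(k = k, signatures = W, exposures = H,
         reconstruction_error = best$error,
         relative_error = best$error / sqrt(sum(V^2)),
         objective = best$objective,
         rank_deficient = k > qr(V)$rank),
    class = "signature_set"
  )
}

#' @export
print.signature_set <- function(x, ...) {
  cat(sprintf("signature_set: k = %d, %d samples, relative error %.4g\n",
              x$k, ncol(x$exposures), x$relative_error))
  invisible(x)
}

# Bootstrap-resample a count matrix: each sample column is redrawn
# multinomially with its own total and channel proportions.
bootstrap_counts <- function(V) {
  out <- V
  for (j in seq_len(ncol(V))) {
    tot <- sum(V[, j])
    if (tot == 0) next
    out[, j] <- rmultinom(1, tot, V[, j] / tot)
  }
  out
}

#' Select the number of mutational processes
#'
#' Scores each candidate `k` by bootstrap reproducibility: the catalog is
#' refit on `n_boot` multinomial resamples of every sample's mutation counts,
#' each resample's signatures are matched one-to-one against the full-data
#' solution (the assignment maximizing the worst pairwise cosine), and the
#' stability of `k` is the mean across resamples of that worst matched
#' cosine. A spurious process (k above the true number) fails to reproduce
#' across resamples and drags the worst matched cosine down, while every k up
#' to the true number reproduces almost exactly. Walking up from the smallest
#' candidate, the chosen `k` is the largest one reached before stability
#' first falls below `stability_min` (argmax stability as fallback when even
#' the smallest candidate is unstable). Reconstruction error of the full-data
#' fit is reported alongside.
#'
#' @param counts 96 x n context count matrix.
#' @param k_range Candidate numbers of processes (default 1:6).
#' @param n_boot Bootstrap resamples per k (default 100).
#' @param n_restarts Random restarts for each bootstrap fit (the full-data
#'   fit uses `2 * n_restarts + 2`).
#' @param max_iter,tol Controls for each NMF fit (lighter defaults than
#'   [extract_signatures()] since many fits are run).
#' @param stability_min Minimum mean matched cosine for a k to be accepted.
#' @param seed Optional integer seed.
#' @return List with `best_k` and `report`, a tibble of per-k `stability`
#'   (mean worst matched cosine) and the full-data fit's `relative_error`.
#' @export
select_n_processes <- function(counts, k_range = 1:6, n_boot = 100,
                               n_restarts = 3, max_iter = 500, tol = 1e-6,
                               stability_min = 0.95, seed = NULL) {
  V <- as.matrix(counts)
  if (!is.null(seed)) set.seed(seed)
  k_range <- sort(unique(as.integer(k_range)))
  report <- purrr::map_dfr(k_range, function(k) {
    full <- extract_signatures(V, k, n_restarts = 2 * n_restarts + 2,
                               max_iter = max_iter, tol = tol)
    mc <- vapply(seq_len(n_boot), function(b) {
      fit <- extract_signatures(bootstrap_counts(V), k,
                                n_restarts = n_restarts,
                                max_iter = max_iter, tol = tol)
      matched_min_cosine(full$signatures, fit$signatures)
    }, numeric(1))
    tibble(k = k, stability = mean(mc), relative_error = full$relative_error)
  })
  # walk up from the smallest k; stop at the first k whose bootstrap
  # solutions stop reproducing (spurious stability can reappear at larger k)
  stable <- report$stability >= stability_min
  run <- cumprod(stable) == 1
  best_k <- if (any(run)) max(report$k[run])
  else report$k[which.max(report$stability)]
  list(best_k = as.integer(best_k), report = report)
}

# Best one-to-one matching of columns of A and B under the max-min cosine
# criterion; exact over permutations for k <= 7, greedy beyond.
matched_min_cosine <- function(A, B) {
  cs <- cosine_matrix(A, B)
  k <- ncol(A)
  if (k == 1) return(cs[1, 1])
  if (k <= 7) {
    perms <- permutations_of(k)
    return(max(apply(perms, 1, function(idx) min(cs[cbind(seq_len(k), idx)]))))
  }
  used <- logical(k)
  worst <- 1
  for (i in order(-apply(cs, 1, max))) {
    j <- which.max(ifelse(used, -Inf, cs[i, ]))
    used[j] <- TRUE
    worst <- min(worst, cs[i, j])
  }
  worst
}

permutations_of <- function(k) {
  if (k == 1) return(matrix(1, 1, 1))
  sub <- permutations_of(k - 1)
  do.call(rbind, lapply(seq_len(k), function(i) {
    cbind(i, ifelse(sub >= i, sub + 1, sub))
  }))
}

#' Match extracted signatures against a reference catalog
#'
#' Reports, for every extracted signature, the reference signature with the
#' highest cosine similarity, together with the Pearson correlation. No
#' assignment threshold is applied; `matched` flags cosine >= `cosine_min`
#' (default 0.80) for convenience.
#'
#' @param signature_set A `"signature_set"` or a 96 x k nonnegative matrix.
#' @param reference 96 x K reference matrix (rownames must equal
#'   [sig_channels()] in order; no silent reordering).
#' @param cosine_min Threshold for the `matched` flag.
#' @return Tibble: `signature, best_match, cosine, pearson, matched`.
#' @export
match_reference <- function(signature_set, reference, cosine_min = 0.80) {
  W <- if (inherits(signature_set, "signature_set")) signature_set$signatures
  else as.matrix(signature_set)
  reference <- as.matrix(reference)
  if (!identical(rownames(reference), sig_channels()) ||
      !identical(rownames(W) %||% sig_channels(), sig_channels())) {
    abort("channel order mismatch: both matrices must use sig_channels() ordering")
  }
  cs <- cosine_matrix(W, reference)
  best <- apply(cs, 1, which.max)
  pear <- vapply(seq_len(ncol(W)), function(j) {
    cor(W[, j], reference[, best[j]])
  }, numeric(1))
  tibble(
    signature = colnames(W) %||% paste0("S", seq_len(ncol(W))),
    best_match = colnames(reference)[best],
    cosine = cs[cbind(seq_len(ncol(W)), best)],
    pearson = pear,
    matched = cs[cbind(seq_len(ncol(W)), best)] >= cosine_min
  )
}

# Nonnegative least-squares refit of exposures for a pooled catalog vector.
refit_exposures <- function(signatures, counts_vector) {
  fit <- pracma::lsqnonneg(as.matrix(signatures), as.numeric(counts_vector))
  setNames(fit$x, colnames(signatures))
}

#' Clonal vs subclonal enrichment of mutational signatures
#'
#' Attributes each stratum's pooled mutation catalog to the fitted signatures
#' by nonnegative least squares, then tests each signature's 2x2 table
#' (attributed to the signature vs to the others) x (clonal vs subclonal) with
#' a two-sided Fisher exact test; p-values are FDR-adjusted across signatures.
#'
#' @param clonal_counts,subclonal_counts 96 x n context count matrices for the
#'   clonal and subclonal strata of the same cohort.
#' @param signature_set Fitted `"signature_set"`.
#' @return Tibble per signature: attributed counts in both strata, `odds_ratio`
#'   (clonal odds over subclonal odds), `p_value`, `fdr`, and `direction`
#'   (`"clonal"`/`"subclonal"` by the sign of the association). All-NA rows
#'   when a stratum has no mutations.
#' @export
signature_clonality_enrichment <- function(clonal_counts, subclonal_counts,
                                           signature_set) {
  W <- signature_set$signatures
  k <- ncol(W)
  sig_names <- colnames(W)
  cl_tot <- rowSums(as.matrix(clonal_counts))
  su_tot <- rowSums(as.matrix(subclonal_counts))
  if (sum(cl_tot) == 0 || sum(su_tot) == 0) {
    warn("a stratum has zero mutations; enrichment undefined")
    return(tibble(signature = sig_names, n_clonal = NA_real_,
                  n_subclonal = NA_real_, odds_ratio = NA_real_,
                  p_value = NA_real_, fdr = NA_real_,
                  direction = NA_character_))
  }
  e_cl <- refit_exposures(W, cl_tot)
  e_su <- refit_exposures(W, su_tot)
  # rescale attributions to the stratum totals and round to counts
  a_cl <- round(e_cl / sum(e_cl) * sum(cl_tot))
  a_su <- round(e_su / sum(e_su) * sum(su_tot))
  res <- purrr::map_dfr(seq_len(k), function(j) {
    tab <- matrix(c(a_cl[j], sum(a_cl) - a_cl[j],
                    a_su[j], sum(a_su) - a_su[j]), nrow = 2, byrow = TRUE)
    ft <- fisher.test(tab, alternative = "two.sided")
    tibble(signature = sig_names[j], n_clonal = a_cl[j], n_subclonal = a_su[j],
           odds_ratio = unname(ft$estimate), p_value = ft$p.value)
  })
  res %>%
    mutate(fdr = p.adjust(.data$p_value, method = "fdr"),
           direction = if_else(.data$odds_ratio >= 1, "clonal", "subclonal"))
  }
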
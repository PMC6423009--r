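# Single-sample gene-set enrichment (ssGSEA) scoring.

# Raw integrated running-sum statistic for one sample.
# expr_ranks: named vector of expression ranks (higher = more expressed).
ssgsea_sample <- function(expr_ranks, set, alpha) {
  ord <- order(expr_ranks, decreasing = TRUE)
  in_set <- names(expr_ranks)[ord] %in% set
  if (!any(in_set)) return(NA_real_)
  w <- ifelse(in_set, abs(expr_ranks[ord])^alpha, 0)
  p_in <- cumsum(w) / sum(w)
  n_out <- sum(!in_set)
  p_out <- cumsum(!in_set) / max(n_out, 1)
  sum(p_in - p_out)
}

#' ssGSEA scores for gene sets across samples
#'
#' For every sample, genes are ranked by expression; the score of a gene set
#' is the integrated difference between the weighted cumulative distribution
#' of in-set genes (ranks raised to `weight_exponent`) and the unweighted
#' cumulative distribution of out-of-set genes, summed over all ranks
#' (the integrated running-sum statistic). Scores depend on the expression
#' values only through their within-sample ranks, so they are invariant under
#' strictly monotone transformations.
#'
#' @param expression Numeric genes x samples matrix with gene rownames.
#' @param gene_sets Named list of gene identifier vectors.
#' @param weight_exponent Exponent on the ranks (default 0.25).
#' @param normalize `"ngenes"` (default: divide raw scores by the number of
#'   genes), `"minmax"` (additionally min-max normalize each set across
#'   samples), or `"none"` (raw integrated statistic).
#' @return Numeric sets x samples matrix; `NA` when a set has no expressed
#'   member gene.
#' @export
ssgsea_scores <- function(expression, gene_sets,
                          weight_exponent = 0.25,
                          normalize = c("ngenes", "minmax", "none")) {
  normalize <- match.arg(normalize)
  expression <- as.matrix(expression)
  if (is.null(rownames(expression))) abort("expression matrix needs gene rownames")
  n_genes <- nrow(expression)
  scores <- matrix(NA_real_, nrow = length(gene_sets), ncol = ncol(expression),
                   dimnames = list(names(gene_sets), colnames(expression)))
  for (j in seq_len(ncol(expression))) {
    r <- rank(expression[, j], ties.method = "average")
    names(r) <- rownames(expression)
    for (i in seq_along(gene_sets)) {
      scores[i, j] <- ssgsea_sample(r, gene_sets[[i]], weight_exponent)
    }
  }
  if (normalize %in% c("ngenes", "minmax")) {
    scores <- scores / n_genes
  }
  if (normalize == "minmax") {
    rng <- apply(scores, 1, function(x) diff(range(x, na.rm = TRUE)))
    rng[rng == 0 | is.na(rng)] <- 1
    scores <- (scores - apply(scores, 1, min, na.rm = TRUE)) / rng
  }
  scores
}

#' Immune cell-type score ratios
#'
#' Ratios of ssGSEA scores between paired immune populations (by default
#' Th17/Th2 and CD8/Treg). Because ssGSEA scores can be negative, both scores
#' of a pair are first shifted by the cohort-wide minimum of the two sets plus
#' `epsilon`, which makes the ratio positive and invariant to adding any
#' constant to all scores of both sets.
#'
#' @param scores ssGSEA sets x samples matrix (see [ssgsea_scores()]).
#' @param pairs Named list of 2-vectors `c(numerator, denominator)` of set
#'   names; the names become the ratio column names.
#' @param epsilon Positivity shift (default 1e-3).
#' @return Tibble with `sample_id` and one column per ratio.
#' @export
immune_ratios <- function(scores,
                          pairs = list(th17_th2 = c("Th17", "Th2"),
                                       cd8_treg = c("CD8", "Treg")),
                          epsilon = 1e-3) {
  needed <- unique(unlist(pairs))
  missing <- setdiff(needed, rownames(scores))
  if (length(missing) > 0) {
    abort(sprintf("missing gene set score(s): %s", paste(missing, collapse = ", ")))
  }
  out <- tibble(sample_id = colnames(scores) %||% as.character(seq_len(ncol(scores))))
  for (nm in names(pairs)) {
    num <- scores[pairs[[nm]][1], ]
    den <- scores[pairs[[nm]][2], ]
    shift <- min(c(num, den), na.rm = TRUE)
    out[[nm]] <- (num - shift + epsilon) / (den - shift + epsilon)
  }
  out
}
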
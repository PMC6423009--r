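# Writers mirroring the readers; every table round-trips through its reader.

write_tsv_commented <- function(df, path, comment = NULL) {
  lines <- character()
  if (!is.null(comment)) lines <- paste0("# ", comment)
  body <- readr::format_tsv(df)
  readr::write_lines(c(lines, sub("\n$", "", body)), path)
  invisible(path)
}

#' Write a mutation table
#'
#' @param mutations Tibble of mutation records (see [read_mutations()]).
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
write_mutations <- function(mutations, path) {
  cols <- c(MUTATION_COLUMNS, "context_5p", "context_3p")
  extra <- setdiff(names(mutations), c(cols, "mutation_id"))
  df <- mutations[, c(intersect(c("mutation_id", cols), names(mutations)), extra)]
  write_tsv_commented(df, path, "somatic SNVs; coordinates 1-based")
}

#' Write a segment table
#' @param segments Tibble of segment records (see [read_segments()]).
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
write_segments <- function(segments, path) {
  write_tsv_commented(segments, path, "copy-number segments; coordinates 1-based closed")
}

#' Write a purity/ploidy table
#' @param purity Tibble with `sample_id, purity, ploidy`.
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
write_purity <- function(purity, path) {
  write_tsv_commented(purity, path)
}

#' Write chromosome-arm definitions
#' @param arms Tibble with `arm_id, chromosome, start, end`.
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
write_arm_definitions <- function(arms, path) {
  write_tsv_commented(arms, path, "chromosome arms; coordinates 1-based closed")
}

#' Write a clinical table
#' @param clinical Tibble of clinical records (see [read_clinical()]).
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
write_clinical <- function(clinical, path) {
  write_tsv_commented(clinical, path)
}

#' Write a genes-by-samples expression matrix
#' @param expression Numeric matrix with gene rownames.
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
write_expression <- function(expression, path) {
  df <- bind_cols(tibble(gene = rownames(expression)),
                  as_tibble(as.data.frame(expression)))
  write_tsv_commented(df, path)
}

#' Write a 96-channel signature matrix
#' @param signatures Numeric 96 x K matrix with channel rownames.
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
write_signature_matrix <- function(signatures, path) {
  df <- bind_cols(tibble(channel = rownames(signatures)),
                  as_tibble(as.data.frame(signatures)))
  write_tsv_commented(df, path)
}

#' Write gene sets to a GMT file
#' @param sets Named list of character vectors.
#' @param path Output GMT path.
#' @param descriptions Optional character vector of set descriptions.
#' @return The path, invisibly.
#' @export
write_gene_sets <- function(sets, path, descriptions = NULL) {
  descriptions <- descriptions %||% rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1))
  readr::write_lines(lines, path)
  invisible(path)
}

#' Write every table of a generated cohort into a directory
#'
#' Emits exactly the file formats the readers consume: `mutations.tsv`,
#' `segments.tsv`, `purity.tsv`, `arms.tsv`, `clinical.tsv`,
#' `expression.tsv`, `immune_sets.gmt`.
#'
#' @param cohort A cohort object from [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_mutations(cohort$mutations, file.path(dir, "mutations.tsv"))
  write_segments(cohort$segments, file.path(dir, "segments.tsv"))
  write_purity(cohort$purity, file.path(dir, "purity.tsv"))
  write_arm_definitions(cohort$arms, file.path(dir, "arms.tsv"))
  write_clinical(cohort$clinical, file.path(dir, "clinical.tsv"))
  write_expression(cohort$expression, file.path(dir, "expression.tsv"))
  write_gene_sets(cohort$gene_sets, file.path(dir, "immune_sets.gmt"))
  invisible(dir)
}
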
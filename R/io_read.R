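# Readers for the on-disk tables. All coordinates are 1-based and closed
# (SEG convention); chromosome names are normalized by stripping "chr".

MUTATION_COLUMNS <- c(
  "sample_id", "gene", "chromosome", "position", "ref_allele", "alt_allele",
  "tumor_alt_count", "tumor_depth", "normal_alt_count", "normal_depth", "effect"
)

read_tsv_quiet <- function(path, ...) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                  progress = FALSE, ...)
}

n_leading_comments <- function(path) {
  lines <- readr::read_lines(path, n_max = 50L)
  m <- which(!startsWith(lines, "#"))
  if (length(m) == 0) 0L else m[1] - 1L
}

#' Read somatic mutation calls (MAF-like TSV)
#'
#' Reads a tab-separated mutation table with one row per somatic SNV. Required
#' columns: `sample_id, gene, chromosome, position, ref_allele, alt_allele,
#' tumor_alt_count, tumor_depth, normal_alt_count, normal_depth, effect`
#' (`effect` one of `"silent"`, `"non_silent"`). Optional columns
#' `context_5p`/`context_3p` give the flanking reference bases; when absent, a
#' reference FASTA must be supplied and the flanks are fetched from it (as
#' written on the reference strand; pyrimidine folding happens downstream).
#'
#' Rows that fail record-level validation (e.g. `tumor_alt_count >
#' tumor_depth`, `ref_allele == alt_allele`) are not silently dropped: they are
#' collected with their file line numbers in the `"rejects"` attribute (see
#' [mutation_rejects()]) and a warning is raised.
#'
#' @param path Path to the TSV file. Lines starting with `#` are comments.
#' @param reference_fasta Optional path to a FASTA file used to fetch flanking
#'   bases when the context columns are absent (requires the Biostrings
#'   package).
#' @return A tibble of validated mutation records with attribute `"rejects"`.
#' @seealso [write_mutations()], [mutation_rejects()]
#' @export
read_mutations <- function(path, reference_fasta = NULL) {
  # single-base columns like "T" must never be guessed as logicals
  char_cols <- c("sample_id", "gene", "chromosome", "ref_allele", "alt_allele",
                 "context_5p", "context_3p", "effect")
  header <- strsplit(readr::read_lines(path, skip = n_leading_comments(path),
                                       n_max = 1L), "\t", fixed = TRUE)[[1]]
  spec <- do.call(readr::cols,
                  setNames(as.list(rep("c", sum(header %in% char_cols))),
                           intersect(header, char_cols)))
  df <- read_tsv_quiet(path, col_types = spec)
  check_columns(df, MUTATION_COLUMNS, "mutation table")
  offset <- n_leading_comments(path) + 1L  # header line
  df$.line <- seq_len(nrow(df)) + offset

  has_context <- all(c("context_5p", "context_3p") %in% names(df))
  if (!has_context) {
    if (is.null(reference_fasta)) {
      abort("mutation table has no context_5p/context_3p columns and no reference FASTA was provided")
    }
    ctx <- fetch_context(df$chromosome, df$position, reference_fasta)
    df$context_5p <- ctx$five_prime
    df$context_3p <- ctx$three_prime
  }
  validate_mutations(df)
}

# Shared validator: returns kept tibble with a "rejects" attribute.
validate_mutations <- function(df) {
  df <- df %>%
    mutate(
      sample_id = as.character(.data$sample_id),
      gene = as.character(.data$gene),
      chromosome = normalize_chromosome(.data$chromosome),
      position = as.integer(.data$position),
      ref_allele = toupper(as.character(.data$ref_allele)),
      alt_allele = toupper(as.character(.data$alt_allele)),
      context_5p = toupper(as.character(.data$context_5p)),
      context_3p = toupper(as.character(.data$context_3p))
    )
  if (!".line" %in% names(df)) df$.line <- seq_len(nrow(df)) + 1L

  reason <- rep(NA_character_, nrow(df))
  flag <- function(bad, msg) ifelse(is.na(reason) & bad, msg, reason)
  reason <- flag(!df$effect %in% c("silent", "non_silent"),
                 "effect must be 'silent' or 'non_silent'")
  reason <- flag(is.na(df$position) | df$position < 1, "position must be >= 1")
  reason <- flag(!df$ref_allele %in% BASES | !df$alt_allele %in% BASES,
                 "alleles must be single bases A/C/G/T")
  reason <- flag(df$ref_allele == df$alt_allele, "alt_allele equals ref_allele")
  reason <- flag(is.na(df$tumor_depth) | df$tumor_depth < 1, "tumor_depth must be positive")
  reason <- flag(is.na(df$normal_depth) | df$normal_depth < 1, "normal_depth must be positive")
  reason <- flag(is.na(df$tumor_alt_count) | df$tumor_alt_count < 0 |
                   df$tumor_alt_count > df$tumor_depth,
                 "tumor_alt_count must be in [0, tumor_depth]")
  reason <- flag(is.na(df$normal_alt_count) | df$normal_alt_count < 0 |
                   df$normal_alt_count > df$normal_depth,
                 "normal_alt_count must be in [0, normal_depth]")

  rejects <- tibble(line = df$.line[!is.na(reason)], reason = reason[!is.na(reason)])
  kept <- df[is.na(reason), setdiff(names(df), ".line"), drop = FALSE]
  if (nrow(rejects) > 0) {
    warn(sprintf("%d mutation row(s) rejected (lines %s); see mutation_rejects()",
                 nrow(rejects), paste(rejects$line, collapse = ", ")))
  }
  attr(kept, "rejects") <- rejects
  kept
}

#' Rejected rows from a mutation table
#'
#' @param mutations A tibble returned by [read_mutations()].
#' @return Tibble with columns `line` and `reason` (empty when nothing was
#'   rejected).
#' @export
mutation_rejects <- function(mutations) {
  attr(mutations, "rejects") %||% tibble(line = integer(), reason = character())
}

# Fetch 5'/3' flanking bases from a FASTA file (upper-cased, reference strand).
fetch_context <- function(chromosome, position, fasta_path) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    abort("fetching flanking bases from FASTA requires the Biostrings package")
  }
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  names(seqs) <- normalize_chromosome(names(seqs))
  chrom <- normalize_chromosome(chromosome)
  missing <- setdiff(unique(chrom), names(seqs))
  if (length(missing) > 0) {
    abort(sprintf("chromosome(s) not present in FASTA: %s",
                  paste(missing, collapse = ", ")))
  }
  lens <- setNames(Biostrings::width(seqs), names(seqs))[chrom]
  fp <- rep(NA_character_, length(chrom))
  tp <- rep(NA_character_, length(chrom))
  ok5 <- position > 1
  ok3 <- position < lens
  if (any(ok5)) {
    fp[ok5] <- toupper(as.character(Biostrings::subseq(
      seqs[chrom[ok5]], start = position[ok5] - 1L, width = 1L)))
  }
  if (any(ok3)) {
    tp[ok3] <- toupper(as.character(Biostrings::subseq(
      seqs[chrom[ok3]], start = position[ok3] + 1L, width = 1L)))
  }
  if (any(!ok5 | !ok3)) {
    warn(sprintf("%d site(s) at a contig boundary have missing flanking bases",
                 sum(!ok5 | !ok3)))
  }
  tibble(five_prime = fp, three_prime = tp)
}

#' Read copy-number segments (SEG-style TSV)
#'
#' Required columns: `sample_id, chromosome, start, end, total_copy_number,
#' segment_ccf`. Coordinates are 1-based closed; `segment_ccf` is the fraction
#' of tumor cells carrying the segment's alteration (may be `NA` for
#' copy-neutral segments). Records are returned sorted by
#' (sample, chromosome, start); overlapping segments within one sample and
#' chromosome are an error.
#'
#' @param path Path to the TSV file.
#' @return Tibble of segment records.
#' @export
read_segments <- function(path) {
  df <- read_tsv_quiet(path, col_types = readr::cols(sample_id = "c",
                                                     chromosome = "c"))
  check_columns(df, c("sample_id", "chromosome", "start", "end",
                      "total_copy_number", "segment_ccf"), "segment table")
  df <- df %>%
    mutate(
      sample_id = as.character(.data$sample_id),
      chromosome = normalize_chromosome(.data$chromosome),
      start = as.numeric(.data$start),
      end = as.numeric(.data$end),
      total_copy_number = as.integer(.data$total_copy_number),
      segment_ccf = as.numeric(.data$segment_ccf)
    )
  if (any(df$end < df$start)) {
    i <- which(df$end < df$start)[1]
    abort(sprintf("segment with end < start (sample %s, chromosome %s, start %g)",
                  df$sample_id[i], df$chromosome[i], df$start[i]))
  }
  if (any(df$total_copy_number < 0, na.rm = TRUE)) {
    abort("total_copy_number must be >= 0")
  }
  bad_ccf <- !is.na(df$segment_ccf) & (df$segment_ccf < 0 | df$segment_ccf > 1)
  if (any(bad_ccf)) abort("segment_ccf must be in [0, 1] or NA")

  df <- arrange(df, .data$sample_id, .data$chromosome, .data$start)
  ov <- df %>%
    group_by(.data$sample_id, .data$chromosome) %>%
    filter(row_number() > 1 & .data$start <= lag(.data$end)) %>%
    ungroup()
  if (nrow(ov) > 0) {
    abort(sprintf(
      "overlapping segments within sample %s, chromosome %s near position %g",
      ov$sample_id[1], ov$chromosome[1], ov$start[1]))
  }
  df
}

#' Read the per-sample purity/ploidy table
#'
#' @param path TSV with columns `sample_id, purity, ploidy`.
#' @return Tibble with purity in (0, 1] and positive ploidy.
#' @export
read_purity <- function(path) {
  df <- read_tsv_quiet(path, col_types = readr::cols(sample_id = "c"))
  check_columns(df, c("sample_id", "purity", "ploidy"), "purity table")
  df <- mutate(df, sample_id = as.character(.data$sample_id),
               purity = as.numeric(.data$purity), ploidy = as.numeric(.data$ploidy))
  check_range(df$purity, 0, 1, "purity", lo_open = TRUE)
  if (any(df$ploidy <= 0)) abort("ploidy must be positive")
  df
}

#' Read chromosome-arm definitions
#'
#' @param path TSV with columns `arm_id, chromosome, start, end` (1-based
#'   closed). Arms within a chromosome must not overlap.
#' @return Tibble of arm definitions.
#' @export
read_arm_definitions <- function(path) {
  df <- read_tsv_quiet(path, col_types = readr::cols(arm_id = "c",
                                                     chromosome = "c"))
  check_columns(df, c("arm_id", "chromosome", "start", "end"), "arm table")
  df <- df %>%
    mutate(arm_id = as.character(.data$arm_id),
           chromosome = normalize_chromosome(.data$chromosome),
           start = as.numeric(.data$start), end = as.numeric(.data$end)) %>%
    arrange(.data$chromosome, .data$start)
  if (any(df$end <= df$start)) abort("arm end must be > start")
  ov <- df %>%
    group_by(.data$chromosome) %>%
    filter(row_number() > 1 & .data$start <= lag(.data$end)) %>%
    ungroup()
  if (nrow(ov) > 0) {
    abort(sprintf("overlapping arms on chromosome %s", ov$chromosome[1]))
  }
  df
}

#' Read the clinical table
#'
#' @param path TSV with columns `sample_id, survival_time, event_observed,
#'   age, sex, t_stage, fuhrman_grade`. `survival_time` is in months and must
#'   be positive; `event_observed` is logical (or 0/1).
#' @return Tibble of clinical records.
#' @export
read_clinical <- function(path) {
  df <- read_tsv_quiet(path, col_types = readr::cols(sample_id = "c", sex = "c",
                                                     t_stage = "c",
                                                     fuhrman_grade = "c"))
  check_columns(df, c("sample_id", "survival_time", "event_observed", "age",
                      "sex", "t_stage", "fuhrman_grade"), "clinical table")
  df <- mutate(df,
               sample_id = as.character(.data$sample_id),
               survival_time = as.numeric(.data$survival_time),
               event_observed = as.logical(.data$event_observed),
               age = as.numeric(.data$age),
               sex = as.character(.data$sex),
               t_stage = as.character(.data$t_stage),
               fuhrman_grade = as.character(.data$fuhrman_grade))
  if (any(df$survival_time <= 0)) abort("survival_time must be positive")
  if (!all(df$t_stage %in% paste0("T", 1:4))) abort("t_stage must be T1-T4")
  if (!all(df$fuhrman_grade %in% paste0("G", 1:4))) abort("fuhrman_grade must be G1-G4")
  df
}

#' Read a genes-by-samples expression matrix
#'
#' @param path TSV whose first column (`gene`) names the genes; remaining
#'   columns are samples.
#' @return Numeric matrix with gene rownames and sample colnames.
#' @export
read_expression <- function(path) {
  df <- read_tsv_quiet(path)
  check_columns(df, "gene", "expression matrix")
  m <- as.matrix(df[, -1, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- as.character(df$gene)
  m
}

#' Read a 96-channel reference signature matrix
#'
#' @param path TSV whose first column (`channel`) holds the 96 trinucleotide
#'   channel labels; remaining columns are reference signatures, each summing
#'   to 1. Rows may be in any order and are reordered (with a message) to the
#'   canonical [sig_channels()] ordering.
#' @return Numeric 96 x K matrix with channel rownames.
#' @export
read_signature_matrix <- function(path) {
  df <- read_tsv_quiet(path)
  check_columns(df, "channel", "signature matrix")
  canonical <- sig_channels()
  if (!setequal(df$channel, canonical) || nrow(df) != 96) {
    abort("signature matrix must contain exactly the 96 trinucleotide channels")
  }
  if (!identical(as.character(df$channel), canonical)) {
    inform("reordering signature matrix rows to canonical channel order")
    df <- df[match(canonical, df$channel), , drop = FALSE]
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- canonical
  if (any(m < 0)) abort("reference signatures must be nonnegative")
  sums <- colSums(m)
  if (any(abs(sums - 1) > 1e-6)) {
    abort(sprintf("reference signature column(s) not summing to 1: %s",
                  paste(colnames(m)[abs(sums - 1) > 1e-6], collapse = ", ")))
  }
  m
}

#' Read gene sets from a GMT file
#'
#' Each GMT line holds a set name, a description, and the member genes.
#' Duplicate members within a set are removed; empty sets are skipped with a
#' warning.
#'
#' @param path Path to the GMT file.
#' @return Named list of character vectors of gene identifiers.
#' @export
read_gene_sets <- function(path) {
  if (requireNamespace("fgsea", quietly = TRUE)) {
    sets <- fgsea::gmtPathways(path)
  } else {
    lines <- readr::read_lines(path)
    lines <- lines[nzchar(lines)]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    sets <- setNames(
      lapply(parts, function(p) if (length(p) > 2) p[-c(1, 2)] else character()),
      vapply(parts, `[`, character(1), 1)
    )
  }
  if (anyDuplicated(names(sets))) abort("duplicate gene-set names in GMT file")
  sets <- lapply(sets, function(g) unique(g[nzchar(g)]))
  empty <- vapply(sets, length, integer(1)) == 0
  if (any(empty)) {
    warn(sprintf("skipping %d empty gene set(s): %s", sum(empty),
                 paste(names(sets)[empty], collapse = ", ")))
    sets <- sets[!empty]
  }
  sets
}
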
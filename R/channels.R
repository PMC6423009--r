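# Trinucleotide context channels (pyrimidine-strand convention).

BASES <- c("A", "C", "G", "T")
SUBSTITUTIONS <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")

#' The 96 trinucleotide context channels
#'
#' Channel labels follow the COSMIC convention `"X[R>A]Y"`: the mutated base
#' folded to the pyrimidine strand (C or T), flanked by its 5' and 3'
#' neighbours. Ordering is by substitution class (C>A, C>G, C>T, T>A, T>C,
#' T>G), then 5' base, then 3' base, each in alphabetical order.
#'
#' @return Character vector of 96 channel labels.
#' @examples
#' head(sig_channels())
#' @export
sig_channels <- function() {
  unlist(lapply(SUBSTITUTIONS, function(s) {
    ref <- substr(s, 1, 1)
    unlist(lapply(BASES, function(fp) paste0(fp, "[", s, "]", BASES)))
  }), use.names = FALSE)
}

revcomp_base <- function(x) {
  chartr("ACGT", "TGCA", x)
}

#' Fold a substitution with flanks onto its 96-channel label
#'
#' Mutations whose reference base is a purine (A or G) are reverse-complemented
#' so that the mutated base is always a pyrimidine (C or T); the flanking bases
#' swap roles and are complemented accordingly.
#'
#' @param ref,alt Reference and alternate bases (single characters, vectorized).
#' @param five_prime,three_prime Flanking bases on the reference strand.
#' @return Character vector of channel labels; `NA` (with a warning) for
#'   entries containing a base outside A/C/G/T or with `ref == alt`.
#' @examples
#' context_channel("C", "T", "A", "G")  # "A[C>T]G"
#' context_channel("G", "A", "C", "T")  # same channel, purine strand folded
#' @export
context_channel <- function(ref, alt, five_prime, three_prime) {
  ref <- toupper(as.character(ref)); alt <- toupper(as.character(alt))
  fp <- toupper(as.character(five_prime)); tp <- toupper(as.character(three_prime))
  n <- max(length(ref), length(alt), length(fp), length(tp))
  ref <- rep_len(ref, n); alt <- rep_len(alt, n)
  fp <- rep_len(fp, n); tp <- rep_len(tp, n)

  ok <- ref %in% BASES & alt %in% BASES & fp %in% BASES & tp %in% BASES &
    ref != alt
  if (any(!ok)) {
    warn(sprintf("%d mutation(s) dropped: ambiguous base or ref == alt", sum(!ok)))
  }
  purine <- ref %in% c("A", "G")
  r <- ifelse(purine, revcomp_base(ref), ref)
  a <- ifelse(purine, revcomp_base(alt), alt)
  f <- ifelse(purine, revcomp_base(tp), fp)
  t3 <- ifelse(purine, revcomp_base(fp), tp)
  out <- paste0(f, "[", r, ">", a, "]", t3)
  out[!ok] <- NA_character_
  out
}

# Parse channel labels back into (five_prime, ref, alt, three_prime) on the
# pyrimidine strand. Used by the synthetic generator.
parse_channel <- function(channel) {
  stopifnot(all(grepl("^[ACGT]\\[[CT]>[ACGT]\\][ACGT]$", channel)))
  tibble(
    five_prime = substr(channel, 1, 1),
    ref = substr(channel, 3, 3),
    alt = substr(channel, 5, 5),
    three_prime = substr(channel, 7, 7)
  )
}
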
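# Shared sequence helpers. All internal sequences are plain upper-case
# character strings on the DNA alphabet; RNA display (T -> U) happens only at
# reporting boundaries.

#' Reverse complement of DNA strings
#'
#' Thin vectorised wrapper around [Biostrings::reverseComplement()].
#'
#' @param x Character vector of DNA sequences.
#' @return Character vector of reverse complements.
#' @keywords internal
revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(as_dna(x))))
}

#' GC content of nucleotide sequences
#'
#' Computes 100 * (G + C) / (A + C + G + T). Ambiguity codes (including N)
#' are excluded from both numerator and denominator.
#'
#' @param x Character vector of DNA/RNA sequences; multiple sequences are
#'   pooled into a single percentage.
#' @return GC percentage on the 0-100 scale.
#' @examples
#' gc_percent("ATGC")   # 50
#' gc_percent("ATGCN")  # 50, N ignored
#' @export
gc_percent <- function(x) {
  x <- toupper(paste(x, collapse = ""))
  x <- chartr("U", "T", x)
  n <- nchar(x)
  if (n == 0) abort("empty sequence")
  counts <- vapply(c("A", "C", "G", "T"), function(b) {
    lengths(regmatches(x, gregexpr(b, x, fixed = TRUE)))
  }, numeric(1))
  tot <- sum(counts)
  if (tot == 0) abort("sequence contains no unambiguous A/C/G/T bases")
  100 * (counts[["G"]] + counts[["C"]]) / tot
}

#' Per-sequence GC content
#' @param x Character vector of sequences.
#' @return Numeric vector, one GC percentage per element (NA for elements
#'   with no unambiguous base).
#' @keywords internal
gc_percent_each <- function(x) {
  vapply(x, function(s) {
    tryCatch(gc_percent(s), error = function(e) NA_real_)
  }, numeric(1), USE.NAMES = FALSE)
}

# split a DNA string into codons; drops a trailing partial codon
split_codons <- function(x) {
  n <- nchar(x) %/% 3L
  if (n == 0) return(character(0))
  substring(x, 3L * seq_len(n) - 2L, 3L * seq_len(n))
}

# display helper: DNA -> RNA alphabet
as_rna <- function(x) chartr("Tt", "Uu", x)
as_dna <- function(x) chartr("Uu", "Tt", x)
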
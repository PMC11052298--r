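# Translation termination signals: stop codon usage per expression class.
# The +4 nucleotide is carried in the feature table (downstream context) for
# extensibility but not analysed here.

#' Stop codon usage table
#'
#' Counts UAA, UAG and UGA stop codons. Genes whose terminal codon is not a
#' canonical stop (annotation truncations) are excluded from N with a
#' warning, since the percentages assume canonical termination. UAA% is on
#' the 0-100 scale; proportions sum to 1.
#'
#' @inheritParams start_codon_usage
#' @return One-row tibble: counts `UAA`, `UAG`, `UGA`, `n`, `uaa_percent`,
#'   and proportions `p_uaa`, `p_uag`, `p_uga`.
#' @examples
#' stop_codon_usage(c(rep("UAA", 6), rep("UGA", 3), "UAG"))
#' @export
stop_codon_usage <- function(x, class_filter = NULL) {
  codons <- codon_column(x, class_filter, "stop_codon")
  if (length(codons) == 0) abort("empty gene set")
  codons <- toupper(as_dna(codons))
  canonical <- codons %in% c("TAA", "TAG", "TGA")
  if (any(!canonical)) {
    warn(sprintf("%d gene(s) without a canonical stop codon excluded from N",
                 sum(!canonical)))
    codons <- codons[canonical]
  }
  if (length(codons) == 0) abort("no genes with canonical stop codons")
  n <- length(codons)
  uaa <- sum(codons == "TAA")
  uag <- sum(codons == "TAG")
  uga <- sum(codons == "TGA")
  tibble::tibble(
    UAA = uaa, UAG = uag, UGA = uga, n = n,
    uaa_percent = 100 * uaa / n,
    p_uaa = uaa / n, p_uag = uag / n, p_uga = uga / n
  )
}
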
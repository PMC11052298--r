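# Feature-level genome statistics: rrn operon counting, expression-class
# labelling, and the per-gene export table.

#' Count rRNA (rrn) operons
#'
#' Each rrn operon carries one 16S, one 23S 'and one 5S rRNA transcribed as a
#' unit, so the number of 16S rRNA gene copies is used as the operon count.
#' This avoids fragile co-location clustering of the three genes.
#'
#' @param genome An `annotated_genome`.
#' @param quiet Suppress the warnings for missing rRNA annotation.
#' @return Non-negative integer count of 16S rRNA genes.
#' @export
count_rrn_operons <- function(genome, quiet = FALSE) {
  rr <- genome$rrna
  if (nrow(rr) == 0) {
    if (!quiet) warn("no rRNA features annotated; a functional genome needs at least one rrn operon")
    return(0L)
  }
  n16 <- sum(rr$subunit == "16S", na.rm = TRUE)
  if (n16 > 0 && !quiet &&
      (sum(rr$subunit == "23S", na.rm = TRUE) == 0 ||
       sum(rr$subunit == "5S", na.rm = TRUE) == 0)) {
    warn("16S rRNA genes present but 23S/5S missing; operon count is the 16S copy number")
  }
  as.integer(n16)
}

#' Default highly-expressed-gene name patterns
#'
#' Regular expressions (matched case-insensitively against gene names) for
#' the canonical highly expressed gene set: small and large ribosomal protein
#' genes (rps*, rpl*, rpm*), RNA polymerase core subunits (rpoA/B/C) and
#' elongation factors (tuf*, fusA). Fully overridable wherever a `heg_spec`
#' argument is accepted.
#'
#' @return Character vector of regular expressions.
#' @export
default_heg_patterns <- function() {
  c("^rps[a-z0-9]", "^rpl[a-z0-9]", "^rpm[a-z0-9]",
    "^rpo[abcz]$", "^tuf[a-z0-9]?$", "^fusa?$")
}

#' Label genes as highly expressed (HEG) or background (REST)
#'
#' Every non-pseudo coding gene is labelled `HEG` if its gene name matches a
#' pattern in `heg_spec` (or its locus tag is listed explicitly), otherwise
#' `REST`. Pseudogenes keep `NA` and are excluded from all downstream
#' analyses. The partition over non-pseudo genes is exhaustive and disjoint.
#'
#' @param x An `annotated_genome` or a gene tibble (as in `genome$genes`).
#' @param heg_spec Character vector of case-insensitive regular expressions
#'   for gene names, and/or exact locus tags.
#' @return Object of the same type with the `class` column filled in.
#' @examples
#' # rpsA, rplB, rpoB are HEG; dnaA, ftsZ are REST
#' @export
classify_expression <- function(x, heg_spec = default_heg_patterns()) {
  if (length(heg_spec) == 0) {
    abort("empty heg_spec: the HEG/REST contrast (and DITE) is undefined without HEGs")
  }
  genes <- if (inherits(x, "annotated_genome")) x$genes else x
  name <- tolower(ifelse(is.na(genes$gene), "", genes$gene))
  pat <- paste0("(", paste(tolower(heg_spec), collapse = ")|("), ")")
  is_heg <- grepl(pat, name, perl = TRUE) |
    (genes$locus_tag %in% heg_spec)
  genes$class <- ifelse(genes$is_pseudo, NA_character_,
                        ifelse(is_heg, "HEG", "REST"))
  if (inherits(x, "annotated_genome")) {
    x$genes <- genes
    x
  } else {
    genes
  }
}

#' Per-gene feature table
#'
#' Flat per-species table of the per-gene quantities used downstream; the
#' shape written by the pipeline's TSV export.
#'
#' @param genome An `annotated_genome` (classify first for the `class`
#'   column).
#' @return Tibble with locus_tag, gene, class, strand, is_pseudo,
#'   start_codon, stop_codon (RNA alphabet), downstream +4 nucleotide and
#'   gc_percent of the coding sequence.
#' @export
feature_table <- function(genome) {
  genome$genes |>
    dplyr::transmute(
      species = genome$meta$species,
      locus_tag = .data$locus_tag, gene = .data$gene, class = .data$class,
      strand = .data$strand, is_pseudo = .data$is_pseudo,
      start_codon = as_rna(.data$start_codon),
      stop_codon = as_rna(.data$stop_codon),
      plus4 = substr(.data$downstream, 1L, 1L),
      gc_percent = .data$gc
    )
}

#' Non-pseudo genes of one expression class
#'
#' Convenience accessor: the classified, non-pseudo gene rows of a genome,
#' optionally restricted to one expression class. Errors if the genome has
#' not been through [classify_expression()].
#'
#' @param genome A classified `annotated_genome`.
#' @param class_filter Optional class(es) to keep (`"HEG"`, `"REST"`).
#' @return Gene tibble.
#' @export
class_genes <- function(genome, class_filter = NULL) {
  genes <- dplyr::filter(genome$genes, !.data$is_pseudo)
  if (all(is.na(genes$class))) {
    abort("genes are unclassified; call classify_expression() first")
  }
  if (!is.null(class_filter)) {
    genes <- dplyr::filter(genes, .data$class %in% class_filter)
  }
  genes
}
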
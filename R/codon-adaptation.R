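# Codon adaptation: codon usage tables, the index of translation efficiency
# (I_TE, a CAI-style geometric mean with mutation-background-corrected
# weights), the HEG-minus-REST difference DITE, and the effective number of
# codons/anticodons (Wright's homozygosity formula).
#
# The genetic code is fixed to bacterial translation table 11 (whose sense
# codon -> amino acid map equals the standard code; the difference is only in
# permitted start codons).

codon_families <- local({
  code <- NULL
  function() {
    if (is.null(code)) {
      gc <- Biostrings::GENETIC_CODE
      tb <- tibble::tibble(codon = names(gc), amino_acid = unname(gc))
      tb <- tb[tb$amino_acid != "*", ]
      fam <- table(tb$amino_acid)
      tb$fold <- as.integer(fam[tb$amino_acid])
      code <<- tb
    }
    code
  }
})

#' Codon usage counts grouped into synonymous families
#'
#' Counts the 61 sense codons over a set of coding sequences. The first codon
#' of each gene is excluded (start-codon bias is analysed separately) and the
#' stop codon is excluded. Genes whose length is not a multiple of 3 are
#' skipped with a warning.
#'
#' @param x An `annotated_genome`, a gene tibble with a `cds` column, or a
#'   character vector of coding sequences.
#' @param class_filter Optional expression class filter.
#' @return Tibble with `codon`, `amino_acid`, `fold` (synonymous family
#'   size), `count`, `family_count` and `rel_freq` (within-family relative
#'   frequency; families with zero total get `NA`).
#' @export
codon_frequencies <- function(x, class_filter = NULL) {
  cds <- if (is.character(x)) x else codon_column(x, class_filter, "cds")
  bad <- nchar(cds) %% 3L != 0L
  if (any(bad)) {
    warn(sprintf("%d sequence(s) not a multiple of 3 skipped", sum(bad)))
    cds <- cds[!bad]
  }
  cds <- toupper(as_dna(cds))
  inner <- substr(cds, 4L, nchar(cds) - 3L)
  codons <- unlist(lapply(inner, split_codons), use.names = FALSE)
  fam <- codon_families()
  counts <- table(factor(codons, levels = fam$codon))
  fam |>
    dplyr::mutate(count = as.integer(counts[.data$codon])) |>
    dplyr::group_by(.data$amino_acid) |>
    dplyr::mutate(family_count = sum(.data$count),
                  rel_freq = ifelse(.data$family_count > 0,
                                    .data$count / .data$family_count, NA_real_)) |>
    dplyr::ungroup()
}

# background within-family codon probabilities expected from genome-wide GC
# at each codon position: f(G) = f(C) = gc/2, f(A) = f(T) = (1-gc)/2,
# renormalised within each synonymous family.
gc_background <- function(gc) {
  p <- gc / 100
  base_p <- c(A = (1 - p) / 2, C = p / 2, G = p / 2, T = (1 - p) / 2)
  fam <- codon_families()
  raw <- vapply(fam$codon, function(cd) {
    prod(base_p[strsplit(cd, "")[[1]]])
  }, numeric(1), USE.NAMES = FALSE)
  fam |>
    dplyr::mutate(raw = raw) |>
    dplyr::group_by(.data$amino_acid) |>
    dplyr::mutate(rel_freq = .data$raw / sum(.data$raw)) |>
    dplyr::ungroup() |>
    dplyr::select("codon", "amino_acid", "fold", "rel_freq")
}

#' I_TE codon weights
#'
#' Per-codon weights for the index of translation efficiency: the ratio of
#' the within-family codon frequency in highly expressed genes to its
#' background expectation, renormalised to a maximum of 1 per synonymous
#' family. The background correction is what distinguishes I_TE from the
#' classical CAI: a codon merely favoured by mutation bias gets no credit.
#'
#' @param heg_table Codon table from [codon_frequencies()] on the HEG set.
#' @param background Either a single number (genomic GC%, giving the
#'   mutation-expectation background) or a codon table from
#'   [codon_frequencies()] (e.g. on REST genes).
#' @param eps Pseudo-frequency added to both numerator and denominator;
#'   default `0.5 / family_count` per family (prevents zero weights).
#' @return Tibble with `codon`, `amino_acid`, `fold`, `weight` in (0, 1];
#'   Met, Trp (single-codon families) carry weight 1 and are excluded from
#'   gene scoring.
#' @export
ite_weights <- function(heg_table, background, eps = NULL) {
  fam <- codon_families()
  bg <- if (is.numeric(background) && length(background) == 1) {
    gc_background(background)
  } else {
    dplyr::select(background, "codon", "rel_freq")
  }
  tb <- heg_table |>
    dplyr::select("codon", "amino_acid", "fold", "count", "family_count",
                  p_heg = "rel_freq") |>
    dplyr::left_join(dplyr::select(bg, "codon", p_bg = "rel_freq"),
                     by = "codon")
  empty <- unique(tb$amino_acid[tb$family_count == 0 & tb$fold > 1])
  if (length(empty)) {
    warn(paste0("families absent from HEGs get weight 1: ",
                paste(empty, collapse = ", ")))
  }
  tb |>
    dplyr::group_by(.data$amino_acid) |>
    dplyr::mutate(
      eps_fam = if (is.null(eps)) {
        ifelse(.data$family_count > 0, 0.5 / .data$family_count, 0.5)
      } else {
        eps
      },
      p_heg = ifelse(is.na(.data$p_heg), 1 / .data$fold, .data$p_heg),
      p_bg = ifelse(is.na(.data$p_bg), 1 / .data$fold, .data$p_bg),
      raw = (.data$p_heg + .data$eps_fam) / (.data$p_bg + .data$eps_fam),
      weight = .data$raw / max(.data$raw)
    ) |>
    dplyr::ungroup() |>
    dplyr::select("codon", "amino_acid", "fold", "weight")
}

#' Per-gene index of translation efficiency
#'
#' Geometric mean of I_TE weights over a gene's scorable codons. The first
#' codon, the stop codon and single-codon families (Met, Trp) are excluded.
#' Genes with no scorable codon get `NA`.
#'
#' @param cds Character vector of coding sequences (or a gene tibble /
#'   `annotated_genome`, scored over all non-pseudo genes).
#' @param weights Weight table from [ite_weights()].
#' @return Numeric vector of I_TE scores in (0, 1].
#' @export
gene_ite <- function(cds, weights, class_filter = NULL) {
  if (!is.character(cds)) cds <- codon_column(cds, class_filter, "cds")
  scorable <- weights$fold > 1
  w <- setNames(weights$weight, weights$codon)[weights$codon[scorable]]
  vapply(toupper(as_dna(cds)), function(s) {
    codons <- split_codons(substr(s, 4L, nchar(s) - 3L))
    lw <- log(w[codons])
    lw <- lw[!is.na(lw)]
    if (length(lw) == 0) return(NA_real_)
    exp(mean(lw))
  }, numeric(1), USE.NAMES = FALSE)
}

#' @rdname gene_ite
#' @param class_filter Optional expression class filter when `cds` is a gene
#'   tibble or genome.
#' @export
dite <- function(ite_heg, ite_rest) {
  ite_heg <- ite_heg[!is.na(ite_heg)]
  ite_rest <- ite_rest[!is.na(ite_rest)]
  if (length(ite_heg) == 0 || length(ite_rest) == 0) {
    abort("both expression classes must have at least one scored gene")
  }
  mean(ite_heg) - mean(ite_rest)
}

#' Species-level codon adaptation summary
#'
#' Fits I_TE weights on the genome's HEGs against the chosen background,
#' scores every classified gene, and reports the class means and their
#' difference DITE = mean I_TE(HEG) - mean I_TE(REST). Under no selection for
#' elongation efficiency DITE is expected to be 0; it grows with the
#' selection intensity on highly expressed genes.
#'
#' @param genome A classified `annotated_genome`.
#' @param background `"gc"` (mutation expectation from genomic GC%, default)
#'   or `"rest"` (REST-gene codon table).
#' @return One-row tibble: `mean_ite_heg`, `mean_ite_rest`, `dite`, `n_heg`,
#'   `n_rest`. Per-gene scores are attached as attribute `per_gene`.
#' @export
adaptation_summary <- function(genome, background = c("gc", "rest")) {
  background <- match.arg(background)
  heg <- class_genes(genome, "HEG")
  rest <- class_genes(genome, "REST")
  if (nrow(heg) == 0 || nrow(rest) == 0) abort("need both HEG and REST genes")
  heg_tab <- codon_frequencies(heg$cds)
  bg <- if (background == "gc") genome$gc_percent else codon_frequencies(rest$cds)
  w <- ite_weights(heg_tab, bg)
  ite_h <- gene_ite(heg$cds, w)
  ite_r <- gene_ite(rest$cds, w)
  out <- tibble::tibble(
    mean_ite_heg = mean(ite_h, na.rm = TRUE),
    mean_ite_rest = mean(ite_r, na.rm = TRUE),
    dite = dite(ite_h, ite_r),
    n_heg = nrow(heg), n_rest = nrow(rest)
  )
  attr(out, "per_gene") <- tibble::tibble(
    locus_tag = c(heg$locus_tag, rest$locus_tag),
    class = c(rep("HEG", nrow(heg)), rep("REST", nrow(rest))),
    ite = c(ite_h, ite_r)
  )
  out
}

# -- effective number of codons / anticodons ----------------------------------

#' Effective number of codons or anticodons
#'
#' Wright's homozygosity-based effective number. Units (codons, or the
#' anticodons of tRNA genes) are grouped into synonymous families; for each
#' family with n > 1 units the homozygosity is `F = (n * sum(p_i^2) - 1) /
#' (n - 1)` over the distinct unit types, class means `F_k` are taken over
#' the families of each degeneracy class k, and the effective number is
#' `2 + 9/F2 + 1/F3 + 5/F4 + 3/F6`. Minimal diversity (one unit type per
#' family) gives 20; uniform usage of all 61 sense units tends to 61.
#'
#' Families with n <= 1 units or non-positive F are excluded from their
#' class mean with a warning; a class with no usable family is imputed:
#' F3 from (F2 + F4)/2, other classes from the mean of adjacent available
#' classes in the order 2, 3, 4, 6 (standard effective-number practice).
#' Values above 61 are clamped to 61 with a warning.
#'
#' @param units Character vector of codons (DNA or RNA) or anticodons
#'   (`type = "anticodon"`, 5'->3'), one element per gene copy so that
#'   frequencies are copy-number weighted. Pass unique anticodons for the
#'   distinct-anticodon variant.
#' @param type `"codon"` or `"anticodon"`. Anticodons are mapped to their
#'   Watson-Crick codon to find the synonymous family; anticodons whose
#'   WC codon is a stop are dropped with a warning.
#' @param amino_acids Optional explicit family assignment (amino-acid
#'   letters or names per unit), overriding the WC mapping — use for
#'   annotation-derived tRNA pools where wobble makes the WC map ambiguous.
#' @param n_correction Use the small-sample bias correction
#'   `F = (n sum(p^2) - 1)/(n - 1)` (default). With `FALSE`, F is the plain
#'   homozygosity `sum(p^2)` and single-unit families are retained (F = 1);
#'   the uncorrected form is the one that remains stable for the small
#'   per-family counts of tRNA gene pools, where the corrected estimator
#'   collapses to 0 for evenly covered families and must be discarded.
#' @return An `effective_number` object: list with `effective_number`,
#'   `families` (per-family F), `class_means`, and `capped` flag.
#' @examples
#' effective_number(c("TTT", "TTT", "GGA"))  # near-minimal diversity
#' @export
effective_number <- function(units, type = c("codon", "anticodon"),
                             amino_acids = NULL, n_correction = TRUE) {
  type <- match.arg(type)
  units <- toupper(as_dna(units))
  fam <- codon_families()
  if (is.null(amino_acids)) {
    codon <- if (type == "anticodon") revcomp(units) else units
    amino_acids <- fam$amino_acid[match(codon, fam$codon)]
    if (anyNA(amino_acids)) {
      warn(sprintf("%d unit(s) mapping to stop codons or invalid triplets dropped",
                   sum(is.na(amino_acids))))
      units <- units[!is.na(amino_acids)]
      amino_acids <- amino_acids[!is.na(amino_acids)]
    }
  } else {
    amino_acids <- normalize_aa(amino_acids)
  }
  fold_of <- setNames(fam$fold, fam$amino_acid)[!duplicated(fam$amino_acid)]
  fams <- dplyr::tibble(unit = units, amino_acid = amino_acids) |>
    dplyr::group_by(.data$amino_acid) |>
    dplyr::summarise(
      n = dplyr::n(),
      n_types = dplyr::n_distinct(.data$unit),
      sum_p2 = sum((table(.data$unit) / dplyr::n())^2),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      fold = as.integer(fold_of[.data$amino_acid]),
      f_hom = if (n_correction) {
        ifelse(.data$n > 1, (.data$n * .data$sum_p2 - 1) / (.data$n - 1),
               NA_real_)
      } else {
        .data$sum_p2
      }
    )
  usable <- fams$fold > 1 & !is.na(fams$f_hom) & fams$f_hom > 0
  if (any(fams$fold > 1 & !usable)) {
    warn(sprintf("%d family(ies) with n <= 1 or non-positive F excluded from class means",
                 sum(fams$fold > 1 & !usable)))
  }
  cls <- c(2L, 3L, 4L, 6L)
  f_bar <- vapply(cls, function(k) {
    v <- fams$f_hom[usable & fams$fold == k]
    if (length(v)) mean(v) else NA_real_
  }, numeric(1))
  names(f_bar) <- as.character(cls)
  imputed <- is.na(f_bar)
  # impute F3 from flanking classes; other gaps from adjacent available means
  for (i in which(is.na(f_bar))) {
    nb <- c(i - 1L, i + 1L)
    nb <- nb[nb >= 1 & nb <= 4]
    v <- f_bar[nb][!is.na(f_bar[nb])]
    if (length(v) == 0) v <- f_bar[!is.na(f_bar)]
    if (length(v) == 0) abort("no usable synonymous family; effective number undefined")
    f_bar[i] <- mean(v)
  }
  en <- 2 + 9 / f_bar[["2"]] + 1 / f_bar[["3"]] + 5 / f_bar[["4"]] +
    3 / f_bar[["6"]]
  capped <- en > 61
  if (capped) {
    warn(sprintf("effective number %.2f exceeds 61; clamped", en))
    en <- 61
  }
  structure(list(
    effective_number = as.numeric(en),
    families = fams,
    class_means = tibble::tibble(fold = cls, f_bar = unname(f_bar),
                                 imputed = unname(imputed)),
    capped = capped,
    type = type
  ), class = "effective_number")
}

#' @export
print.effective_number <- function(x, ...) {
  cat(sprintf("<effective_number> %s basis: %.4f%s\n", x$type,
              x$effective_number, if (x$capped) " (capped at 61)" else ""))
  invisible(x)
}

#' @export
tidy.effective_number <- function(x, ...) x$families

#' @export
glance.effective_number <- function(x, ...) {
  tibble::tibble(effective_number = x$effective_number,
                 n_units = sum(x$families$n),
                 n_families = nrow(x$families), capped = x$capped)
}

#' Effective number of anticodons of a genome's tRNA pool
#'
#' Convenience wrapper building the anticodon pool from a genome's annotated
#' tRNA genes (copy-number weighted: one unit per tRNA gene) and calling
#' [effective_number()]. tRNA genes without an anticodon qualifier are
#' skipped with a warning. Initiator Met tRNAs are counted in the Met family
#' unless excluded. The homozygosity is uncorrected by default
#' (`n_correction = FALSE`): tRNA families hold only a handful of gene
#' copies, where the bias-corrected estimator degenerates (F = 0 for an
#' evenly covered family) and published anticodon effective numbers sit in
#' the uncorrected regime.
#'
#' @param genome An `annotated_genome`.
#' @param distinct Use distinct anticodons instead of copy-number weighting.
#' @param exclude_initiator Drop initiator Met tRNAs (amino acid `fMet`).
#' @inheritParams effective_number
#' @return An `effective_number` object.
#' @export
trna_effective_number <- function(genome, distinct = FALSE,
                                  exclude_initiator = FALSE,
                                  n_correction = FALSE) {
  tr <- genome$trna
  if (exclude_initiator) tr <- dplyr::filter(tr, .data$amino_acid != "fMet")
  missing_ac <- is.na(tr$anticodon)
  if (any(missing_ac)) {
    warn(sprintf("%d tRNA gene(s) without anticodon annotation skipped",
                 sum(missing_ac)))
    tr <- tr[!missing_ac, ]
  }
  if (distinct) tr <- dplyr::distinct(tr, .data$amino_acid, .data$anticodon)
  effective_number(tr$anticodon, type = "anticodon",
                   amino_acids = tr$amino_acid, n_correction = n_correction)
}

AA_THREE <- c(Ala = "A", Arg = "R", Asn = "N", Asp = "D", Cys = "C",
              Gln = "Q", Glu = "E", Gly = "G", His = "H", Ile = "I",
              Leu = "L", Lys = "K", Met = "M", fMet = "M", Phe = "F",
              Pro = "P", Ser = "S", Thr = "T", Trp = "W", Tyr = "Y",
              Val = "V")

normalize_aa <- function(x) {
  out <- ifelse(x %in% names(AA_THREE), AA_THREE[x], x)
  bad <- !out %in% unique(codon_families()$amino_acid)
  if (any(bad)) abort(paste0("unknown amino acid(s): ",
                             paste(unique(x[bad]), collapse = ", ")))
  unname(out)
}
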
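# Reference panel: nine mesophilic bacterial species spanning generation
# times from ~10 minutes (Vibrio natriegens) to ~7 days (Mycobacterium
# leprae), ranked by generation time (rank_gt, 1 = fastest). These curated
# summary tables feed the cross-species regression stages directly, so the
# statistical layer can be exercised without genome downloads.

PANEL_SPECIES <- c("Vibrio natriegens", "Vibrio cholerae", "Escherichia coli",
                   "Bacillus subtilis", "Haemophilus influenzae",
                   "Mycolicibacterium smegmatis", "Mycobacterioides abscessus",
                   "Mycobacterium tuberculosis", "Mycobacterium leprae")

#' Reference panel: translation machinery counts
#'
#' Genome length, number of protein-coding genes, rrn operon count and tRNA
#' gene count for the nine-species reference panel, ordered by
#' generation-time rank. Short-generation species carry up to 11 rrn operons
#' and 129 tRNA genes; the slowest carry the single-operon minimum.
#'
#' @return Tibble with `species`, `rank_gt`, `genome_length`, `n_cds`,
#'   `n_rrn`, `n_trna`.
#' @export
panel_machinery <- function() {
  tibble::tibble(
    species = PANEL_SPECIES,
    rank_gt = 1:9,
    genome_length = c(5175153L, 4089299L, 4641652L, 4215606L, 1846259L,
                      6993871L, 5067231L, 4411532L, 3187112L),
    n_cds = c(4496L, 3628L, 4298L, 4237L, 1714L, 6540L, 4938L, 3905L, 2328L),
    n_rrn = c(11L, 10L, 7L, 10L, 6L, 3L, 1L, 1L, 1L),
    n_trna = c(129L, 102L, 86L, 86L, 59L, 47L, 47L, 45L, 45L)
  )
}

#' Reference panel: start codon usage by expression class
#'
#' Start codon category counts (AUG, GUG, YUG = CUG + UUG, AUH = AUA + AUC +
#' AUU) for highly expressed genes and the remaining genes of each panel
#' species. `aug_percent` is computed from the counts (100 * AUG / n).
#'
#' @return Tibble with `species`, `rank_gt`, `class`, category counts, `n`
#'   and `aug_percent`.
#' @export
panel_start_usage <- function() {
  heg <- tibble::tibble(
    species = PANEL_SPECIES, rank_gt = 1:9, class = "HEG",
    AUG = c(71L, 70L, 69L, 58L, 68L, 54L, 53L, 49L, 48L),
    GUG = c(3L, 3L, 3L, 5L, 1L, 18L, 14L, 13L, 16L),
    YUG = c(2L, 3L, 1L, 3L, 1L, 0L, 1L, 0L, 3L),
    AUH = 0L,
    n = c(76L, 76L, 73L, 66L, 70L, 72L, 68L, 62L, 67L)
  )
  rest <- tibble::tibble(
    species = PANEL_SPECIES, rank_gt = 1:9, class = "REST",
    AUG = c(3976L, 3166L, 3805L, 3225L, 1554L, 4255L, 3255L, 2357L, 1162L),
    GUG = c(297L, 253L, 335L, 382L, 51L, 1998L, 1458L, 1306L, 782L),
    YUG = c(124L, 131L, 81L, 555L, 28L, 187L, 145L, 177L, 276L),
    AUH = c(15L, 18L, 4L, 9L, 10L, 26L, 14L, 4L, 43L),
    n = c(4412L, 3568L, 4225L, 4171L, 1643L, 6466L, 4872L, 3844L, 2263L)
  )
  dplyr::bind_rows(heg, rest) |>
    dplyr::mutate(aug_percent = 100 * .data$AUG / .data$n)
}

#' Reference panel: AUG% regression input
#'
#' The species x class table used to model AUG start-codon usage: AUG%
#' (full precision, from [panel_start_usage()] counts), generation-time
#' rank, genomic GC% and the expression class.
#'
#' @return Tibble with `species`, `class`, `aug_percent`, `rank_gt`, `gc`,
#'   `ge` (dummy, HEG = 0 / REST = 1).
#' @export
panel_aug <- function() {
  gc <- c(45.0, 47.3, 50.8, 43.5, 38.2, 67.4, 64.1, 65.6, 57.8)
  panel_start_usage() |>
    dplyr::mutate(gc = rep(gc, 2), ge = encode_ge(.data$class)) |>
    dplyr::select("species", "class", "aug_percent", "rank_gt", "gc", "ge")
}

#' Reference panel: codon adaptation differences (DITE)
#'
#' Difference in mean index of translation efficiency between highly
#' expressed and remaining genes, per species.
#'
#' @return Tibble with `species`, `rank_gt`, `dite`.
#' @export
panel_dite <- function() {
  tibble::tibble(
    species = PANEL_SPECIES, rank_gt = 1:9,
    dite = c(0.2516, 0.2380, 0.2465, 0.2380, 0.2092, 0.1266, 0.1806,
             0.0267, 0.0689)
  )
}

#' Reference panel: effective number of anticodons
#'
#' @return Tibble with `species`, `rank_gt`, `n_ac`.
#' @export
panel_anticodon <- function() {
  tibble::tibble(
    species = PANEL_SPECIES, rank_gt = 1:9,
    n_ac = c(40.2129, 44.2802, 49.0127, 45.8531, 50.4305, 59.0667,
             58.8153, 59.3744, 59.3744)
  )
}

#' Reference panel: MeanMFE regression input
#'
#' Species x class MeanMFE (mean sliding-window minimum folding energy over
#' mid-window sites spanning the SD region and start codon) with the
#' class-specific GC% of the scanned sequences.
#'
#' @return Tibble with `species`, `rank_gt`, `class`, `gc`, `ge`,
#'   `mean_mfe`.
#' @export
panel_mfe <- function() {
  heg <- tibble::tibble(
    species = PANEL_SPECIES, rank_gt = 1:9, class = "HEG",
    gc = c(42.8557, 43.7813, 46.5955, 38.7556, 37.9329, 60.4224, 60.4048,
           61.5043, 56.5344),
    mean_mfe = c(-4.2351, -4.0721, -4.2153, -3.7484, -3.2660, -6.4462,
                 -5.5966, -6.2934, -5.7794)
  )
  rest <- tibble::tibble(
    species = PANEL_SPECIES, rank_gt = 1:9, class = "REST",
    gc = c(40.4234, 43.3125, 45.6418, 38.6014, 33.7986, 63.6954, 61.2667,
           63.0856, 57.1858),
    mean_mfe = c(-3.5238, -4.0330, -4.4059, -3.7406, -2.5466, -8.6708,
                 -8.3538, -9.1141, -7.9865)
  )
  dplyr::bind_rows(heg, rest) |>
    dplyr::mutate(ge = encode_ge(.data$class)) |>
    dplyr::select("species", "rank_gt", "class", "gc", "ge", "mean_mfe")
}
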
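# End-to-end orchestration: genomes -> per-species x class summary table ->
# cross-species regressions. Two entry modes: from genomes (full pipeline)
# and from a summary table (regression-only, e.g. on the packaged reference
# panel tables).

#' Summarise one genome into species x class rows
#'
#' Computes, for each expression class of a classified genome, the summary
#' statistics feeding the cross-species models: gene counts, AUG% and UAA%,
#' mean I_TE, class GC%, and (optionally) the MeanMFE of the start-anchored
#' structure scan; plus the species-level rrn/tRNA counts, DITE and the
#' effective number of anticodons.
#'
#' @param genome An `annotated_genome`.
#' @param heg_spec HEG name patterns/locus tags (see
#'   [classify_expression()]); applied unless the genome is already
#'   classified.
#' @param mfe Compute the structure-scan MeanMFE per class? (The folding
#'   stage dominates runtime on large gene sets.)
#' @param engine Folding engine for the structure scan.
#' @param background Background model for I_TE weights.
#' @return Tibble with one row per class (HEG, REST).
#' @export
summarize_genome <- function(genome, heg_spec = default_heg_patterns(),
                             mfe = TRUE, engine = "builtin",
                             background = "gc") {
  if (all(is.na(genome$genes$class))) {
    genome <- classify_expression(genome, heg_spec)
  }
  adapt <- adaptation_summary(genome, background = background)
  nac <- suppressWarnings(trna_effective_number(genome))
  rows <- purrr::map(c("HEG", "REST"), function(cl) {
    genes <- class_genes(genome, cl)
    start_tb <- start_codon_usage(genes)
    stop_tb <- suppressWarnings(stop_codon_usage(genes))
    mean_mfe <- NA_real_
    if (mfe) {
      prof <- suppressMessages(
        structure_profiles(genome, class_filter = cl, anchor = "start",
                           engine = engine)
      )
      if (dplyr::n_distinct(prof$locus_tag) >= 2) {
        mean_mfe <- mean_mfe_summary(aggregate_profiles(prof))
      }
    }
    tibble::tibble(
      species = genome$meta$species,
      rank_gt = genome$meta$rank_gt,
      class = cl, ge = encode_ge(cl),
      n_genes = nrow(genes),
      gc_genome = genome$gc_percent,
      gc_class = mean(genes$gc, na.rm = TRUE),
      n_rrn = genome$rrn_count,
      n_trna = genome$trna_count,
      aug_percent = start_tb$aug_percent,
      uaa_percent = stop_tb$uaa_percent,
      mean_ite = if (cl == "HEG") adapt$mean_ite_heg else adapt$mean_ite_rest,
      dite = adapt$dite,
      n_ac = nac$effective_number,
      mean_mfe = mean_mfe
    )
  })
  dplyr::bind_rows(rows)
}

#' Cross-species models on a summary table
#'
#' The three class-contrast regressions of the analysis, fitted on a
#' species x class summary table (from [run_pipeline()], the packaged
#' reference tables, or a synthetic panel):
#' * start: `aug_percent ~ rank_gt + gc + ge`
#' * stop: `uaa_percent ~ rank_gt + gc + ge`
#' * structure: `mean_mfe ~ rank_gt + gc + ge + gc:ge` (with a declared
#'   one-tailed negative prediction for the rank term)
#'
#' @param data Tibble with the response and `rank_gt`, `gc`, `ge` columns.
#' @name translation_models
#' @return An `ols_fit`.
#' @export
fit_start_model <- function(data) {
  ols_fit(data, aug_percent ~ rank_gt + gc + ge)
}

#' @rdname translation_models
#' @export
fit_stop_model <- function(data) {
  ols_fit(data, uaa_percent ~ rank_gt + gc + ge)
}

#' @rdname translation_models
#' @export
fit_structure_model <- function(data) {
  ols_fit(data, mean_mfe ~ rank_gt + gc + ge + gc:ge,
          one_tailed = "rank_gt")
}

#' Run the full cross-species pipeline
#'
#' Genomes in, summary table and regression layer out: parses (or accepts)
#' annotated genomes, classifies genes, summarises each species with
#' [summarize_genome()], fits the machinery-count floor-exponential models
#' and the class-contrast regressions, and optionally writes every table as
#' TSV.
#'
#' @param x Character vector of GenBank file paths, or a list of
#'   `annotated_genome` objects.
#' @param rank_gt Generation-time ranks, one per genome (taken from genome
#'   metadata when `NULL`).
#' @param heg_spec HEG classification spec.
#' @param mfe,engine,background Passed to [summarize_genome()].
#' @param fit_models Fit the cross-species regressions? Disable for small
#'   or degenerate panels (fewer than 3 species, constant GC) where the
#'   design is singular and only the summary table is wanted.
#' @param out_dir Optional directory for TSV outputs (`summary.tsv`,
#'   `regressions.tsv`, `machinery_fits.tsv`).
#' @return List with `summary` (species x class tibble), `models` (named
#'   `ols_fit`s: start, stop and — when MFE was computed — structure),
#'   `machinery_fits` (floor-exponential fits of n_rrn with floor 1 and
#'   n_trna with free floor), and `class_equations`.
#' @export
run_pipeline <- function(x, rank_gt = NULL,
                         heg_spec = default_heg_patterns(),
                         mfe = TRUE, engine = "builtin", background = "gc",
                         fit_models = TRUE, out_dir = NULL) {
  genomes <- if (is.character(x)) {
    purrr::map(x, read_genbank)
  } else {
    x
  }
  if (!is.null(rank_gt)) {
    genomes <- purrr::map2(genomes, rank_gt, function(g, r) {
      g$meta$rank_gt <- as.integer(r)
      g
    })
  }
  summary_tb <- dplyr::bind_rows(purrr::map(genomes, function(g) {
    tryCatch(
      summarize_genome(g, heg_spec = heg_spec, mfe = mfe, engine = engine,
                       background = background),
      error = function(e) {
        abort(sprintf("summary stage failed for %s: %s",
                      g$meta$species, conditionMessage(e)))
      }
    )
  }))

  species_tb <- dplyr::distinct(summary_tb, .data$species, .data$rank_gt,
                                .data$n_rrn, .data$n_trna)
  machinery <- if (nrow(species_tb) >= 4) {
    list(
      rrn = fit_floor_exponential(species_tb$rank_gt, species_tb$n_rrn,
                                  floor = 1),
      trna = fit_floor_exponential(species_tb$rank_gt, species_tb$n_trna)
    )
  } else {
    message("fewer than 4 species: machinery-count fits skipped")
    NULL
  }

  models <- list()
  class_eq <- list()
  if (fit_models) {
    start_dat <- dplyr::transmute(summary_tb, aug_percent = .data$aug_percent,
                                  uaa_percent = .data$uaa_percent,
                                  rank_gt = .data$rank_gt,
                                  gc = .data$gc_genome, ge = .data$ge)
    models <- list(start = fit_start_model(start_dat),
                   stop = fit_stop_model(start_dat))
    if (mfe && !anyNA(summary_tb$mean_mfe)) {
      mfe_dat <- dplyr::transmute(summary_tb, mean_mfe = .data$mean_mfe,
                                  rank_gt = .data$rank_gt,
                                  gc = .data$gc_class, ge = .data$ge)
      models$structure <- fit_structure_model(mfe_dat)
    }
    class_eq <- purrr::map(models, derive_class_equations)
  }

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    readr::write_tsv(summary_tb, file.path(out_dir, "summary.tsv"))
    if (length(models)) {
      reg_tb <- dplyr::bind_rows(
        purrr::imap(models, function(m, nm) {
          dplyr::mutate(tidy(m), model = nm, r_squared = m$r_squared)
        })
      )
      readr::write_tsv(reg_tb, file.path(out_dir, "regressions.tsv"))
    }
    if (!is.null(machinery)) {
      mach_tb <- dplyr::bind_rows(
        purrr::imap(machinery, function(m, nm) dplyr::mutate(tidy(m), model = nm))
      )
      readr::write_tsv(mach_tb, file.path(out_dir, "machinery_fits.tsv"))
    }
  }
  list(summary = summary_tb, models = models, machinery_fits = machinery,
       class_equations = class_eq)
}
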
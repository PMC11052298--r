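# Sliding-window minimum-folding-energy (MFE) profiles around the start and
# stop codons, aggregation with 95% limits, and the MeanMFE summary.
#
# Two folding engines share one contract (deterministic, MFE <= 0, T mapped
# to U, ambiguity codes unpairable): "builtin" is the package's Zuker-style
# dynamic program over a compact nearest-neighbour parameter set (always
# available, validated against exhaustive enumeration); "vienna" shells out
# to ViennaRNA's RNAfold when installed, for full Turner-parameter energies.

#' Minimum folding energy of RNA windows
#'
#' @param windows Character vector of RNA/DNA windows (typically 40 nt).
#'   Windows shorter than 6 nt return 0 (no hairpin possible under the
#'   minimum loop length of 3).
#' @param engine `"builtin"` (default) or `"vienna"` (requires the RNAfold
#'   executable on the PATH).
#' @param temperature Folding temperature in Celsius; only the vienna engine
#'   uses it (the builtin parameter set is fixed at 37).
#' @return Numeric vector of MFE values in kcal/mol, all <= 0.
#' @examples
#' fold_mfe(strrep("A", 40))          # 0: no complementary pairs
#' fold_mfe("GGGGGAAAAACCCCC") < 0    # a strong hairpin
#' @export
fold_mfe <- function(windows, engine = c("builtin", "vienna"),
                     temperature = 37) {
  engine <- match.arg(engine)
  windows <- toupper(windows)
  out <- numeric(length(windows))
  long <- nchar(windows) >= 6L
  if (any(long)) {
    out[long] <- if (engine == "builtin") {
      .fold_mfe_cpp(windows[long])
    } else {
      fold_mfe_vienna(windows[long], temperature)
    }
  }
  out
}

fold_mfe_vienna <- function(windows, temperature = 37) {
  if (Sys.which("RNAfold") == "") abort("RNAfold not found on PATH")
  inp <- tempfile(fileext = ".seq")
  writeLines(as_rna(windows), inp)
  res <- system2("RNAfold", c("--noPS", "--temp", format(temperature)),
                 stdin = inp, stdout = TRUE)
  unlink(inp)
  elines <- res[seq(2, length(res), by = 2)]
  mfe <- as.numeric(sub(".*\\(\\s*(-?[0-9.]+)\\)\\s*$", "\\1", elines))
  pmin(mfe, 0)
}

#' Energy parameters of the builtin folding engine
#'
#' Returns the full nearest-neighbour parameter set used by the builtin
#' dynamic program (stacking energies, loop penalty tables, extrapolation
#' constants, multiloop costs), so that independent structure-scoring code
#' can reproduce its energies exactly.
#'
#' @return Named list of parameter tables and constants.
#' @export
fold_params <- function() .fold_params_cpp()

#' Sliding-window MFE profile of one sequence
#'
#' Folds every `window`-nt window (step 1 by default) and reports the energy
#' at the window's mid site, `window_start + window/2 - 1` in 1-based
#' coordinates (site 20 for the first 40-nt window).
#'
#' @param sequence A single RNA/DNA string.
#' @param window Window width in nt (default 40).
#' @param step Step between window starts (default 1).
#' @inheritParams fold_mfe
#' @return Tibble with `mid_site` and `mfe`; empty (with a warning) when the
#'   sequence is shorter than `window`.
#' @export
sliding_mfe <- function(sequence, window = 40L, step = 1L,
                        engine = c("builtin", "vienna"), temperature = 37) {
  L <- nchar(sequence)
  if (L < window) {
    warn(sprintf("sequence length %d < window %d: empty profile", L, window))
    return(tibble::tibble(mid_site = integer(), mfe = double()))
  }
  starts <- seq(1L, L - window + 1L, by = step)
  wins <- substring(sequence, starts, starts + window - 1L)
  tibble::tibble(
    mid_site = starts + window %/% 2L - 1L,
    mfe = fold_mfe(wins, engine = engine, temperature = temperature)
  )
}

#' Per-gene MFE profiles anchored at the start or stop codon
#'
#' Assembles, for every classified gene with sufficient context, the scan
#' sequence used for initiation/termination structure profiles and computes
#' its sliding-window MFE profile:
#' * `anchor = "start"`: 60 nt upstream + first 61 nt of CDS (121 nt; the
#'   start codon occupies sites 61-63),
#' * `anchor = "stop"`: last 60 nt of CDS (57 nt tail + stop codon) + 60 nt
#'   downstream (120 nt; the stop codon occupies sites 58-60).
#'
#' Genes with less than 60 nt of flanking context, or CDS shorter than the
#' required interior stretch, are excluded; the excluded count is reported
#' as attribute `n_excluded` and via a message.
#'
#' @param genome A classified `annotated_genome`.
#' @param class_filter Expression class(es) to scan.
#' @param anchor `"start"` or `"stop"`.
#' @inheritParams fold_mfe
#' @param window Window width (default 40).
#' @return Tibble of class `mfe_profiles`: `locus_tag`, `mid_site`, `mfe`.
#' @export
structure_profiles <- function(genome, class_filter = NULL,
                               anchor = c("start", "stop"),
                               engine = c("builtin", "vienna"),
                               window = 40L, temperature = 37) {
  anchor <- match.arg(anchor)
  engine <- match.arg(engine)
  genes <- class_genes(genome, class_filter)
  genes <- dplyr::filter(genes, .data$length_ok)
  if (anchor == "start") {
    keep <- nchar(genes$upstream) >= 60L & nchar(genes$cds) >= 61L
    scan_seq <- paste0(substr(genes$upstream, nchar(genes$upstream) - 59L,
                              nchar(genes$upstream)),
                       substr(genes$cds, 1L, 61L))
  } else {
    keep <- nchar(genes$downstream) >= 60L & nchar(genes$cds) >= 60L
    scan_seq <- paste0(substr(genes$cds, nchar(genes$cds) - 59L, nchar(genes$cds)),
                       substr(genes$downstream, 1L, 60L))
  }
  n_excluded <- sum(!keep)
  if (n_excluded > 0) {
    message(sprintf("%d gene(s) without full flanking context excluded from the %s scan",
                    n_excluded, anchor))
  }
  genes <- genes[keep, ]
  scan_seq <- scan_seq[keep]
  prof <- purrr::map2(genes$locus_tag, scan_seq, function(tag, s) {
    p <- sliding_mfe(s, window = window, engine = engine,
                     temperature = temperature)
    p$locus_tag <- tag
    p
  })
  out <- dplyr::bind_rows(prof)[, c("locus_tag", "mid_site", "mfe")]
  attr(out, "n_excluded") <- n_excluded
  attr(out, "anchor") <- anchor
  class(out) <- c("mfe_profiles", class(out))
  out
}

#' Aggregate per-gene MFE profiles
#'
#' Per-site mean curve with normal-approximation 95% limits
#' (mean +/- 1.96 * sd / sqrt(n)) and per-site gene counts.
#'
#' @param profiles An `mfe_profiles` tibble (or any tibble with `locus_tag`,
#'   `mid_site`, `mfe`); at least 2 profiles.
#' @return Tibble of class `mfe_profile_agg`: `mid_site`, `mean_mfe`, `ll`,
#'   `ul`, `n`.
#' @export
aggregate_profiles <- function(profiles) {
  if (nrow(profiles) == 0) abort("no profiles to aggregate")
  if (dplyr::n_distinct(profiles$locus_tag) < 2) {
    abort("need at least 2 gene profiles to aggregate")
  }
  out <- profiles |>
    dplyr::group_by(.data$mid_site) |>
    dplyr::summarise(
      mean_mfe = mean(.data$mfe),
      se = stats::sd(.data$mfe) / sqrt(dplyr::n()),
      n = dplyr::n(), .groups = "drop"
    ) |>
    dplyr::mutate(ll = .data$mean_mfe - 1.96 * .data$se,
                  ul = .data$mean_mfe + 1.96 * .data$se) |>
    dplyr::select("mid_site", "mean_mfe", "ll", "ul", "n")
  class(out) <- c("mfe_profile_agg", class(out))
  out
}

#' @export
autoplot.mfe_profile_agg <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$mid_site, y = .data$mean_mfe)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ll, ymax = .data$ul),
                         fill = "steelblue", alpha = 0.25) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::labs(x = "mid-window site", y = "MFE (kcal/mol)")
}

#' MeanMFE summary over the initiation-signal window
#'
#' Unweighted mean of the aggregated per-site mean curve over mid-window
#' sites `site_lo .. site_hi` (default 46-65, the stretch spanning the SD
#' region and the start codon under the start-at-61-63 anchor convention).
#'
#' @param aggregated An `mfe_profile_agg` tibble covering the site range.
#' @param site_lo,site_hi Inclusive mid-window site range.
#' @return MeanMFE in kcal/mol (<= 0).
#' @export
mean_mfe_summary <- function(aggregated, site_lo = 46L, site_hi = 65L) {
  sites <- site_lo:site_hi
  if (!all(sites %in% aggregated$mid_site)) {
    abort(sprintf("aggregated profile does not cover mid-window sites %d-%d",
                  site_lo, site_hi))
  }
  mean(aggregated$mean_mfe[match(sites, aggregated$mid_site)])
}
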
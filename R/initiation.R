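# Translation initiation signals: start codon usage, upstream nucleotide
# frequency and PWM profiles around the Shine-Dalgarno (SD) region, the
# C-vs-U avoidance G-test, and the aSD match distance to the start codon.

START_CATEGORIES <- list(
  AUG = "ATG", GUG = "GTG", YUG = c("CTG", "TTG"), AUH = c("ATA", "ATC", "ATT")
)

#' Start codon usage table
#'
#' Counts start codons into the canonical categories AUG, GUG, YUG
#' (CUG + UUG) and AUH (AUA + AUC + AUU); any remaining codons are reported
#' in an `other` bucket. AUG% is 100 * AUG / N with N the full group size, so
#' percentages stay comparable across species.
#'
#' @param x An `annotated_genome` (classified), a gene tibble with
#'   `start_codon` and `class` columns, or a plain character vector of start
#'   codons (DNA or RNA alphabet).
#' @param class_filter Optional expression class(es) to keep (`"HEG"`,
#'   `"REST"`).
#' @return One-row tibble with category counts, `n` and `aug_percent`.
#' @examples
#' start_codon_usage(c(rep("AUG", 71), rep("GUG", 3), rep("UUG", 2)))
#' @export
start_codon_usage <- function(x, class_filter = NULL) {
  codons <- codon_column(x, class_filter, "start_codon")
  if (length(codons) == 0) abort("empty gene set")
  codons <- toupper(as_dna(codons))
  cnt <- function(set) sum(codons %in% set)
  n <- length(codons)
  aug <- cnt(START_CATEGORIES$AUG)
  tibble::tibble(
    AUG = aug, GUG = cnt(START_CATEGORIES$GUG),
    YUG = cnt(START_CATEGORIES$YUG), AUH = cnt(START_CATEGORIES$AUH),
    other = n - aug - cnt(START_CATEGORIES$GUG) - cnt(START_CATEGORIES$YUG) -
      cnt(START_CATEGORIES$AUH),
    n = n, aug_percent = 100 * aug / n
  )
}

codon_column <- function(x, class_filter, column) {
  if (is.character(x)) return(x)
  genes <- if (inherits(x, "annotated_genome")) {
    class_genes(x, class_filter)
  } else {
    g <- dplyr::filter(x, !.data$is_pseudo)
    if (!is.null(class_filter)) g <- dplyr::filter(g, .data$class %in% class_filter)
    g
  }
  genes[[column]]
}

#' Per-site nucleotide frequencies upstream of the start codon
#'
#' Sequences are right-aligned so that site `width` (default 60) abuts the
#' start codon (the start codon itself occupies sites `width + 1 .. width + 3`
#' in figure coordinates). Shorter upstreams contribute only to the sites
#' they cover; ambiguity codes are excluded from each site's denominator.
#'
#' @param upstreams Character vector of upstream sequences (5'->3').
#' @param width Window width in nt (default 60).
#' @return Tibble with columns `site`, `base` (A/C/G/U), `freq`, `n`
#'   (site coverage).
#' @export
positional_frequencies <- function(upstreams, width = 60L) {
  if (length(upstreams) == 0) abort("no sequences")
  mat <- align_right(upstreams, width)
  counts <- sapply(c("A", "C", "G", "T"), function(b) colSums(mat == b))
  n_site <- rowSums(counts)
  tibble::tibble(
    site = rep(seq_len(width), 4L),
    base = rep(c("A", "C", "G", "U"), each = width),
    freq = as.vector(counts) / rep(pmax(n_site, 1L), 4L),
    n = rep(n_site, 4L)
  )
}

# character matrix: rows = sequences, columns = sites 1..width (right-aligned)
align_right <- function(upstreams, width) {
  upstreams <- toupper(as_dna(upstreams))
  mat <- matrix("", nrow = length(upstreams), ncol = width)
  for (i in seq_along(upstreams)) {
    s <- upstreams[i]
    if (is.na(s)) next
    L <- min(nchar(s), width)
    if (L == 0) next
    tailseq <- substr(s, nchar(s) - L + 1L, nchar(s))
    mat[i, (width - L + 1L):width] <- strsplit(tailseq, "")[[1]]
  }
  mat
}

#' Positional weight matrix scores of upstream sequences
#'
#' Log-odds (bits) of per-site nucleotide usage relative to background
#' frequencies, with a pseudocount spread proportionally to the background:
#' `score(site, b) = log2( (count + pc * bg_b) / (N_site + pc) / bg_b )`.
#' Zero means usage equals the background; positive is overuse; negative is
#' avoidance.
#'
#' @param upstreams Character vector of upstream sequences (right-aligned as
#'   in [positional_frequencies()]).
#' @param background Named numeric vector of background frequencies for
#'   A/C/G/U (positive, summing to 1). Defaults to the pooled composition of
#'   `upstreams` itself; for genome-relative scores pass the genome's base
#'   frequencies.
#' @param pseudocount Total pseudocount per site (default 1).
#' @param width Window width (default 60).
#' @return Tibble of class `pwm_profile` with `site`, `base`, `score`; the
#'   background used is attached as attribute `background`.
#' @export
pwm_scores <- function(upstreams, background = NULL, pseudocount = 1,
                       width = 60L) {
  if (length(upstreams) == 0) abort("no sequences")
  mat <- align_right(upstreams, width)
  if (is.null(background)) {
    pooled <- table(factor(mat[mat %in% c("A", "C", "G", "T")],
                           levels = c("A", "C", "G", "T")))
    background <- as.numeric(pooled) / sum(pooled)
    names(background) <- c("A", "C", "G", "U")
  }
  background <- background[c("A", "C", "G", "U")]
  if (any(is.na(background)) || any(background <= 0)) {
    abort("background frequencies must be positive for all of A, C, G, U")
  }
  background <- background / sum(background)
  counts <- sapply(c("A", "C", "G", "T"), function(b) colSums(mat == b))
  n_site <- rowSums(counts)
  score <- sapply(1:4, function(j) {
    log2((counts[, j] + pseudocount * background[j]) /
           (n_site + pseudocount) / background[j])
  })
  out <- tibble::tibble(
    site = rep(seq_len(width), 4L),
    base = rep(c("A", "C", "G", "U"), each = width),
    score = as.vector(score)
  )
  attr(out, "background") <- background
  class(out) <- c("pwm_profile", class(out))
  out
}

#' @export
autoplot.pwm_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$site, y = .data$score,
                                       colour = .data$base)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "site (start codon at width+1..width+3)",
                  y = "PWM score (bits)", colour = NULL)
}

#' Likelihood-ratio G-test for C-vs-U avoidance
#'
#' Tests whether the C fraction among C+U nucleotides differs between two
#' gene groups over a window of upstream sites (classically the SD window,
#' sites 45-55). The statistic is `G = 2 * sum(O * ln(O/E))` over the 2x2
#' table with independence expectations, compared to chi-square with 1 df.
#'
#' @param c1,u1 C and U counts in group 1 (e.g. HEGs).
#' @param c2,u2 C and U counts in group 2 (e.g. REST genes).
#' @return One-row tibble: `statistic`, `df`, `p_value`,
#'   `percent_c_group1`, `percent_c_group2`.
#' @examples
#' c_vs_u_test(36, 129, 2952, 7069)
#' @export
c_vs_u_test <- function(c1, u1, c2, u2) {
  o <- matrix(c(c1, u1, c2, u2), nrow = 2, byrow = TRUE)
  if (any(o < 0)) abort("counts must be non-negative")
  if (any(rowSums(o) == 0) || any(colSums(o) == 0)) {
    abort("a zero row or column sum leaves the test undefined")
  }
  e <- outer(rowSums(o), colSums(o)) / sum(o)
  terms <- ifelse(o == 0, 0, o * log(o / e))
  g <- 2 * sum(terms)
  tibble::tibble(
    statistic = g, df = 1L,
    p_value = pchisq(g, df = 1L, lower.tail = FALSE),
    percent_c_group1 = 100 * c1 / (c1 + u1),
    percent_c_group2 = 100 * c2 / (c2 + u2)
  )
}

#' Count C and U in an upstream site window
#'
#' Helper feeding [c_vs_u_test()]: pools C and U(T) counts over a site range
#' of right-aligned upstream sequences (default the SD window 45-55).
#'
#' @param upstreams Character vector of upstream sequences.
#' @param sites Integer site range (1..width coordinates).
#' @param width Alignment width.
#' @return Named vector `c(C = ..., U = ...)`.
#' @export
count_c_u <- function(upstreams, sites = 45:55, width = 60L) {
  mat <- align_right(upstreams, width)[, sites, drop = FALSE]
  c(C = sum(mat == "C"), U = sum(mat == "T"))
}

SD_PAIRS <- c(AT = TRUE, TA = TRUE, GC = TRUE, CG = TRUE, GT = TRUE, TG = TRUE)

#' Distance from the SD match to the start codon
#'
#' Finds, within each upstream sequence, the best Watson-Crick + GU
#' antiparallel match of the anti-SD (aSD) sequence; the match score is the
#' longest run of consecutive pairs, ties resolved towards the start codon.
#' `d_to_start` is the number of nucleotides between the 3'-most paired
#' upstream base and the first base of the start codon. Matches shorter than
#' `min_match` consecutive pairs are reported as missing.
#'
#' @param upstreams Character vector of upstream sequences (5'->3', abutting
#'   the start codon at their 3' end).
#' @param asd aSD sequence, RNA alphabet. Interpreted per `orientation`:
#'   the default is the 3'-terminal core of the small-subunit rRNA written
#'   5'->3' (`"CCUCCUUA"`).
#' @param min_match Minimum consecutive-pair run to accept (default 4).
#' @param orientation `"5to3"` (default) or `"3to5"` for the aSD string.
#' @return Tibble with one row per upstream: `d_to_start`, `match_score`
#'   (run length), `match_end` (site index of the 3'-most paired base,
#'   counting from the start codon side).
#' @examples
#' d_to_start(paste0(strrep("A", 20), "AGGAGG", strrep("A", 7)),
#'            asd = "CCUCCU")
#' @export
d_to_start <- function(upstreams, asd = "CCUCCUUA", min_match = 4L,
                       orientation = c("5to3", "3to5")) {
  orientation <- match.arg(orientation)
  asd <- toupper(as_dna(asd))
  if (nchar(asd) < 4) abort("aSD must be at least 4 nt")
  if (orientation == "3to5") {
    asd <- paste(rev(strsplit(asd, "")[[1]]), collapse = "")
  }
  # antiparallel pairing: upstream 5'->3' pairs against the reversed aSD
  asd_rev <- rev(strsplit(asd, "")[[1]])
  m <- length(asd_rev)
  rows <- purrr::map(upstreams, function(up) {
    up <- toupper(as_dna(up))
    L <- nchar(up)
    bases <- strsplit(up, "")[[1]]
    best <- list(score = 0L, end = NA_integer_)
    if (L >= min_match) {
      for (off in seq_len(L - min_match + 1L)) {
        k_max <- min(m, L - off + 1L)
        paired <- vapply(seq_len(k_max), function(k) {
          isTRUE(SD_PAIRS[paste0(bases[off + k - 1L], asd_rev[k])])
        }, logical(1))
        runs <- rle(paired)
        if (!any(runs$values)) next
        run_ends <- cumsum(runs$lengths)
        ok <- which(runs$values)
        len <- runs$lengths[ok]
        ends <- off - 1L + run_ends[ok]
        j <- which(len == max(len))
        j <- j[which.max(ends[j])]
        if (len[j] > best$score ||
            (len[j] == best$score && !is.na(best$end) && ends[j] > best$end)) {
          best <- list(score = len[j], end = ends[j])
        }
      }
    }
    if (best$score < min_match) {
      tibble::tibble(d_to_start = NA_integer_, match_score = NA_integer_,
                     match_end = NA_integer_)
    } else {
      tibble::tibble(d_to_start = L - best$end, match_score = best$score,
                     match_end = best$end)
    }
  })
  dplyr::bind_rows(rows)
}
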
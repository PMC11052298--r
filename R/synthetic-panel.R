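# Synthetic genome panel generator.
#
# Emits annotated bacterial genomes (GenBank flat files) whose
# translation-related features follow the generative models the
# cross-species analysis assumes: rrn operon and tRNA gene counts decay
# exponentially to a floor with generation-time rank, start/stop codon
# preferences follow the per-class linear models (clamped to [0.01, 0.99]
# on the probability scale), HEG codon usage is skewed towards per-family
# optimal codons with a rank- and class-dependent selection strength, the
# tRNA anticodon pool is concentrated on cognates of optimal codons with a
# rank-dependent weight, and upstream regions carry an SD motif with
# class-dependent fidelity. A ground-truth manifest sufficient to recompute
# every expected summary statistic accompanies the sequences.

#' Synthetic panel configuration
#'
#' Defaults encode the study conditions of the nine-species reference
#' panel: ranks 1..9, the panel's genomic GC targets, machinery-count decay
#' parameters from least-squares fits of the reference counts, and the
#' published-form start/stop codon linear models. See the methods vignette
#' for the rationale behind each default.
#'
#' @param n_species Number of species (ranks 1..n).
#' @param gc Per-species genomic GC% targets (recycled to `n_species`).
#' @param genes_per_class Named vector `c(heg = ..., rest = ...)`.
#' @param rrn `list(a, b)`: operon count model `round(1 + a e^(-b r))`.
#' @param trna `list(c, a, b)`: tRNA count model `round(c + a e^(-b r))`.
#' @param start_model,stop_model Linear models on the percentage scale with
#'   per-class intercepts and rank/GC slopes.
#' @param selection `list(heg_max, heg_decay, rest_frac)`: per-codon
#'   probability of emitting the family's optimal codon,
#'   `s_heg(r) = max(0, heg_max - heg_decay (r - 1))`,
#'   `s_rest = rest_frac * s_heg`.
#' @param anticodon_conc `list(max, decay)`: probability that an extra tRNA
#'   gene carries its family's major anticodon.
#' @param structure_weaken `NULL` (off), or `list(threshold = c(heg, rest),
#'   max_tries)`: re-sample a gene's upstream background until the 40-nt
#'   window spanning the SD region and start codon folds no more stably
#'   than the class threshold (kcal/mol), giving highly expressed genes the
#'   weaker initiation-region structure the selection hypothesis predicts.
#'   Off by default (it multiplies generation cost by the folding step).
#' @param sd `list(motif, offset, jitter, fidelity = c(heg, rest))`:
#'   SD motif insertion into the upstream region, ending
#'   `offset (+/- jitter)` nt before the start codon, each motif base kept
#'   with the class's fidelity.
#' @param gene_length Range of in-frame CDS lengths in nt.
#' @param n_pseudo Pseudogenes per species (flagged `/pseudo`, REST-like).
#' @param minus_strand_prob Probability a CDS is placed on the minus strand.
#' @param seed Mandatory RNG seed.
#' @return A validated `panel_config` list.
#' @export
panel_config <- function(n_species = 9L,
                         gc = c(45.0, 47.3, 50.8, 43.5, 38.2, 67.4, 64.1,
                                65.6, 57.8),
                         genes_per_class = c(heg = 60L, rest = 600L),
                         rrn = list(a = 14.6, b = 0.27),
                         trna = list(c = 30, a = 130, b = 0.27),
                         start_model = list(intercept_heg = 125.86,
                                            intercept_rest = 116.68,
                                            rank = -2.54, gc = -0.52),
                         stop_model = list(intercept_heg = 197.95,
                                           intercept_rest = 180.60,
                                           rank = -3.78, gc = -2.22),
                         selection = list(heg_max = 0.70, heg_decay = 0.065,
                                          rest_frac = 0.35),
                         anticodon_conc = list(max = 0.80, decay = 0.075),
                         sd = list(motif = "AGGAGG", offset = 7L, jitter = 2L,
                                   fidelity = c(heg = 0.95, rest = 0.65)),
                         structure_weaken = NULL,
                         gene_length = c(300L, 1500L),
                         n_pseudo = 2L,
                         minus_strand_prob = 0.3,
                         seed) {
  if (missing(seed)) abort("seed is mandatory for a panel_config")
  cfg <- list(
    n_species = as.integer(n_species),
    gc = rep_len(gc, n_species),
    genes_per_class = genes_per_class,
    rrn = rrn, trna = trna,
    start_model = start_model, stop_model = stop_model,
    selection = selection, anticodon_conc = anticodon_conc, sd = sd,
    structure_weaken = structure_weaken,
    gene_length = as.integer(gene_length), n_pseudo = as.integer(n_pseudo),
    minus_strand_prob = minus_strand_prob, seed = as.integer(seed)
  )
  ranks <- seq_len(cfg$n_species)
  n_trna <- round(cfg$trna$c + cfg$trna$a * exp(-cfg$trna$b * ranks))
  if (any(n_trna < 20)) {
    abort("infeasible config: some species get fewer than 20 tRNA genes (one per amino-acid family)")
  }
  if (cfg$gene_length[1] < 9 || diff(cfg$gene_length) < 0) {
    abort("gene_length must be an increasing range of at least 9 nt")
  }
  structure(cfg, class = "panel_config")
}

clamp_prob <- function(p) pmin(0.99, pmax(0.01, p))

#' Generate a synthetic annotated genome panel
#'
#' Draws the panel under `config` (deterministically for a given config +
#' seed: identical calls produce byte-identical GenBank output) and writes
#' one GenBank file per species when `dir` is given.
#'
#' @param config A [panel_config()].
#' @param dir Output directory for GenBank files (created if needed);
#'   `NULL` skips writing and returns sequences in memory.
#' @return List with `files` (paths, or `NULL`), `records` (per-species
#'   list of sequence + feature tables) and `manifest` (list of tibbles:
#'   `species`, `genes`, `trna`, `optimal_codons`).
#' @export
generate_panel <- function(config, dir = NULL) {
  stopifnot(inherits(config, "panel_config"))
  set.seed(config$seed)
  fam <- codon_families()
  multi <- fam[fam$fold > 1, ]
  optimal <- multi |>
    dplyr::group_by(.data$amino_acid) |>
    dplyr::summarise(codon = sample(.data$codon, 1L), .groups = "drop")
  optimal <- dplyr::bind_rows(
    optimal,
    fam[fam$fold == 1, c("amino_acid", "codon")]
  ) |> dplyr::arrange(.data$amino_acid)

  if (!is.null(dir) && !dir.exists(dir)) dir.create(dir, recursive = TRUE)

  species_rows <- list(); gene_rows <- list(); trna_rows <- list()
  files <- character(0); records <- list()

  for (i in seq_len(config$n_species)) {
    sp <- sprintf("Synthbacter panelensis r%02d", i)
    acc <- sprintf("SYNPAN%02d", i)
    out <- generate_species(config, i, sp, acc, optimal)
    species_rows[[i]] <- out$species_row
    gene_rows[[i]] <- out$genes
    trna_rows[[i]] <- out$trna
    records[[sp]] <- out$record
    if (!is.null(dir)) {
      path <- file.path(dir, sprintf("%s.gbk", acc))
      write_genbank(acc, sp, out$record$sequence, out$record$features, path)
      files <- c(files, path)
    }
  }
  manifest <- list(
    species = dplyr::bind_rows(species_rows),
    genes = dplyr::bind_rows(gene_rows),
    trna = dplyr::bind_rows(trna_rows),
    optimal_codons = optimal
  )
  if (!is.null(dir)) {
    for (nm in names(manifest)) {
      readr::write_tsv(manifest[[nm]],
                       file.path(dir, sprintf("manifest_%s.tsv", nm)))
    }
  }
  list(files = if (is.null(dir)) NULL else files, records = records,
       manifest = manifest)
}

#' Generate a no-selection (null) panel
#'
#' Same generative process as [generate_panel()] but with codon selection
#' switched off (both classes draw codons from the GC-conditioned
#' background), no SD motif insertion, and equal class treatment — the
#' calibration input for null behaviour of DITE, PWM scores and MeanMFE
#' class differences.
#'
#' @inheritParams generate_panel
#' @return As [generate_panel()].
#' @export
null_panel <- function(config, dir = NULL) {
  config$selection <- list(heg_max = 0, heg_decay = 0, rest_frac = 0)
  config$sd$fidelity <- c(heg = 0, rest = 0)
  generate_panel(config, dir)
}

# -- internals ----------------------------------------------------------------

rand_bases <- function(n, gc) {
  p <- gc / 100
  sample(c("A", "C", "G", "T"), n, replace = TRUE,
         prob = c((1 - p) / 2, p / 2, p / 2, (1 - p) / 2))
}

generate_species <- function(config, i, sp, acc, optimal) {
  gc_t <- config$gc[i]
  n_heg <- as.integer(config$genes_per_class[["heg"]])
  n_rest <- as.integer(config$genes_per_class[["rest"]])
  n_rrn <- as.integer(round(1 + config$rrn$a * exp(-config$rrn$b * i)))
  n_trna <- as.integer(round(config$trna$c + config$trna$a * exp(-config$trna$b * i)))

  p_aug <- c(
    HEG = clamp_prob((config$start_model$intercept_heg +
                        config$start_model$rank * i +
                        config$start_model$gc * gc_t) / 100),
    REST = clamp_prob((config$start_model$intercept_rest +
                         config$start_model$rank * i +
                         config$start_model$gc * gc_t) / 100)
  )
  p_uaa <- c(
    HEG = clamp_prob((config$stop_model$intercept_heg +
                        config$stop_model$rank * i +
                        config$stop_model$gc * gc_t) / 100),
    REST = clamp_prob((config$stop_model$intercept_rest +
                         config$stop_model$rank * i +
                         config$stop_model$gc * gc_t) / 100)
  )
  s_heg <- max(0, config$selection$heg_max -
                 config$selection$heg_decay * (i - 1))
  s <- c(HEG = s_heg, REST = config$selection$rest_frac * s_heg)
  conc <- max(0.05, config$anticodon_conc$max -
                config$anticodon_conc$decay * (i - 1))

  n_genes <- n_heg + n_rest
  class <- c(rep("HEG", n_heg), rep("REST", n_rest))
  is_pseudo <- c(rep(FALSE, n_genes - config$n_pseudo),
                 rep(TRUE, config$n_pseudo))
  gene_name <- c(sprintf("rps%02d", seq_len(n_heg)),
                 sprintf("yfg%04d", seq_len(n_rest)))
  locus_tag <- sprintf("%s_G%04d", acc, seq_len(n_genes))
  strand <- ifelse(runif(n_genes) < config$minus_strand_prob, "-", "+")

  n_codons <- sample(seq(config$gene_length[1] %/% 3L,
                         config$gene_length[2] %/% 3L), n_genes,
                     replace = TRUE)
  start_codon <- unname(ifelse(runif(n_genes) < p_aug[class], "ATG",
                               ifelse(runif(n_genes) < 0.7, "GTG", "TTG")))
  stop_codon <- unname(ifelse(runif(n_genes) < p_uaa[class], "TAA",
                              ifelse(runif(n_genes) < 0.5, "TAG", "TGA")))

  bodies <- draw_codon_bodies(n_codons - 2L, s[class], gc_t, optimal)
  cds <- paste0(start_codon, bodies, stop_codon)

  sd_off <- config$sd$offset +
    sample(seq(-config$sd$jitter, config$sd$jitter), n_genes, replace = TRUE)
  sd_off <- pmax(0L, sd_off)
  fid <- config$sd$fidelity[tolower(class)]
  upstream <- make_upstreams(n_genes, gc_t, config$sd$motif, sd_off, fid)
  if (!is.null(config$structure_weaken)) {
    sw <- config$structure_weaken
    thr <- sw$threshold[tolower(class)]
    max_tries <- sw$max_tries %||% 15L
    for (g in seq_len(n_genes)) {
      if (!is.finite(thr[g])) next
      tries <- 0L
      repeat {
        win <- paste0(substr(upstream[g], 33L, 60L), substr(cds[g], 1L, 12L))
        if (fold_mfe(win) >= thr[g] || tries >= max_tries) break
        upstream[g] <- make_upstreams(1L, gc_t, config$sd$motif, sd_off[g],
                                      fid[g])
        tries <- tries + 1L
      }
    }
  }

  # assemble replicon: gene cassettes (up60 + CDS + down60), rrn operon
  # clusters, tRNA genes, separated by 20-nt spacers
  pieces <- character(0); feats <- list(); pos <- 0L
  add_piece <- function(seq) {
    pieces[[length(pieces) + 1L]] <<- seq
    pos <<- pos + nchar(seq)
  }
  spacer <- function() add_piece(paste(rand_bases(20L, gc_t), collapse = ""))

  for (g in seq_len(n_genes)) {
    spacer()
    down <- paste(rand_bases(60L, gc_t), collapse = "")
    cassette <- paste0(upstream[g], cds[g], down)
    L <- nchar(cds[g])
    cds_start <- pos + 61L
    cds_end <- pos + 60L + L
    add_piece(if (strand[g] == "-") revcomp(cassette) else cassette)
    quals <- list(gene = gene_name[g], locus_tag = locus_tag[g])
    if (is_pseudo[g]) quals$pseudo <- TRUE
    feats[[length(feats) + 1L]] <- tibble::tibble(
      key = "CDS", start = cds_start, end = cds_end, strand = strand[g],
      qualifiers = list(quals)
    )
  }

  for (r in seq_len(n_rrn)) {
    for (sub in c("16S", "23S", "5S")) {
      spacer()
      len <- c(`16S` = 120L, `23S` = 150L, `5S` = 80L)[[sub]]
      add_piece(paste(rand_bases(len, gc_t), collapse = ""))
      feats[[length(feats) + 1L]] <- tibble::tibble(
        key = "rRNA", start = pos - len + 1L, end = pos, strand = "+",
        qualifiers = list(list(
          product = paste(sub, "ribosomal RNA"),
          locus_tag = sprintf("%s_R%02d%s", acc, r, sub)
        ))
      )
    }
  }

  trna_pool <- draw_trna_pool(n_trna, conc, optimal)
  trna_tags <- sprintf("%s_T%03d", acc, seq_len(n_trna))
  for (t in seq_len(n_trna)) {
    spacer()
    add_piece(paste(rand_bases(76L, gc_t), collapse = ""))
    feats[[length(feats) + 1L]] <- tibble::tibble(
      key = "tRNA", start = pos - 75L, end = pos, strand = "+",
      qualifiers = list(list(
        product = paste0("tRNA-", trna_pool$amino_acid_name[t]),
        anticodon = sprintf("(pos:%d..%d,aa:%s,seq:%s)", pos - 41L, pos - 39L,
                            trna_pool$amino_acid_name[t],
                            tolower(as_rna(trna_pool$anticodon[t]))),
        locus_tag = trna_tags[t]
      ))
    )
  }
  spacer()

  list(
    record = list(sequence = paste(pieces, collapse = ""),
                  features = dplyr::bind_rows(feats)),
    species_row = tibble::tibble(
      species = sp, accession = acc, rank_gt = i, gc_target = gc_t,
      n_rrn = n_rrn, n_trna = n_trna,
      n_heg = n_heg, n_rest = n_rest, n_pseudo = config$n_pseudo,
      p_aug_heg = p_aug[["HEG"]], p_aug_rest = p_aug[["REST"]],
      p_uaa_heg = p_uaa[["HEG"]], p_uaa_rest = p_uaa[["REST"]],
      s_heg = s[["HEG"]], s_rest = s[["REST"]], anticodon_conc = conc
    ),
    genes = tibble::tibble(
      species = sp, locus_tag = locus_tag, gene = gene_name, class = class,
      is_pseudo = is_pseudo, strand = strand,
      start_codon = start_codon, stop_codon = stop_codon,
      n_codons = n_codons, sd_offset = sd_off
    ),
    trna = tibble::tibble(
      species = sp, locus_tag = trna_tags,
      amino_acid = trna_pool$amino_acid_name,
      anticodon = as_rna(trna_pool$anticodon)
    )
  )
}

# codon bodies: mixture of per-family optimal codon (probability s) and a
# GC-conditioned background draw, amino acids uniform
draw_codon_bodies <- function(n_codons, s, gc_t, optimal) {
  fam <- codon_families()
  bg <- gc_background(gc_t)
  aa_levels <- sort(unique(fam$amino_acid))
  total <- sum(n_codons)
  gene_idx <- rep.int(seq_along(n_codons), n_codons)
  aa <- sample(aa_levels, total, replace = TRUE)
  use_opt <- runif(total) < rep.int(s, n_codons)
  codons <- character(total)
  opt_of <- setNames(optimal$codon, optimal$amino_acid)
  for (a in aa_levels) {
    idx <- which(aa == a)
    if (!length(idx)) next
    fam_codons <- bg$codon[bg$amino_acid == a]
    fam_p <- bg$rel_freq[bg$amino_acid == a]
    codons[idx] <- sample(fam_codons, length(idx), replace = TRUE, prob = fam_p)
    opt_idx <- idx[use_opt[idx]]
    codons[opt_idx] <- opt_of[[a]]
  }
  vapply(split(codons, gene_idx), paste, character(1), collapse = "")
}

make_upstreams <- function(n, gc_t, motif, offset, fidelity) {
  m <- nchar(motif)
  motif_chars <- strsplit(motif, "")[[1]]
  vapply(seq_len(n), function(g) {
    up <- rand_bases(60L, gc_t)
    end_pos <- 60L - offset[g]
    start_pos <- end_pos - m + 1L
    if (start_pos >= 1L && fidelity[g] > 0) {
      keep <- runif(m) < fidelity[g]
      up[start_pos:end_pos][keep] <- motif_chars[keep]
    }
    paste(up, collapse = "")
  }, character(1))
}

# tRNA pool with a rank-dependent anticodon skew. Family sizes are spread
# as evenly as round-robin allows; within a family of n genes,
# 1 + round(conc * (n - 1)) copies carry the major anticodon (the
# Watson-Crick partner of the family's optimal codon) and the remainder
# cycle through the family's other anticodons. High concentration thus
# piles copies on the major anticodon (low effective number), low
# concentration covers the anticodon repertoire evenly.
draw_trna_pool <- function(n_trna, conc, optimal) {
  fam <- codon_families()
  aa_names <- setNames(names(AA_THREE)[match(sort(unique(fam$amino_acid)),
                                             AA_THREE)],
                       sort(unique(fam$amino_acid)))
  aa_names <- aa_names[!duplicated(names(aa_names))]
  major <- setNames(revcomp(optimal$codon), optimal$amino_acid)
  aa_levels <- names(major)
  # even family sizes: one base gene each, extras round-robin in random order
  sizes <- setNames(rep(1L, length(aa_levels)), aa_levels)
  extra <- n_trna - length(aa_levels)
  if (extra > 0) {
    add <- rep(sample(aa_levels), length.out = extra)
    tab <- table(add)
    sizes[names(tab)] <- sizes[names(tab)] + as.integer(tab)
  }
  aa <- character(0); anticodon <- character(0)
  for (a in aa_levels) {
    n_f <- sizes[[a]]
    others <- setdiff(revcomp(fam$codon[fam$amino_acid == a]), major[[a]])
    m <- min(n_f, 1L + as.integer(round(conc * (n_f - 1L))))
    acs <- c(rep(major[[a]], m),
             if (n_f > m && length(others)) {
               rep(others, length.out = n_f - m)
             } else {
               rep(major[[a]], n_f - m)
             })
    aa <- c(aa, rep(a, n_f))
    anticodon <- c(anticodon, acs)
  }
  tibble::tibble(
    amino_acid = aa,
    amino_acid_name = unname(aa_names[aa]),
    anticodon = anticodon
  )
}
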
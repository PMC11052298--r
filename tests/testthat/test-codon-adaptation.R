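# Codon usage tables, I_TE weights and scores, DITE, and the effective
# number of codons / anticodons.

test_that("codon counting excludes start and stop and groups families", {
  tb <- codon_frequencies("ATGAAAAAGTAA")
  expect_equal(sum(tb$count), 2L)
  expect_equal(tb$count[tb$codon == "AAA"], 1L)
  expect_equal(tb$count[tb$codon == "AAG"], 1L)
  expect_equal(tb$rel_freq[tb$codon == "AAA"], 0.5)
  tb2 <- codon_frequencies(rep("ATGAAAAAGTAA", 2))
  expect_equal(tb2$count[tb2$codon == "AAA"], 2L)
  expect_warning(codon_frequencies(c("ATGAAAT", "ATGAAAAAGTAA")), "skipped")
  # within-family relative frequencies sum to 1 for non-empty families
  sums <- tapply(tb$rel_freq, tb$amino_acid, sum)
  expect_true(all(abs(sums[!is.na(sums)] - 1) < 1e-12))
})

test_that("sampled codon sets recover their generating distribution", {
  set.seed(31)
  bg <- gc_background(55)
  lys <- bg[bg$amino_acid == "K", ]
  draws <- sample(lys$codon, 1e5, replace = TRUE, prob = lys$rel_freq)
  gene <- paste0("ATG", paste(draws, collapse = ""), "TAA")
  tb <- codon_frequencies(gene)
  got <- tb$rel_freq[match(lys$codon, tb$codon)]
  expect_true(all(abs(got - lys$rel_freq) < 0.01))
})

test_that("I_TE weights are background-relative and family-normalised", {
  # no selection signal: HEG usage equal to background -> all weights 1
  heg <- codon_frequencies(paste0("ATG", strrep("AAAAAG", 50), "TAA"))
  w0 <- suppressWarnings(ite_weights(heg, heg))
  expect_true(all(w0$weight == 1))
  # 2-codon family at (0.8, 0.2) vs uniform background -> weights (1, ~0.25)
  gene <- paste0("ATG", strrep("AAA", 8000), strrep("AAG", 2000), "TAA")
  w <- suppressWarnings(ite_weights(codon_frequencies(gene), 50))
  expect_equal(w$weight[w$codon == "AAA"], 1)
  expect_equal(w$weight[w$codon == "AAG"], 0.25, tolerance = 2e-3)
  # per-family maximum is exactly 1 (normalisation invariant)
  sp <- shared_panel()
  g <- sp$genomes[[1]]
  wfit <- ite_weights(codon_frequencies(class_genes(g, "HEG")$cds),
                      g$gc_percent)
  fam_max <- tapply(wfit$weight, wfit$amino_acid, max)
  expect_true(all(abs(fam_max - 1) < 1e-12))
})

test_that("weight argmax identifies the generator's optimal codons", {
  sp <- shared_panel()
  g <- sp$genomes[[1]]  # rank 1: strongest selection
  w <- ite_weights(codon_frequencies(class_genes(g, "HEG")$cds), g$gc_percent)
  multi <- w[w$fold > 1, ]
  argmax <- do.call(rbind, lapply(split(multi, multi$amino_acid), function(d) {
    d[which.max(d$weight), ]
  }))
  opt <- sp$panel$manifest$optimal_codons
  hit <- mean(argmax$codon == opt$codon[match(argmax$amino_acid,
                                              opt$amino_acid)])
  expect_gte(hit, 0.95)
})

test_that("gene I_TE is the geometric mean over scorable codons", {
  fam <- codon_families()
  w <- tibble::tibble(codon = fam$codon, amino_acid = fam$amino_acid,
                      fold = fam$fold, weight = 1)
  expect_equal(gene_ite("ATGAAAAAGTAA", w), 1)
  w$weight[w$codon == "AAA"] <- 0.25
  expect_equal(gene_ite("ATGAAAAAGTAA", w), 0.5)  # sqrt(0.25 * 1)
  # Met/Trp (and the start codon) never contribute
  expect_true(is.na(gene_ite("ATGATGTGGTAA", w)))
})

test_that("DITE is the class-mean difference and is antisymmetric", {
  expect_equal(dite(c(0.5, 0.5), c(0.3, 0.3)), 0.2)
  set.seed(8)
  a <- runif(20); b <- runif(30)
  expect_equal(dite(a, b), -dite(b, a))
  expect_error(dite(numeric(0), b), "both expression classes")
})

test_that("DITE declines with rank on selection panels", {
  summ <- shared_panel()$summary
  sp_level <- summ[summ$class == "HEG", ]
  expect_lt(cor(sp_level$rank_gt, sp_level$dite, method = "spearman"), 0)
  expect_true(all(sp_level$dite > 0))
})

test_that("effective number hits the minimal- and maximal-diversity anchors", {
  fam <- codon_families()
  # one unit type per family, arbitrary copy numbers -> F = 1 -> 20
  one_per <- unlist(lapply(split(fam$codon, fam$amino_acid), function(cs) {
    rep(cs[1], 3)
  }))
  en <- effective_number(one_per)
  expect_equal(en$effective_number, 20)
  # uniform usage of all 61 sense codons, large n -> 61 (clamped)
  uniform <- rep(fam$codon, each = 100)
  expect_warning(en61 <- effective_number(uniform), "clamped")
  expect_equal(en61$effective_number, 61)
})

test_that("effective number matches a directly-coded oracle on random pools", {
  # independent route: straight tapply computation of Wright's formula
  enc_direct <- function(units, aa) {
    fams <- split(units, aa)
    fold <- table(codon_families()$amino_acid)
    f_by_class <- list(`2` = c(), `3` = c(), `4` = c(), `6` = c())
    for (a in names(fams)) {
      k <- as.integer(fold[[a]])
      if (k == 1) next
      u <- fams[[a]]; n <- length(u)
      if (n <= 1) next
      p <- as.numeric(table(u)) / n
      f <- (n * sum(p^2) - 1) / (n - 1)
      if (f <= 0) next
      f_by_class[[as.character(k)]] <- c(f_by_class[[as.character(k)]], f)
    }
    fb <- vapply(f_by_class, function(v) if (length(v)) mean(v) else NA_real_,
                 numeric(1))
    for (i in seq_along(fb)) {
      if (is.na(fb[i])) {
        nb <- fb[setdiff(c(i - 1, i + 1), c(0, 5))]
        nb <- nb[!is.na(nb)]
        fb[i] <- if (length(nb)) mean(nb) else mean(fb, na.rm = TRUE)
      }
    }
    min(61, 2 + 9 / fb[["2"]] + 1 / fb[["3"]] + 5 / fb[["4"]] + 3 / fb[["6"]])
  }
  fam <- codon_families()
  aa_of <- setNames(fam$amino_acid, fam$codon)
  set.seed(17)
  for (rep in 1:20) {
    n <- sample(45:130, 1)
    units <- sample(fam$codon, n, replace = TRUE)
    aa <- unname(aa_of[units])
    got <- suppressWarnings(effective_number(units, amino_acids = aa))
    expect_equal(got$effective_number, enc_direct(units, aa),
                 tolerance = 1e-9)
    # relabeling units within families leaves the result unchanged
    relabel <- setNames(paste0("u", seq_along(unique(units))), unique(units))
    got2 <- suppressWarnings(
      effective_number(unname(relabel[units]), amino_acids = aa)
    )
    expect_equal(got2$effective_number, got$effective_number)
    # duplicating the pool only acts through the n-correction
    dup <- suppressWarnings(
      effective_number(c(units, units), amino_acids = c(aa, aa))
    )
    expect_equal(dup$effective_number,
                 enc_direct(c(units, units), c(aa, aa)), tolerance = 1e-9)
  }
})

test_that("anticodon pools from the generator order N_AC by rank", {
  sp <- shared_panel()
  nac <- vapply(sp$genomes, function(g) {
    suppressWarnings(trna_effective_number(g))$effective_number
  }, numeric(1))
  expect_gt(cor(seq_along(nac), nac, method = "spearman"), 0)
})

test_that("tRNA genes without anticodons are skipped with a warning", {
  g <- shared_panel()$genomes[[1]]
  g$trna$anticodon[1] <- NA_character_
  expect_warning(trna_effective_number(g), "skipped")
})
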
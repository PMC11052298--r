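# Start codon usage, upstream frequency/PWM profiles, the C-vs-U G-test and
# the SD-to-start distance.

test_that("start codon usage reproduces reference HEG rows", {
  # 71 AUG of 76 starts
  tb <- start_codon_usage(c(rep("AUG", 71), rep("GUG", 3), rep("UUG", 2)))
  expect_equal(tb$n, 76L)
  expect_equal(round(tb$aug_percent, 2), 93.42)
  tb2 <- start_codon_usage(c(rep("ATG", 68), "GTG", "CTG"))
  expect_equal(round(tb2$aug_percent, 2), 97.14)
  expect_equal(start_codon_usage(rep("AUG", 10))$aug_percent, 100)
  expect_error(start_codon_usage(character(0)), "empty")
})

test_that("start codon categories sum to n and are permutation-invariant", {
  set.seed(4)
  codons <- sample(c("ATG", "GTG", "TTG", "CTG", "ATA", "ATC", "ATT", "AAA"),
                   200, replace = TRUE)
  tb <- start_codon_usage(codons)
  expect_equal(tb$AUG + tb$GUG + tb$YUG + tb$AUH + tb$other, tb$n)
  expect_equal(start_codon_usage(rev(codons)), tb)
})

test_that("positional frequencies right-align and normalise per site", {
  ups <- c("GA", "GC", "GG", "AT")  # site 59 = {G,G,G,A}, site 60 = {A,C,G,T}
  pf <- positional_frequencies(ups)
  expect_equal(pf$freq[pf$site == 59 & pf$base == "G"], 0.75)
  expect_equal(sum(pf$freq[pf$site == 60]), 1)
  expect_equal(unique(pf$n[pf$site < 59]), 0L)  # uncovered sites
  ident <- positional_frequencies(rep(strrep("ACGT", 15), 5))
  maxes <- tapply(ident$freq, ident$site, max)
  expect_true(all(maxes == 1))
  expect_error(positional_frequencies(character(0)), "no sequences")
})

test_that("SD G-enrichment from the generator lands in the expected sites", {
  g <- shared_panel()$genomes[[1]]
  ups <- class_genes(g, "HEG")$upstream
  pf <- positional_frequencies(ups)
  gfreq <- pf[pf$base == "G", ]
  peak <- gfreq$site[which.max(gfreq$freq)]
  expect_gte(peak, 46)
  expect_lte(peak, 55)
})

test_that("PWM scores are zero at background and hit the log-odds limit", {
  # each site sees exactly one A, C, G, T: usage equals pooled background
  ups <- c(strrep("A", 60), strrep("C", 60), strrep("G", 60), strrep("T", 60))
  pw <- pwm_scores(ups)
  expect_true(all(abs(pw$score) < 1e-12))
  # all-G sites against uniform background, vanishing pseudocount -> 2 bits
  pw2 <- pwm_scores(rep(strrep("G", 60), 1000),
                    background = c(A = 0.25, C = 0.25, G = 0.25, U = 0.25),
                    pseudocount = 1e-9)
  expect_equal(max(pw2$score), 2, tolerance = 1e-6)
  expect_error(pwm_scores("ACGT", background = c(A = 0, C = 0.5, G = 0.25,
                                                 U = 0.25)),
               "positive")
})

test_that("PWM scores of background-drawn samples stay within the MC bound", {
  set.seed(2024)
  ups <- vapply(1:1000, function(i) {
    paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE), collapse = "")
  }, character(1))
  pw <- pwm_scores(ups)
  expect_lt(max(abs(pw$score)), 0.3)
})

test_that("the C-vs-U G-test matches an entropy-based oracle and is symmetric", {
  g_entropy <- function(o) {
    # G = 2 n (H(rows) + H(cols) - H(cells)), an algebraically different route
    n <- sum(o)
    H <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
    2 * n * (H(rowSums(o) / n) + H(colSums(o) / n) - H(o / n))
  }
  set.seed(7)
  for (rep in 1:25) {
    o <- matrix(sample(1:50, 4, replace = TRUE), 2)
    got <- c_vs_u_test(o[1, 1], o[1, 2], o[2, 1], o[2, 2])
    expect_lt(abs(got$statistic - g_entropy(o)), 1e-10)
    # row and column swaps leave G unchanged
    swapped <- c_vs_u_test(o[2, 1], o[2, 2], o[1, 1], o[1, 2])
    expect_equal(swapped$statistic, got$statistic, tolerance = 1e-12)
    cols <- c_vs_u_test(o[1, 2], o[1, 1], o[2, 2], o[2, 1])
    expect_equal(cols$statistic, got$statistic, tolerance = 1e-12)
  }
  # identical proportions give exactly zero
  expect_equal(c_vs_u_test(10, 30, 100, 300)$statistic, 0)
  expect_error(c_vs_u_test(0, 0, 5, 5), "zero row")
})

test_that("count_c_u pools the SD window", {
  ups <- rep(paste0(strrep("A", 44), "CCCUUUUUAAA", strrep("A", 5)), 2)
  cu <- count_c_u(ups)  # sites 45-55 hold CCCUUUUUAAA minus last 3 A
  expect_equal(unname(cu["C"]), 6L)
  expect_equal(unname(cu["U"]), 10L)
})

test_that("d_to_start finds the aSD match and its distance", {
  up <- paste0(strrep("A", 47), "AGGAGG", strrep("A", 7))
  hit <- d_to_start(up, asd = "CCUCCU")
  expect_equal(hit$d_to_start, 7L)
  expect_equal(hit$match_score, 6L)
  # no complementary run of 4 or more -> missing
  miss <- d_to_start(strrep("A", 60), asd = "CCUCCU")
  expect_true(is.na(miss$d_to_start))
  expect_error(d_to_start(up, asd = "CCU"), "at least 4")
  # GU wobble pairs count towards the run (U in the message pairs G in aSD)
  up_gu <- paste0(strrep("A", 49), "TTTT", strrep("A", 7))
  hit_gu <- d_to_start(up_gu, asd = "GGGG")
  expect_equal(hit_gu$match_score, 4L)
  expect_equal(hit_gu$d_to_start, 7L)
})

test_that("generator SD placement sets the modal d_to_start", {
  cfg <- panel_config(n_species = 1, genes_per_class = c(heg = 60L, rest = 5L),
                      gene_length = c(150L, 300L),
                      sd = list(motif = "AGGAGG", offset = 8L, jitter = 0L,
                                fidelity = c(heg = 1, rest = 0.5)),
                      seed = 7)
  p <- generate_panel(cfg)
  g <- classify_expression(
    read_genbank(write_panel_record(p, 1), rank_gt = 1)
  )
  dd <- d_to_start(class_genes(g, "HEG")$upstream)
  modal <- as.integer(names(which.max(table(dd$d_to_start))))
  expect_equal(modal, 8L)
})
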
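# MFE folding engine, sliding-window profiles, aggregation and MeanMFE.

test_that("folding contract: no pairs means zero, energies never positive", {
  expect_equal(fold_mfe(strrep("A", 40)), 0)
  expect_equal(fold_mfe("ACG"), 0)  # below the minimum foldable length
  set.seed(42)
  seqs <- vapply(1:25, function(i) {
    paste(sample(c("A", "C", "G", "U"), 40, replace = TRUE), collapse = "")
  }, character(1))
  mfe <- fold_mfe(seqs)
  expect_true(all(mfe <= 0))
  expect_true(all(fold_mfe(revcomp(seqs)) <= 0))
  # deterministic
  expect_identical(fold_mfe(seqs), mfe)
  # T and U are equivalent; ambiguity codes are unpairable
  expect_equal(fold_mfe("GGGGGAAAAACCCCC"), fold_mfe("GGGGGAAAAACCCCC"))
  expect_equal(fold_mfe(chartr("U", "T", seqs[1])), mfe[1])
  expect_equal(fold_mfe(strrep("N", 40)), 0)
})

test_that("the dynamic program matches exhaustive enumeration on short RNA", {
  set.seed(5)
  for (rep in 1:40) {
    L <- sample(8:16, 1)
    s <- paste(sample(c("A", "C", "G", "U"), L, replace = TRUE,
                      prob = c(0.2, 0.3, 0.3, 0.2)), collapse = "")
    expect_equal(fold_mfe(s), oracle_mfe(s), tolerance = 1e-9)
  }
})

test_that("the vienna engine is usable and agrees on the trivial cases", {
  v <- fold_mfe(c(strrep("A", 40), "GGGGGGGGGGAAAAACCCCCCCCCC"),
                engine = "vienna")
  expect_equal(v[1], 0)
  expect_lt(v[2], -10)
  expect_identical(v, fold_mfe(c(strrep("A", 40),
                                 "GGGGGGGGGGAAAAACCCCCCCCCC"),
                               engine = "vienna"))
})

test_that("sliding windows count L - 39 and mid sites anchor at start + 19", {
  p <- sliding_mfe(strrep("AC", 50))  # L = 100
  expect_equal(nrow(p), 61L)
  expect_equal(p$mid_site, 20:80)
  flat <- sliding_mfe(strrep("A", 80))
  expect_true(all(flat$mfe == 0))
  expect_warning(short <- sliding_mfe(strrep("A", 30)), "empty profile")
  expect_equal(nrow(short), 0L)
})

test_that("a planted hairpin pulls the profile minimum to its position", {
  set.seed(12)
  bases <- rep("A", 121)
  hairpin <- strsplit("GGGGGGGGGGCAACCCCCCCCCC", "")[[1]]  # centred 10-bp stem
  centre <- 60
  bases[(centre - 11):(centre + 11)] <- hairpin
  prof <- sliding_mfe(paste(bases, collapse = ""))
  expect_lt(min(prof$mfe), -10)
  # windows fully containing the stem tie at the minimum; take their centre
  best <- mean(prof$mid_site[prof$mfe == min(prof$mfe)])
  expect_lte(abs(best - centre), 5)
})

test_that("aggregation gives per-site means with symmetric 95% limits", {
  prof <- tibble::tibble(
    locus_tag = rep(c("a", "b"), each = 3),
    mid_site = rep(20:22, 2),
    mfe = c(0, 0, 0, -2, -2, -2)
  )
  agg <- aggregate_profiles(prof)
  expect_equal(agg$mean_mfe, rep(-1, 3))
  expect_equal(agg$ul - agg$mean_mfe, agg$mean_mfe - agg$ll)
  ident <- aggregate_profiles(tibble::tibble(
    locus_tag = rep(c("a", "b"), each = 2),
    mid_site = rep(1:2, 2), mfe = rep(-3, 4)
  ))
  expect_equal(ident$ll, ident$mean_mfe)
  expect_equal(ident$ul, ident$mean_mfe)
  expect_error(aggregate_profiles(prof[prof$locus_tag == "a", ]),
               "at least 2")
  # recomputation oracle: plain column means
  set.seed(3)
  many <- tibble::tibble(
    locus_tag = rep(sprintf("g%02d", 1:76), each = 5),
    mid_site = rep(20:24, 76),
    mfe = -runif(380, 0, 8)
  )
  agg2 <- aggregate_profiles(many)
  direct <- tapply(many$mfe, many$mid_site, mean)
  expect_equal(agg2$mean_mfe, as.numeric(direct), tolerance = 1e-12)
  # ordering invariance
  shuffled <- many[sample(nrow(many)), ]
  expect_equal(aggregate_profiles(shuffled)$mean_mfe, agg2$mean_mfe)
})

test_that("MeanMFE summarises mid-window sites 46-65", {
  flat <- tibble::tibble(mid_site = 20:101, mean_mfe = -4, ll = -4, ul = -4,
                         n = 10)
  class(flat) <- c("mfe_profile_agg", class(flat))
  expect_equal(mean_mfe_summary(flat), -4)
  ramp <- tibble::tibble(mid_site = 46:65, mean_mfe = -(46:65) / 10,
                         ll = 0, ul = 0, n = 10)
  expect_equal(mean_mfe_summary(ramp), -5.55)
  expect_error(mean_mfe_summary(ramp[1:10, ]), "does not cover")
})

test_that("structure scans assemble the anchor windows and exclude short genes", {
  g <- shared_panel()$genomes[[1]]
  prof <- suppressMessages(structure_profiles(g, "HEG", anchor = "start"))
  # 121-nt scan: mid sites 20..101 for every included gene
  sites <- tapply(prof$mid_site, prof$locus_tag, function(s) range(s))
  expect_true(all(vapply(sites, identical, logical(1), c(20L, 101L))))
  stopp <- suppressMessages(structure_profiles(g, "HEG", anchor = "stop"))
  expect_true(all(tapply(stopp$mid_site, stopp$locus_tag, max) == 100L))
})

test_that("structure-weakened HEGs show the weaker initiation structure", {
  cfg <- panel_config(
    n_species = 1, genes_per_class = c(heg = 25L, rest = 25L),
    gene_length = c(300L, 600L),
    structure_weaken = list(threshold = c(heg = -4, rest = -Inf),
                            max_tries = 25),
    seed = 21
  )
  p <- generate_panel(cfg)
  g <- classify_expression(read_genbank(write_panel_record(p, 1),
                                        rank_gt = 1))
  m_heg <- mean_mfe_summary(aggregate_profiles(
    suppressMessages(structure_profiles(g, "HEG"))
  ))
  m_rest <- mean_mfe_summary(aggregate_profiles(
    suppressMessages(structure_profiles(g, "REST"))
  ))
  expect_lte(m_heg, 0)
  expect_gt(m_heg, m_rest)
})
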
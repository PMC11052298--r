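# GenBank parsing: locations, strands, qualifiers, round trips, and an
# independent cross-check against biopython.

make_test_record <- function() {
  set.seed(99)
  seqv <- sample(c("A", "C", "G", "T"), 300, replace = TRUE)
  # plant a known minus-strand CDS at 101..160 and a plus CDS at 11..31
  seqv[101:160] <- strsplit(revcomp(paste0(
    "ATG", strrep("GAT", 18), "TAA"
  )), "")[[1]]
  seqv[11:31] <- strsplit("ATGAAACCCGGGTTTACGTAA", "")[[1]]
  seq <- paste(seqv, collapse = "")
  feats <- tibble::tibble(
    key = c("CDS", "CDS", "CDS", "tRNA", "tRNA", "rRNA", "rRNA", "rRNA"),
    start = c(11L, 101L, 200L, 170L, 180L, 210L, 230L, 250L),
    end = c(31L, 160L, 220L, 178L, 188L, 215L, 235L, 255L),
    strand = c("+", "-", "+", "+", "+", "+", "+", "+"),
    qualifiers = list(
      list(gene = "rpsA", locus_tag = "T1"),
      list(gene = "yaaB", locus_tag = "T2"),
      list(gene = "yaaC", locus_tag = "T3", pseudo = TRUE),
      list(product = "tRNA-Leu", locus_tag = "T4",
           anticodon = "(pos:172..174,aa:Leu,seq:caa)"),
      list(product = "tRNA-Met", locus_tag = "T5",
           anticodon = "(pos:182..184,aa:Met,seq:cau)"),
      list(product = "16S ribosomal RNA", locus_tag = "T6"),
      list(product = "23S ribosomal RNA", locus_tag = "T7"),
      list(product = "5S ribosomal RNA", locus_tag = "T8")
    )
  )
  path <- tempfile(fileext = ".gbk")
  write_genbank("TESTREC1", "test record", seq, feats, path)
  list(path = path, seq = seq)
}

test_that("a single-record file parses with all feature classes extracted", {
  rec <- make_test_record()
  g <- read_genbank(rec$path)
  expect_equal(nrow(g$genes), 3L)
  expect_equal(sum(g$genes$is_pseudo), 1L)
  expect_equal(nrow(g$trna), 2L)
  expect_equal(nrow(g$rrna), 3L)
  expect_equal(g$n_cds, 2L)
  expect_equal(g$genome_length, 300L)
  expect_equal(g$rrn_count, 1L)
  expect_equal(g$trna$anticodon, c("CAA", "CAU"))
  expect_equal(g$trna$amino_acid, c("Leu", "Met"))
})

test_that("minus-strand CDS equals the reverse complement of its slice", {
  rec <- make_test_record()
  g <- read_genbank(rec$path)
  minus <- g$genes[g$genes$locus_tag == "T2", ]
  expect_equal(minus$strand, "-")
  expect_equal(minus$cds, revcomp(substr(rec$seq, 101, 160)))
  expect_equal(minus$start_codon, "ATG")
  expect_equal(minus$stop_codon, "TAA")
  # involution: re-deriving the plus-strand slice from the stored CDS
  expect_equal(revcomp(minus$cds), substr(rec$seq, 101, 160))
  # strand-aware upstream abuts the start codon on the sense strand
  expect_equal(minus$upstream, revcomp(substr(rec$seq, 161, 220)))
  plus <- g$genes[g$genes$locus_tag == "T1", ]
  expect_equal(plus$cds, substr(rec$seq, 11, 31))
  expect_equal(nchar(plus$upstream), 10L)  # replicon edge: shorter than 60
})

test_that("compound join and complement(join) locations are resolved", {
  loc <- parse_gb_location("join(11..31,41..52)")
  expect_equal(loc$strand, "+")
  expect_equal(loc$segments$start, c(11L, 41L))
  loc2 <- parse_gb_location("complement(join(11..31,41..52))")
  expect_equal(loc2$strand, "-")
  seq <- strrep("ACGT", 20)
  expect_equal(extract_feature_seq(seq, loc2),
               revcomp(paste0(substr(seq, 11, 31), substr(seq, 41, 52))))
  expect_true(parse_gb_location("<11..>31")$partial)
  expect_error(parse_gb_location("11..x"), "cannot parse")
})

test_that("generated panels round-trip: parsed features equal the manifest", {
  sp <- shared_panel()
  m <- sp$panel$manifest
  for (i in seq_along(sp$genomes)) {
    g <- sp$genomes[[i]]
    mg <- m$genes[m$genes$species == g$meta$species, ]
    pg <- g$genes[match(mg$locus_tag, g$genes$locus_tag), ]
    expect_false(anyNA(pg$cds))
    expect_equal(pg$start_codon, mg$start_codon)
    expect_equal(pg$stop_codon, mg$stop_codon)
    expect_equal(pg$strand, mg$strand)
    expect_equal(pg$is_pseudo, mg$is_pseudo)
    expect_equal(nchar(pg$cds), 3L * mg$n_codons)
    ms <- m$species[m$species$species == g$meta$species, ]
    expect_equal(g$rrn_count, ms$n_rrn)
    expect_equal(g$trna_count, ms$n_trna)
    mt <- m$trna[m$trna$species == g$meta$species, ]
    expect_equal(g$trna$anticodon[match(mt$locus_tag, g$trna$locus_tag)],
                 mt$anticodon)
  }
})

test_that("biopython extracts identical CDS sequences from our GenBank", {
  cfg <- panel_config(n_species = 1, genes_per_class = c(heg = 5L, rest = 10L),
                      gene_length = c(150L, 300L), seed = 13)
  dir <- file.path(tempdir(), "bio-oracle")
  p <- generate_panel(cfg, dir)
  script <- tempfile(fileext = ".py")
  writeLines(c(
    "import sys",
    "from Bio import SeqIO",
    "rec = SeqIO.read(sys.argv[1], 'genbank')",
    "for f in rec.features:",
    "    if f.type == 'CDS':",
    "        tag = f.qualifiers['locus_tag'][0]",
    "        print(tag, f.location.strand, f.extract(rec.seq))"
  ), script)
  out <- system2("python", c(script, p$files[1]), stdout = TRUE)
  fields <- strsplit(out, " ")
  g <- read_genbank(p$files[1])
  for (f in fields) {
    row <- g$genes[g$genes$locus_tag == f[1], ]
    expect_equal(row$strand, if (f[2] == "1") "+" else "-")
    expect_equal(row$cds, f[3])
  }
  expect_equal(length(fields), nrow(g$genes))
})

test_that("gc_percent follows the ambiguity-exclusion convention", {
  expect_equal(gc_percent("GCGC"), 100)
  expect_equal(gc_percent("ATGC"), 50)
  expect_equal(gc_percent("ATGCN"), 50)
  expect_equal(gc_percent(c("AT", "GC")), 50)  # pooled
  expect_error(gc_percent("NNNN"), "no unambiguous")
  expect_error(gc_percent(""), "empty")
})
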
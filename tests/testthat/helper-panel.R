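# Shared synthetic-panel fixture, generated once per test run. Constant GC
# across species isolates the rank effect for the direction properties.

panel_cache <- new.env(parent = emptyenv())

shared_panel <- function() {
  if (is.null(panel_cache$panel)) {
    cfg <- panel_config(n_species = 6, gc = 50,
                        genes_per_class = c(heg = 15L, rest = 60L),
                        gene_length = c(300L, 600L), seed = 101)
    dir <- file.path(tempdir(), "transelect-shared-panel")
    p <- generate_panel(cfg, dir)
    genomes <- lapply(seq_along(p$files), function(i) {
      classify_expression(read_genbank(p$files[i], rank_gt = i))
    })
    summary_tb <- dplyr::bind_rows(
      lapply(genomes, summarize_genome, mfe = FALSE)
    )
    panel_cache$panel <- list(cfg = cfg, panel = p, genomes = genomes,
                              summary = summary_tb)
  }
  panel_cache$panel
}

# serialise one in-memory panel record to a temporary GenBank file
write_panel_record <- function(p, i) {
  sp <- p$manifest$species
  rec <- p$records[[sp$species[i]]]
  path <- tempfile(fileext = ".gbk")
  write_genbank(sp$accession[i], sp$species[i], rec$sequence, rec$features,
                path)
  path
}

# exact-binomial analogue of a "within 3 SDs" check, valid when p is near
# 0 or 1 and the normal approximation breaks down
binom_within <- function(successes, n, p, alpha = 0.001) {
  stats::binom.test(successes, n, p)$p.value > alpha
}
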
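# Shared fixtures, built once per test run.  Problem sizes are kept small
# (a handful of multi-exon genes per genome) so the whole suite stays fast
# while still exercising multi-exon splicing, both strands and the
# inverted-order fusion architecture.

# A tiny hand-made genome with fully controlled sequences: one plus- and one
# minus-strand 3-exon gene (short exons so reads cross internal junctions),
# plus a 2-exon gene on a second chromosome.
tiny_fixture <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    set.seed(424243)
    g1 <- paste(sample(c("A", "C", "G", "T"), 1200, TRUE), collapse = "")
    g2 <- paste(sample(c("A", "C", "G", "T"), 900, TRUE), collapse = "")
    genome <- c(c1 = g1, c2 = g2)
    exons <- data.frame(
      gene_id = c("GA", "GA", "GA", "GB", "GB", "GB", "GC", "GC"),
      transcript_id = c(rep("GA.t1", 3), rep("GB.t1", 3), rep("GC.t1", 2)),
      chrom = c(rep("c1", 6), rep("c2", 2)),
      strand = c(rep("+", 3), rep("-", 3), rep("+", 2)),
      start = c(51, 131, 231, 601, 701, 801, 101, 301),
      end = c(80, 170, 290, 640, 750, 860, 200, 420),
      stringsAsFactors = FALSE
    )
    genes <- gene_models(exons, genome)
    cache <<- list(genome = genome, genes = genes,
                   table = build_splicingcode(genes, genome))
    cache
  }
})

# A seeded simulated genome carrying a KANSL1->ARL17A-like inverted-order
# fusion with six isoforms (donor exits 2/3/6, acceptor entries 3/4/7/8),
# the dominant isoform weighted 50x.
fusion_fixture <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    cfg <- sim_config(seed = 2024L, n_chrom = 1L, genes_per_chrom = 4L,
                      exons_per_gene = c(8L, 8L), exon_len = c(150L, 250L))
    sim <- make_genome(cfg)
    fs <- fusion_spec("GENE03", "GENE01", donor_intron = 6L,
                      acceptor_intron = 2L,
                      architecture = "inverted_order",
                      isoforms = cbind(c(2, 3, 3, 6, 6, 6),
                                       c(3, 3, 4, 4, 7, 8)),
                      weights = c(1, 50, 1, 1, 1, 1))
    fus <- inject_fusion(sim, fs, seed = 7L)
    cache <<- list(
      sim = sim, fspec = fs, fusion = fus,
      table = build_splicingcode(sim$genes, sim$genome),
      db = build_homology_db(sim$genes, sim$genome),
      normal = spliced_sequence(sim$genes, sim$genome)
    )
    cache
  }
})
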
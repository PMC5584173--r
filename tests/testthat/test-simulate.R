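test_that("genome generation is bitwise-reproducible and countable", {
  cfg <- sim_config(seed = 7L, n_chrom = 2L, genes_per_chrom = 5L)
  a <- make_genome(cfg)
  b <- make_genome(cfg)
  expect_identical(a$genome, b$genome)
  expect_identical(as.data.frame(a$genes), as.data.frame(b$genes))
  expect_equal(length(unique(a$genes$gene_id)), 10L)
  expect_setequal(unique(a$genes$strand), c("+", "-"))
  # serialized outputs are byte-identical across runs too
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  f1 <- write_sim(a, d1); f2 <- write_sim(b, d2)
  expect_identical(readLines(f1[["fasta"]]), readLines(f2[["fasta"]]))
  expect_identical(readLines(f1[["gtf"]]), readLines(f2[["gtf"]]))
})

test_that("fixed chromosome length errors when genes do not fit", {
  cfg <- sim_config(seed = 7L, n_chrom = 1L, genes_per_chrom = 5L)
  expect_error(make_genome(cfg, chrom_len = 5000L), "larger chromosomes")
})

test_that("pseudogene planting adds sequence but no annotation", {
  cfg <- sim_config(seed = 11L, n_chrom = 1L, genes_per_chrom = 3L)
  plain <- make_genome(cfg)
  sim <- make_genome(cfg, pseudogene_of = "GENE02")
  expect_equal(nrow(sim$pseudogenes), 1L)
  expect_identical(as.data.frame(sim$genes), as.data.frame(plain$genes))
  cdna <- spliced_sequence(sim$genes, plain$genome, "GENE02.t1")[[1]]
  planted <- substring(sim$genome[["chr1"]], sim$pseudogenes$start,
                       sim$pseudogenes$end)
  expect_identical(planted, cdna)
  expect_gt(nchar(sim$genome[["chr1"]]), nchar(plain$genome[["chr1"]]))
})

test_that("fusion alleles join the named introns and derive isoform mRNAs", {
  set.seed(31)
  genome <- c(c1 = paste(sample(c("A", "C", "G", "T"), 3000, TRUE),
                         collapse = ""))
  genes <- gene_models(data.frame(
    gene_id = rep(c("gD", "gAc"), c(3, 3)),
    transcript_id = rep(c("gD.t", "gAc.t"), c(3, 3)),
    chrom = "c1", strand = "+",
    start = c(101, 301, 501, 1501, 1801, 2101),
    end = c(200, 400, 600, 1700, 1950, 2300)), genome)
  sim <- structure(list(genome = genome, genes = genes,
                        pseudogenes = data.frame(),
                        config = sim_config()), class = "sim_genome")
  fs <- fusion_spec("gD", "gAc", donor_intron = 2L, acceptor_intron = 1L,
                    architecture = "distal",
                    isoforms = cbind(2L, 2L))
  fus <- inject_fusion(sim, fs, seed = 3L)
  iso <- fus$isoforms
  # independent construction from spliced slices
  expected <- paste0(substring(genome, 101, 200), substring(genome, 301, 400),
                     substring(genome, 1801, 1950),
                     substring(genome, 2101, 2300))
  expect_identical(iso$seq, expected)
  expect_equal(iso$junction_offset, 200L)
  expect_equal(iso$donor_coord, 400L)
  expect_equal(iso$acceptor_coord, 1801L)
  # breakpoints land strictly inside the named introns
  bp <- fus$breakpoints
  expect_gte(bp$donor_break, 401L); expect_lte(bp$donor_break, 500L)
  expect_gte(bp$acceptor_break, 1701L); expect_lte(bp$acceptor_break, 1800L)
  # the fused genomic allele carries both intron stubs around the junction
  expect_identical(substring(fus$allele, 1, 300),
                   paste0(substring(genome, 101, 400)))
  # isoforms incompatible with the breakpoints are refused
  expect_error(inject_fusion(sim, fusion_spec("gD", "gAc", 2L, 1L,
                                              isoforms = cbind(3L, 2L)),
                             seed = 3L), "downstream of the donor")
  expect_error(inject_fusion(sim, fusion_spec("gD", "gAc", 2L, 2L,
                                              isoforms = cbind(2L, 2L)),
                             seed = 3L), "upstream of the acceptor")
})

test_that("six isoform architectures give six distinct junction pairs", {
  fx <- fusion_fixture()
  iso <- fx$fusion$isoforms
  expect_equal(nrow(iso), 6L)
  expect_equal(anyDuplicated(paste(iso$donor_coord, iso$acceptor_coord)), 0L)
  expect_true(all(iso$junction_offset >= 1 &
                    iso$junction_offset < nchar(iso$seq)))
})

test_that("error-free reads are exact substrings; seeds fix the bytes", {
  fx <- fusion_fixture()
  rd <- simulate_reads(fx$normal, 200, seed = 17)
  for (i in sample(200, 20)) {
    org <- fx$normal[[rd$truth$origin[i]]]
    expect_identical(rd$seqs[i],
                     substring(org, rd$truth$start[i],
                               rd$truth$start[i] + rd$truth$length[i] - 1L))
  }
  rd2 <- simulate_reads(fx$normal, 200, seed = 17)
  expect_identical(rd$seqs, rd2$seqs)
  expect_identical(rd$truth, rd2$truth)

  noisy <- simulate_reads(fx$normal, 300, seed = 18, error_rate = 0.02)
  expect_gt(sum(noisy$truth$n_errors), 0)
  i <- which(noisy$truth$n_errors > 0)[1]
  org <- fx$normal[[noisy$truth$origin[i]]]
  clean <- substring(org, noisy$truth$start[i],
                     noisy$truth$start[i] + noisy$truth$length[i] - 1L)
  pos <- as.integer(strsplit(noisy$truth$error_pos[i], ",")[[1]])
  diff <- which(strsplit(noisy$seqs[i], "")[[1]] !=
                  strsplit(clean, "")[[1]])
  expect_identical(diff, pos)
})

test_that("too-short transcripts are excluded with a warning", {
  pool <- c(long = strrep("ACGT", 50), short = "ACGTACGT")
  expect_warning(rd <- simulate_reads(pool, 50, seed = 19), "shorter")
  expect_true(all(rd$truth$origin == "long"))
  expect_error(simulate_reads(c(short = "ACGT"), 5, seed = 1),
               "long enough")
})

test_that("planted junction reads honour the minimum flank", {
  fx <- fusion_fixture()
  jr <- plant_junction_reads(fx$fusion, 40, seed = 23)
  expect_equal(length(jr$seqs), 40L)
  expect_true(all(jr$truth$L5 >= 20 & jr$truth$L3 >= 20))
  expect_setequal(unique(jr$truth$isoform), fx$fusion$isoforms$name)
  # reads really span the junction: prefix from donor side, rest acceptor
  iso <- fx$fusion$isoforms
  for (i in sample(40, 10)) {
    row <- match(jr$truth$isoform[i], iso$name)
    off <- iso$junction_offset[row]
    s <- off - jr$truth$L5[i] + 1L
    expect_identical(jr$seqs[i],
                     substring(iso$seq[row], s,
                               s + nchar(jr$seqs[i]) - 1L))
  }
})

test_that("cohort carrier draws follow the binomial model", {
  all_neg <- simulate_cohort(50, 0, seed = 29)
  expect_false(any(all_neg$samples$carrier))
  all_pos <- simulate_cohort(50, 1, seed = 29)
  expect_true(all(all_pos$samples$carrier))

  fx <- fusion_fixture()
  coh <- simulate_cohort(4, 0.5, seed = 31, reads = TRUE, sim = fx$sim,
                         fusion = fx$fusion, n_reads = 400)
  expect_length(coh$reads, 4L)
  # carriers' pools include isoforms, non-carriers' never do
  for (i in seq_len(4)) {
    from_iso <- coh$reads[[i]]$truth$origin %in% fx$fusion$isoforms$name
    if (coh$samples$carrier[i]) expect_true(any(from_iso))
    else expect_false(any(from_iso))
  }
})
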
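test_that("a bare key pair from two genes is called with split k and L = 2k", {
  fx <- tiny_fixture()
  tab <- fx$table
  rec <- tab$records
  i <- which(rec$gene_id == "GA")[1]
  j <- which(rec$gene_id == "GC")[1]
  read <- paste0(rec$donor_key[i], rec$acceptor_key[j])
  out <- scan_read(read, tab)
  expect_equal(nrow(out), 1L)
  expect_equal(out$split_offset, 20L)
  expect_equal(out$L, 40L)
  expect_equal(out$L5, 20L)
  expect_identical(out$donor_gene, "GA")
  expect_identical(out$acceptor_gene, "GC")
  expect_equal(out$p_random, 0.25^40, tolerance = 1e-12)
})

test_that("reads from a single annotated transcript are never called", {
  fx <- fusion_fixture()
  rd <- simulate_reads(fx$normal, 300, seed = 99)
  res <- scan_reads(rd$seqs, fx$table, ids = rd$ids)
  expect_equal(nrow(res$candidates), 0L)
  expect_equal(unname(res$stats[["total"]]), 300)
})

test_that("a 75-bp chimera split at offset 30 reports L5/L3 = 30/45", {
  fx <- tiny_fixture()
  tab <- fx$table
  rec <- tab$records
  i <- which(rec$gene_id == "GA")[1]
  j <- which(rec$gene_id == "GC")[1]
  dp <- tab$donor_prefix[i]
  as_ <- tab$acceptor_suffix[j]
  read <- paste0(substring(dp, nchar(dp) - 29L, nchar(dp)),
                 substring(as_, 1L, 45L))
  out <- scan_read(read, tab)
  expect_equal(nrow(out), 1L)
  expect_equal(out$L5, 30L)
  expect_equal(out$L3, 45L)
  expect_equal(out$L, 75L)
  # brute-force all-splits oracle agrees
  orc <- oracle_scan(read, fx$genes, fx$genome)
  expect_equal(out$split_offset, orc$split_offset[orc$orientation ==
                                                    "forward"])
  expect_identical(out$donor_gene,
                   orc$donor_gene[orc$orientation == "forward"])
})

test_that("extension crosses internal splice junctions of the donor gene", {
  fx <- tiny_fixture()
  tab <- fx$table
  rec <- tab$records
  # GA intron 2: donor prefix covers exons 1+2 (30 + 40 bases)
  i <- which(rec$gene_id == "GA" & rec$intron_index == 2)
  j <- which(rec$gene_id == "GC")[1]
  dp <- tab$donor_prefix[i]
  expect_equal(nchar(dp), 70L)
  read <- paste0(substring(dp, 11L, 70L),  # 60 donor bases, crosses e1-e2
                 substring(tab$acceptor_suffix[j], 1L, 41L))
  out <- scan_read(read, tab)
  keep <- out[out$donor_intron == 2 & out$donor_gene == "GA", ]
  expect_equal(nrow(keep), 1L)
  expect_equal(keep$L5, 60L)
  # independent check against spliced-sequence slicing
  sp <- spliced_sequence(fx$genes, fx$genome, "GA.t1")[[1]]
  expect_identical(substring(read, 1L, 60L), substring(sp, 11L, 70L))
})

test_that("a single mismatch in the extended prefix kills the candidate", {
  fx <- tiny_fixture()
  tab <- fx$table
  rec <- tab$records
  i <- which(rec$gene_id == "GA")[1]
  j <- which(rec$gene_id == "GC")[1]
  dp <- tab$donor_prefix[i]
  read <- paste0(substring(dp, nchar(dp) - 29L, nchar(dp)),
                 substring(tab$acceptor_suffix[j], 1L, 45L))
  # mutate a base in the donor flank, outside the key (position 5)
  sub <- chartr("ACGT", "TGCA", substring(read, 5L, 5L))
  mut <- paste0(substring(read, 1, 4), sub, substring(read, 6, nchar(read)))
  expect_equal(nrow(scan_read(mut, fx$table)), 0L)
  # but a 1-mismatch budget recovers it
  relaxed <- scan_params(max_mismatch_extension = 1L)
  expect_equal(nrow(scan_read(mut, fx$table, relaxed)), 1L)
})

test_that("scanning the reverse complement flips orientation only", {
  fx <- tiny_fixture()
  tab <- fx$table
  rec <- tab$records
  i <- which(rec$gene_id == "GB")[1]  # minus-strand donor
  j <- which(rec$gene_id == "GC")[1]
  dp <- tab$donor_prefix[i]
  read <- paste0(substring(dp, nchar(dp) - 34L, nchar(dp)),
                 substring(tab$acceptor_suffix[j], 1L, 40L))
  fwd <- scan_read(read, tab)
  rev <- scan_read(splicekey:::revcomp(read), tab)
  expect_equal(nrow(fwd), 1L)
  expect_equal(nrow(rev), 1L)
  expect_identical(fwd$orientation, "forward")
  expect_identical(rev$orientation, "revcomp")
  cols <- c("split_offset", "donor_gene", "donor_coord",
            "acceptor_gene", "acceptor_coord", "L5", "L3", "L")
  expect_equal(fwd[, cols], rev[, cols])
})

test_that("short reads are skipped with a counter, ambiguity cap empties calls", {
  fx <- tiny_fixture()
  res <- scan_reads("ACGTACGTACGT", fx$table)
  expect_equal(unname(res$stats[["skipped_short"]]), 1L)
  expect_equal(nrow(res$candidates), 0L)

  rec <- fx$table$records
  i <- which(rec$gene_id == "GA")[1]
  j <- which(rec$gene_id == "GC")[1]
  read <- paste0(rec$donor_key[i], rec$acceptor_key[j])
  strict <- scan_params(max_pairings = 0L)
  res2 <- scan_reads(read, fx$table, strict)
  expect_equal(nrow(res2$candidates), 0L)
  expect_equal(unname(res2$stats[["ambiguous"]]), 1L)
  # monotonicity: raising the cap restores the candidate set
  res3 <- scan_reads(read, fx$table, scan_params(max_pairings = 4L))
  expect_equal(nrow(res3$candidates), 1L)
})

test_that("scanner equals the brute-force all-splits oracle on mixed reads", {
  fx <- fusion_fixture()
  jr <- plant_junction_reads(fx$fusion, 12, seed = 31)
  bg <- simulate_reads(fx$normal, 12, seed = 32)
  seqs <- c(jr$seqs, bg$seqs)
  for (i in seq_along(seqs)) {
    got <- scan_read(seqs[i], fx$table)
    orc <- oracle_scan(seqs[i], fx$sim$genes, fx$sim$genome)
    if (is.null(orc)) {
      expect_equal(nrow(got), 0L)
    } else {
      cols <- c("orientation", "split_offset", "donor_gene", "donor_coord",
                "acceptor_gene", "acceptor_coord")
      got_k <- do.call(paste, got[, cols])
      orc_k <- do.call(paste, orc[, cols])
      expect_setequal(got_k, orc_k)
    }
  }
})

test_that("every emitted candidate reconstructs its read from the annotation", {
  fx <- fusion_fixture()
  jr <- plant_junction_reads(fx$fusion, 25, seed = 41)
  res <- scan_reads(jr$seqs, fx$table, ids = jr$ids)
  expect_gt(nrow(res$candidates), 0L)
  tab <- fx$table
  for (r in seq_len(nrow(res$candidates))) {
    cc <- res$candidates[r, ]
    drow <- which(tab$records$gene_id == cc$donor_gene &
                    tab$records$donor_coord == cc$donor_coord)[1]
    arow <- which(tab$records$gene_id == cc$acceptor_gene &
                    tab$records$acceptor_coord == cc$acceptor_coord)[1]
    seq <- if (cc$orientation == "forward") cc$read_seq else
      splicekey:::revcomp(cc$read_seq)
    rebuilt <- paste0(
      substring(tab$donor_prefix[drow],
                nchar(tab$donor_prefix[drow]) - cc$L5 + 1L,
                nchar(tab$donor_prefix[drow])),
      substring(tab$acceptor_suffix[arow], 1L, cc$L3))
    expect_identical(seq, rebuilt)
  }
})

test_that("FASTQ scanning matches in-memory scanning and handles empty files", {
  fx <- fusion_fixture()
  fq <- withr::local_tempfile(fileext = ".fq")
  writeLines(character(0), fq)
  res <- scan_fastq(fq, fx$table)
  expect_equal(unname(res$stats[["total"]]), 0L)
  expect_equal(nrow(res$candidates), 0L)

  jr <- plant_junction_reads(fx$fusion, 10, seed = 51)
  bg <- simulate_reads(fx$normal, 40, seed = 52)
  write_fastq(c(jr$seqs, bg$seqs), c(jr$ids, bg$ids), fq)
  a <- scan_fastq(fq, fx$table, chunk_size = 16L)
  b <- scan_reads(c(jr$seqs, bg$seqs), fx$table, ids = c(jr$ids, bg$ids))
  expect_equal(a$candidates, b$candidates)
  expect_equal(a$stats, b$stats)
  # deterministic across repeated runs of the same file
  expect_equal(scan_fastq(fq, fx$table), a)
})

test_that("planted junction reads with errors only disappear, never mutate", {
  fx <- fusion_fixture()
  iso <- stats::setNames(fx$fusion$isoforms$seq, fx$fusion$isoforms$name)
  clean <- simulate_reads(iso, 120, seed = 61, error_rate = 0)
  noisy <- simulate_reads(iso, 120, seed = 61, error_rate = 0.01)
  res_c <- scan_reads(clean$seqs, fx$table, ids = clean$ids)
  res_n <- scan_reads(noisy$seqs, fx$table, ids = noisy$ids)
  expect_lte(nrow(res_n$candidates), nrow(res_c$candidates))
  expect_true(all(res_n$candidates$read_id %in% res_c$candidates$read_id))
})
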
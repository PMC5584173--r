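#' Simulation configuration
#'
#' Defaults mirror the study conditions the package is tested under:
#' 75-101 bp single-end reads, substitution-only sequencing errors, and a
#' European-like carrier frequency of 0.289 for cohort draws.
#'
#' @param seed Master RNG seed.
#' @param n_chrom Number of chromosomes.
#' @param genes_per_chrom Genes per chromosome.
#' @param exons_per_gene Range (min, max) of exons per gene.
#' @param exon_len,intron_len,intergenic Ranges in bases.
#' @param read_len Read-length range, default `c(75, 101)`.
#' @param per_base_error Per-base substitution error probability.
#' @param n_reads Default number of reads per sample.
#' @param carrier_frequency Cohort carrier probability, default 0.289.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_chrom = 2L, genes_per_chrom = 5L,
                       exons_per_gene = c(4L, 8L),
                       exon_len = c(120L, 300L),
                       intron_len = c(200L, 800L),
                       intergenic = c(2000L, 5000L),
                       read_len = c(75L, 101L),
                       per_base_error = 0,
                       n_reads = 10000L,
                       carrier_frequency = 0.289) {
  stopifnot(per_base_error >= 0, per_base_error <= 1,
            carrier_frequency >= 0, carrier_frequency <= 1,
            exons_per_gene[1L] >= 1L, read_len[1L] <= read_len[2L])
  structure(as.list(environment()), class = "sim_config")
}

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

rint <- function(n, range) {
  if (range[1L] == range[2L]) rep(as.integer(range[1L]), n) else
    sample(seq.int(range[1L], range[2L]), n, replace = TRUE)
}

#' Simulate a genome with annotated multi-exon genes
#'
#' Chromosomes are i.i.d. uniform ACGT; genes are placed left to right
#' without overlap, on alternating strands, with one transcript per gene.
#' Optionally a processed pseudogene (the spliced cDNA re-inserted
#' intergenically downstream of the last gene of the chromosome, absent
#' from the annotation) is planted per flagged gene.  Deterministic from
#' `config$seed`.
#'
#' @param config A [sim_config()].
#' @param chrom_len Optional fixed chromosome length; genes that do not fit
#'   raise an error suggesting larger chromosomes.  Default `NULL`
#'   auto-sizes each chromosome to its content.
#' @param pseudogene_of Character vector of gene ids to plant processed
#'   pseudogene copies of.
#' @return List of class `sim_genome`: `genome` (named character),
#'   `genes` ([gene_models()]), `pseudogenes` (data frame of planted
#'   copies), `config`.
#' @export
make_genome <- function(config = sim_config(), chrom_len = NULL,
                        pseudogene_of = character(0)) {
  with_seed(config$seed, {
    exons <- list(); chroms <- character(config$n_chrom)
    names(chroms) <- paste0("chr", seq_len(config$n_chrom))
    gi <- 0L
    for (ci in seq_len(config$n_chrom)) {
      cursor <- 1000L
      for (gk in seq_len(config$genes_per_chrom)) {
        gi <- gi + 1L
        cursor <- cursor + rint(1L, config$intergenic)
        n_ex <- rint(1L, config$exons_per_gene)
        el <- rint(n_ex, config$exon_len)
        il <- if (n_ex > 1L) rint(n_ex - 1L, config$intron_len) else integer(0)
        starts <- cursor + cumsum(c(0L, el[-n_ex] + il))
        exons[[gi]] <- data.frame(
          gene_id = sprintf("GENE%02d", gi),
          transcript_id = sprintf("GENE%02d.t1", gi),
          chrom = names(chroms)[ci],
          strand = if (gi %% 2L == 1L) "+" else "-",
          start = starts, end = starts + el - 1L,
          stringsAsFactors = FALSE)
        cursor <- starts[n_ex] + el[n_ex] - 1L + 1L
      }
      clen <- cursor + 1000L
      if (!is.null(chrom_len)) {
        if (clen > chrom_len)
          stop("genes do not fit in chrom_len = ", chrom_len,
               " (need ", clen, "); use larger chromosomes")
        clen <- chrom_len
      }
      chroms[ci] <- rand_dna(clen)
    }
    genes <- gene_models(do.call(rbind, exons), chroms)
    sim <- structure(list(genome = chroms, genes = genes,
                          pseudogenes = data.frame(),
                          config = config),
                     class = "sim_genome")
    for (g in pseudogene_of) {
      tx <- unique(genes$transcript_id[genes$gene_id == g])
      if (length(tx) == 0L) stop("unknown gene for pseudogene: ", g)
      cdna <- spliced_sequence(genes, sim$genome, tx[1L])
      sim <- plant_sequence(sim, unname(cdna),
                            genes$chrom[genes$gene_id == g][1L],
                            label = paste0("pseudo:", g))
    }
    sim
  })
}

#' Plant an extra sequence into a simulated reference
#'
#' Appends `seq` to the end of a chromosome, separated from the last
#' annotated gene by `gap` bases, leaving all existing gene coordinates
#' untouched.  With the default gap the planted copy lies inside the 20-kb
#' homology window of the chromosome's last gene, so the contiguous-locus
#' filter can see it.
#'
#' @param sim A `sim_genome`.
#' @param seq DNA string to plant.
#' @param chrom Chromosome id.
#' @param gap Distance from the current chromosome end (default 5000).
#' @param label Label recorded in `sim$pseudogenes`.
#' @return The updated `sim_genome`.
#' @export
plant_sequence <- function(sim, seq, chrom, gap = 5000L, label = "planted") {
  old <- sim$genome[[chrom]]
  start <- nchar(old) + gap + 1L
  spacer <- strrep("T", gap)  # homopolymer spacer; key filtering rejects it
  sim$genome[chrom] <- paste0(old, spacer, seq)
  sim$pseudogenes <- rbind(sim$pseudogenes,
                           data.frame(label = label, chrom = chrom,
                                      start = start,
                                      end = start + nchar(seq) - 1L,
                                      stringsAsFactors = FALSE))
  sim
}

#' Fusion allele specification
#'
#' Describes a fusion of two annotated genes: the genomic breakpoints fall
#' strictly inside the named introns, and each splice isoform uses donor
#' exons `1..donor_exon` joined to acceptor exons `acceptor_exon..last`.
#' Isoform donor exits must not lie downstream of the donor breakpoint
#' intron, and acceptor entries must lie downstream of the acceptor
#' breakpoint intron, so every isoform is derivable from the fused allele.
#'
#' @param donor_gene,acceptor_gene Gene ids.
#' @param donor_intron,acceptor_intron 1-based intron indices (transcription
#'   order) containing the genomic breakpoints.
#' @param architecture `"inverted_order"`, `"distal"` or `"read_through"`.
#' @param isoforms Two-column matrix-like (donor_exon, acceptor_exon), one
#'   row per isoform.
#' @param weights Relative expression weights per isoform.
#' @return List of class `fusion_spec`.
#' @export
fusion_spec <- function(donor_gene, acceptor_gene,
                        donor_intron, acceptor_intron,
                        architecture = c("inverted_order", "distal",
                                         "read_through"),
                        isoforms = cbind(donor_exon = donor_intron,
                                         acceptor_exon = acceptor_intron + 1L),
                        weights = NULL) {
  architecture <- match.arg(architecture)
  isoforms <- as.matrix(isoforms)
  if (ncol(isoforms) != 2L) stop("isoforms must have 2 columns")
  colnames(isoforms) <- c("donor_exon", "acceptor_exon")
  if (is.null(weights)) weights <- rep(1, nrow(isoforms))
  stopifnot(length(weights) == nrow(isoforms), all(weights >= 0),
            any(weights > 0))
  structure(list(donor_gene = donor_gene, acceptor_gene = acceptor_gene,
                 donor_intron = as.integer(donor_intron),
                 acceptor_intron = as.integer(acceptor_intron),
                 architecture = architecture,
                 isoforms = isoforms, weights = weights),
            class = "fusion_spec")
}

# transcription-ordered exons of the (single) transcript of a gene
tx_exons <- function(genes, gene) {
  e <- genes[genes$gene_id == gene, , drop = FALSE]
  if (nrow(e) == 0L) stop("unknown gene: ", gene)
  e[order(e$exon_rank), , drop = FALSE]
}

#' Build a fusion allele and its spliced isoforms
#'
#' Joins the donor gene through its named intron to the acceptor gene's
#' named intron (transcription orientation on both sides), choosing
#' breakpoint positions uniformly inside the introns, and derives each
#' isoform's spliced mRNA with its junction coordinates.
#'
#' @param sim A `sim_genome`.
#' @param fspec A [fusion_spec()].
#' @param seed RNG seed for breakpoint placement.
#' @return List of class `fusion_truth`: `allele` (DNA string),
#'   `breakpoints` (data frame), `isoforms` (data frame with `name`,
#'   `donor_exon`, `acceptor_exon`, `donor_coord`, `acceptor_coord`,
#'   `weight`, `junction_offset`, `seq`).
#' @export
inject_fusion <- function(sim, fspec, seed = 1L) {
  genes <- sim$genes
  de <- tx_exons(genes, fspec$donor_gene)
  ae <- tx_exons(genes, fspec$acceptor_gene)
  if (fspec$donor_intron < 1L || fspec$donor_intron >= nrow(de))
    stop("donor breakpoint intron outside gene")
  if (fspec$acceptor_intron < 1L || fspec$acceptor_intron >= nrow(ae))
    stop("acceptor breakpoint intron outside gene")
  iso <- fspec$isoforms
  if (any(iso[, 1L] > fspec$donor_intron))
    stop("isoform donor exit downstream of the donor breakpoint intron")
  if (any(iso[, 2L] <= fspec$acceptor_intron))
    stop("isoform acceptor entry upstream of the acceptor breakpoint intron")
  if (any(iso[, 2L] > nrow(ae)))
    stop("isoform acceptor entry beyond the acceptor gene")

  # transcription-oriented genomic sequence of [from..to] along a gene,
  # where offsets are in transcription direction over the gene body
  gene_piece <- function(e, tx_from, tx_to) {
    chrom <- sim$genome[[e$chrom[1L]]]
    if (e$strand[1L] == "+") {
      substring(chrom, tx_from, tx_to)
    } else {
      revcomp(substring(chrom, tx_to, tx_from))
    }
  }

  with_seed(seed, {
    # genomic intron bounds in transcription direction
    intr_bounds <- function(e, i) {
      if (e$strand[1L] == "+") c(e$end[i] + 1L, e$start[i + 1L] - 1L)
      else c(e$start[i] - 1L, e$end[i + 1L] + 1L)  # descending coords
    }
    db <- intr_bounds(de, fspec$donor_intron)
    ab <- intr_bounds(ae, fspec$acceptor_intron)
    pick <- function(b, plus) {
      rng <- sort(b)
      if (rng[2L] < rng[1L]) stop("breakpoint outside intron")
      sample(seq.int(rng[1L], rng[2L]), 1L)
    }
    donor_break <- pick(db, de$strand[1L] == "+")
    acceptor_break <- pick(ab, ae$strand[1L] == "+")

    # fused genomic allele: donor 5' gene body through its breakpoint,
    # then acceptor from its breakpoint to the gene 3' end
    dstart <- if (de$strand[1L] == "+") de$start[1L] else de$end[1L]
    aend <- if (ae$strand[1L] == "+") ae$end[nrow(ae)] else ae$start[nrow(ae)]
    allele <- paste0(gene_piece(de, dstart, donor_break),
                     gene_piece(ae, acceptor_break, aend))

    iso_rows <- lapply(seq_len(nrow(iso)), function(i) {
      dx <- iso[i, 1L]; ax <- iso[i, 2L]
      dseq <- paste(vapply(seq_len(dx), function(j)
        gene_piece(de, if (de$strand[1L] == "+") de$start[j] else de$end[j],
                   if (de$strand[1L] == "+") de$end[j] else de$start[j]),
        character(1)), collapse = "")
      aseq <- paste(vapply(seq.int(ax, nrow(ae)), function(j)
        gene_piece(ae, if (ae$strand[1L] == "+") ae$start[j] else ae$end[j],
                   if (ae$strand[1L] == "+") ae$end[j] else ae$start[j]),
        character(1)), collapse = "")
      data.frame(
        name = sprintf("%s-%s.iso%d", fspec$donor_gene, fspec$acceptor_gene,
                       i),
        donor_exon = dx, acceptor_exon = ax,
        donor_coord = if (de$strand[1L] == "+") de$end[dx] else de$start[dx],
        acceptor_coord = if (ae$strand[1L] == "+") ae$start[ax] else
          ae$end[ax],
        weight = fspec$weights[i],
        junction_offset = nchar(dseq),
        seq = paste0(dseq, aseq),
        stringsAsFactors = FALSE)
    })
    structure(list(
      spec = fspec,
      allele = allele,
      breakpoints = data.frame(
        donor_gene = fspec$donor_gene, donor_chrom = de$chrom[1L],
        donor_break = donor_break,
        acceptor_gene = fspec$acceptor_gene, acceptor_chrom = ae$chrom[1L],
        acceptor_break = acceptor_break, stringsAsFactors = FALSE),
      isoforms = {
        x <- do.call(rbind, iso_rows); rownames(x) <- NULL; x
      }
    ), class = "fusion_truth")
  })
}

#' Simulate single-end reads from a weighted transcript pool
#'
#' Reads are drawn from transcripts with probability proportional to
#' weight x length, start positions uniform, lengths uniform in
#' `read_len`, with i.i.d. substitution errors at `error_rate`.
#' Transcripts shorter than the minimum read length are excluded with a
#' warning.  Deterministic from `seed`.
#'
#' @param pool Named character vector of transcript sequences.
#' @param n_reads Number of reads.
#' @param weights Relative weights (default 1 each).
#' @param read_len Length range, default `c(75, 101)`.
#' @param error_rate Per-base substitution probability.
#' @param seed RNG seed.
#' @param id_prefix Read-id prefix.
#' @return List with `seqs`, `ids` and a `truth` data frame (`read_id`,
#'   `origin`, `start`, `length`, `n_errors`, `error_pos`).
#' @export
simulate_reads <- function(pool, n_reads, weights = NULL,
                           read_len = c(75L, 101L), error_rate = 0,
                           seed = 1L, id_prefix = "read") {
  stopifnot(length(pool) >= 1L)
  if (is.null(weights)) weights <- rep(1, length(pool))
  stopifnot(length(weights) == length(pool), all(weights >= 0),
            any(weights > 0))
  lens <- nchar(pool)
  ok <- lens >= read_len[1L] & weights > 0
  if (!any(ok)) stop("no transcript long enough for the minimum read length")
  if (any(lens < read_len[1L] & weights > 0))
    warning("excluding ", sum(lens < read_len[1L] & weights > 0),
            " transcript(s) shorter than the minimum read length")
  pool <- pool[ok]; weights <- weights[ok]; lens <- lens[ok]
  with_seed(seed, {
    prob <- weights * lens
    origin <- sample.int(length(pool), n_reads, replace = TRUE,
                         prob = prob / sum(prob))
    L <- pmin(rint(n_reads, read_len), lens[origin])
    start <- floor(runif(n_reads, 1, lens[origin] - L + 1 + 1))
    seqs <- unname(substring(pool[origin], start, start + L - 1L))
    n_err <- stats::rbinom(n_reads, L, error_rate)
    err_pos <- character(n_reads); err_pos[] <- ""
    if (any(n_err > 0L)) {
      bases <- c("A", "C", "G", "T")
      for (i in which(n_err > 0L)) {
        pos <- sample.int(L[i], n_err[i])
        s <- strsplit(seqs[i], "", fixed = TRUE)[[1L]]
        for (p in pos) s[p] <- sample(setdiff(bases, s[p]), 1L)
        seqs[i] <- paste(s, collapse = "")
        err_pos[i] <- paste(sort(pos), collapse = ",")
      }
    }
    ids <- sprintf("%s%06d", id_prefix, seq_len(n_reads))
    list(seqs = seqs, ids = ids,
         truth = data.frame(read_id = ids, origin = names(pool)[origin],
                            start = as.integer(start), length = L,
                            n_errors = n_err, error_pos = err_pos,
                            stringsAsFactors = FALSE))
  })
}

#' Plant junction-spanning reads over fusion isoforms
#'
#' Emits exactly `n` error-free reads that span isoform fusion junctions
#' with at least `min_flank` matched bases on each side (the callable
#' configuration for a key length of `min_flank`).  Every isoform receives
#' at least one read; the remainder are allocated by isoform weight.
#'
#' @param fusion A `fusion_truth` from [inject_fusion()].
#' @param n Total junction reads.
#' @param read_len Length range.
#' @param min_flank Minimum bases on each side of the junction (default 20).
#' @param seed RNG seed.
#' @param id_prefix Read-id prefix.
#' @return List with `seqs`, `ids` and `truth` (`read_id`, `isoform`, `L5`,
#'   `L3`, `donor_coord`, `acceptor_coord`).
#' @export
plant_junction_reads <- function(fusion, n, read_len = c(75L, 101L),
                                 min_flank = 20L, seed = 1L,
                                 id_prefix = "junc") {
  iso <- fusion$isoforms
  ni <- nrow(iso)
  if (n < ni) stop("need at least one read per isoform (n >= ", ni, ")")
  with_seed(seed, {
    extra <- if (n > ni)
      as.vector(stats::rmultinom(1L, n - ni, iso$weight / sum(iso$weight)))
    else rep(0L, ni)
    counts <- 1L + extra
    rows <- rep(seq_len(ni), counts)
    L <- rint(n, read_len)
    donor_len <- iso$junction_offset[rows]
    acceptor_len <- nchar(iso$seq[rows]) - donor_len
    lo <- pmax(min_flank, L - acceptor_len)
    hi <- pmin(L - min_flank, donor_len)
    if (any(lo > hi))
      stop("isoform too short to span its junction with ", min_flank,
           " bases on each side at the requested read lengths")
    L5 <- vapply(seq_len(n), function(i)
      if (lo[i] == hi[i]) lo[i] else
        sample(seq.int(lo[i], hi[i]), 1L), integer(1))
    start <- donor_len - L5 + 1L
    seqs <- substring(iso$seq[rows], start, start + L - 1L)
    ids <- sprintf("%s%05d", id_prefix, seq_len(n))
    list(seqs = seqs, ids = ids,
         truth = data.frame(read_id = ids, isoform = iso$name[rows],
                            L5 = L5, L3 = L - L5,
                            donor_coord = iso$donor_coord[rows],
                            acceptor_coord = iso$acceptor_coord[rows],
                            stringsAsFactors = FALSE))
  })
}

#' Simulate a cohort of carrier / non-carrier samples
#'
#' Each sample is a fusion carrier with probability `carrier_frequency`
#' (seeded).  With `reads = TRUE`, per-sample reads are drawn from the
#' normal transcriptome, plus the fusion isoforms (at their weights) for
#' carriers.  With `reads = FALSE` only carrier status is generated — the
#' binomial sampling model used for cohort-level Monte-Carlo.
#'
#' @param n_samples Number of samples (>= 1).
#' @param carrier_frequency Carrier probability.
#' @param seed RNG seed.
#' @param reads Generate reads (default FALSE).
#' @param sim,fusion `sim_genome` and `fusion_truth`, required when
#'   `reads = TRUE`.
#' @param n_reads Reads per sample when `reads = TRUE`.
#' @param fusion_weight Relative weight of each fusion isoform vs one
#'   normal transcript (default 1).
#' @param error_rate Per-base substitution probability.
#' @return List with `samples` (data frame `sample_id`, `carrier`) and,
#'   when `reads = TRUE`, `reads` (per-sample list of `seqs`/`ids`/`truth`).
#' @export
simulate_cohort <- function(n_samples, carrier_frequency = 0.289, seed = 1L,
                            reads = FALSE, sim = NULL, fusion = NULL,
                            n_reads = 2000L, fusion_weight = 1,
                            error_rate = 0) {
  stopifnot(n_samples >= 1L)
  with_seed(seed, {
    carrier <- stats::runif(n_samples) < carrier_frequency
    samples <- data.frame(sample_id = sprintf("S%04d", seq_len(n_samples)),
                          carrier = carrier, stringsAsFactors = FALSE)
    out <- list(samples = samples)
    if (reads) {
      if (is.null(sim) || is.null(fusion))
        stop("reads = TRUE requires sim and fusion")
      normal <- spliced_sequence(sim$genes, sim$genome)
      iso <- stats::setNames(fusion$isoforms$seq, fusion$isoforms$name)
      seeds <- sample.int(.Machine$integer.max - 1L, n_samples)
      out$reads <- lapply(seq_len(n_samples), function(i) {
        pool <- if (carrier[i]) c(normal, iso) else normal
        w <- if (carrier[i])
          c(rep(1, length(normal)),
            fusion_weight * fusion$isoforms$weight) else
              rep(1, length(normal))
        simulate_reads(pool, n_reads, weights = w,
                       error_rate = error_rate, seed = seeds[i],
                       id_prefix = paste0(samples$sample_id[i], "_"))
      })
      names(out$reads) <- samples$sample_id
    }
    out
  })
}

#' Write simulated genome + annotation to disk
#'
#' @param sim A `sim_genome`.
#' @param dir Output directory (created).
#' @return Named character vector with the `fasta` and `gtf` paths.
#' @export
write_sim <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, "genome.fa")
  gtf <- file.path(dir, "annotation.gtf")
  write_genome(sim$genome, fa)
  write_annotation(sim$genes, gtf)
  c(fasta = fa, gtf = gtf)
}
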
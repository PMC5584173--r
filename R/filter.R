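#' Build the contiguous-locus homology database
#'
#' The database holds the full spliced transcriptome plus, per gene, the
#' genomic span extended by `flank` bases on each side (clipped to the
#' chromosome).  A candidate read contained contiguously (up to a small
#' mismatch budget) in any one of these sequences is explainable by a single
#' locus or splice variant and is rejected.
#'
#' @param genes A [gene_models()] table.
#' @param genome Named character vector from [read_genome()].
#' @param flank Genomic flank width in bases (default 20000).
#' @return A `homology_db` (DNAStringSet of sequences + metadata).
#' @export
build_homology_db <- function(genes, genome, flank = 20000L) {
  tx <- spliced_sequence(genes, genome)
  names(tx) <- paste0("tx:", names(tx))
  sp <- gene_spans(genes)
  loci <- vapply(seq_len(nrow(sp)), function(i) {
    chrom <- genome[[sp$chrom[i]]]
    substring(chrom, max(1L, sp$start[i] - flank),
              min(nchar(chrom), sp$end[i] + flank))
  }, character(1))
  names(loci) <- paste0("locus:", sp$gene_id)
  structure(list(seqs = Biostrings::DNAStringSet(c(tx, loci)),
                 flank = as.integer(flank)),
            class = "homology_db")
}

#' @export
print.homology_db <- function(x, ...) {
  cat("homology_db: ", length(x$seqs), " sequence(s), flank = ",
      x$flank, " bp\n", sep = "")
  invisible(x)
}

#' Contiguous-locus verdict for one read
#'
#' Seed-free mismatch-bounded search of the full read (and its reverse
#' complement) against every database sequence, no gaps.  If any single
#' sequence contains the whole read with at most `max_mismatch` mismatches
#' the chimera is explainable by one locus and the verdict is
#' `rejected_contiguous`; otherwise `accepted`.
#'
#' @param read_seq Read sequence.
#' @param db A `homology_db`.
#' @param max_mismatch Mismatch budget (default 2).
#' @return `"accepted"` or `"rejected_contiguous"`.
#' @export
contiguous_locus_filter <- function(read_seq, db, max_mismatch = 2L) {
  pat <- Biostrings::DNAString(read_seq)
  hit <- any(Biostrings::vcountPattern(pat, db$seqs,
                                       max.mismatch = max_mismatch) > 0L) ||
    any(Biostrings::vcountPattern(Biostrings::reverseComplement(pat),
                                  db$seqs,
                                  max.mismatch = max_mismatch) > 0L)
  if (hit) "rejected_contiguous" else "accepted"
}

#' Classify accepted junctions
#'
#' Every accepted candidate receives exactly one category:
#' \describe{
#'   \item{intra_gene}{donor and acceptor genes identical (reachable only
#'     when `require_distinct_genes` is off).}
#'   \item{read_through}{same chromosome and strand, acceptor gene strictly
#'     downstream of the donor gene in transcription direction, gene-body
#'     gap at most `read_through_gap`.}
#'   \item{inverted_order}{same chromosome, fused order reverses the genes'
#'     genomic order in the donor's transcription direction (the
#'     KANSL1-to-ARL17A pattern).}
#'   \item{distal_fusion}{everything else (incl. different chromosomes).}
#' }
#'
#' @param candidates Candidate data frame from [scan_reads()].
#' @param genes A [gene_models()] table.
#' @param read_through_gap Maximum gene-body gap for read-through chimeras
#'   (default 100000).
#' @return Character vector of categories, one per candidate.
#' @export
classify_junction <- function(candidates, genes, read_through_gap = 1e5) {
  if (nrow(candidates) == 0L) return(character(0))
  sp <- gene_spans(genes)
  rownames(sp) <- sp$gene_id
  d <- sp[candidates$donor_gene, , drop = FALSE]
  a <- sp[candidates$acceptor_gene, , drop = FALSE]
  if (anyNA(d$gene_id) || anyNA(a$gene_id))
    stop("candidate gene absent from annotation")
  same_gene <- candidates$donor_gene == candidates$acceptor_gene
  same_chrom <- d$chrom == a$chrom
  same_strand <- d$strand == a$strand
  # acceptor downstream of donor in the donor's transcription direction
  downstream <- ifelse(d$strand == "+", a$start > d$end, a$end < d$start)
  gap <- ifelse(d$strand == "+", a$start - d$end - 1L, d$start - a$end - 1L)
  out <- rep("distal_fusion", nrow(candidates))
  out[same_chrom & !downstream] <- "inverted_order"
  out[same_chrom & same_strand & downstream &
        gap <= read_through_gap] <- "read_through"
  out[same_gene] <- "intra_gene"
  out
}

#' Homology-screen and classify scan candidates
#'
#' Applies [contiguous_locus_filter()] to each candidate read (each distinct
#' read sequence is searched once) and [classify_junction()] to the
#' survivors.
#'
#' @param candidates Candidate data frame from [scan_reads()].
#' @param db A `homology_db` from [build_homology_db()].
#' @param genes A [gene_models()] table.
#' @param max_mismatch Homology mismatch budget (default 2).
#' @param read_through_gap See [classify_junction()].
#' @return The candidate data frame with `verdict` and `category` columns
#'   (class `junction_calls`); `category` is `NA` for rejected rows.
#' @export
filter_candidates <- function(candidates, db, genes, max_mismatch = 2L,
                              read_through_gap = 1e5) {
  if (nrow(candidates) == 0L) {
    candidates$verdict <- character(0)
    candidates$category <- character(0)
    class(candidates) <- c("junction_calls", "data.frame")
    return(candidates)
  }
  useq <- unique(candidates$read_seq)
  verdict_by_seq <- vapply(useq, contiguous_locus_filter, character(1),
                           db = db, max_mismatch = max_mismatch)
  candidates$verdict <- unname(verdict_by_seq[candidates$read_seq])
  candidates$category <- NA_character_
  acc <- candidates$verdict == "accepted"
  if (any(acc))
    candidates$category[acc] <-
      classify_junction(candidates[acc, , drop = FALSE], genes,
                        read_through_gap = read_through_gap)
  class(candidates) <- c("junction_calls", "data.frame")
  candidates
}

#' Generate random chimeric control reads
#'
#' Each read concatenates a random substring of a random exon with a random
#' substring of an exon (`exon_exon`) or intron (`exon_intron`) of a
#' different gene, both taken in transcription orientation, at a uniformly
#' random split position, total length uniform in `read_len`.  Exon-exon
#' chimeras whose two fragments abut exactly at annotated donor/acceptor key
#' boundaries are excluded (they would be genuine junction reads, not
#' artifacts).  Reproducible from `seed`.
#'
#' @param genes A [gene_models()] table with at least 2 genes.
#' @param genome Named character vector from [read_genome()].
#' @param n Number of chimeras (>= 1).
#' @param kind `"exon_exon"` or `"exon_intron"`.
#' @param read_len Length range, default `c(75, 101)`.
#' @param seed RNG seed.
#' @return List with `seqs`, `ids`, and a `truth` data frame recording the
#'   fragment origins.
#' @export
generate_random_chimeras <- function(genes, genome, n,
                                     kind = c("exon_exon", "exon_intron"),
                                     read_len = c(75L, 101L), seed = 1L) {
  kind <- match.arg(kind)
  n <- as.integer(n)
  if (n < 1L) stop("n must be >= 1")
  if (length(unique(genes$gene_id)) < 2L)
    stop("chimera generation needs an annotation with at least 2 genes")

  exons <- as.data.frame(genes)
  exons$len <- exons$end - exons$start + 1L
  # per-transcript introns (genomic gaps between adjacent exons)
  sp <- split(seq_len(nrow(exons)), exons$transcript_id)
  introns <- do.call(rbind, lapply(sp, function(idx) {
    e <- exons[idx, , drop = FALSE]
    e <- e[order(e$start), , drop = FALSE]
    if (nrow(e) < 2L) return(NULL)
    data.frame(gene_id = e$gene_id[1L], chrom = e$chrom[1L],
               strand = e$strand[1L],
               start = e$end[-nrow(e)] + 1L, end = e$start[-1L] - 1L,
               stringsAsFactors = FALSE)
  }))
  if (kind == "exon_intron" && (is.null(introns) || nrow(introns) == 0L))
    stop("no introns in annotation for exon_intron chimeras")
  if (!is.null(introns)) introns$len <- introns$end - introns$start + 1L

  # transcription-oriented substring of a feature row at offset o (0-based
  # from the feature's 5' end), length w
  frag_seq <- function(feat, o, w) {
    plus <- feat$strand == "+"
    gs <- ifelse(plus, feat$start + o, feat$end - o - w + 1L)
    s <- substring(genome[feat$chrom], gs, gs + w - 1L)
    if (any(!plus)) s[!plus] <- revcomp(s[!plus])
    s
  }

  with_seed(seed, {
    out_seq <- character(n); fill <- 0L
    truth <- vector("list", n)
    guard <- 0L
    while (fill < n) {
      guard <- guard + 1L
      if (guard > 200L) stop("chimera sampling failed to converge; ",
                             "are exons/introns long enough?")
      m <- min(n - fill + ceiling((n - fill) * 0.25) + 16L, 2L * n)
      L <- sample(seq.int(read_len[1L], read_len[2L]), m, replace = TRUE)
      s <- vapply(L, function(l) sample.int(l - 1L, 1L), integer(1))
      de <- exons[sample.int(nrow(exons), m, replace = TRUE), , drop = FALSE]
      pool2 <- if (kind == "exon_exon") exons else introns
      ae <- pool2[sample.int(nrow(pool2), m, replace = TRUE), , drop = FALSE]
      ok <- de$len >= s & ae$len >= (L - s) & de$gene_id != ae$gene_id
      if (!any(ok)) next
      L <- L[ok]; s <- s[ok]
      de <- de[ok, , drop = FALSE]; ae <- ae[ok, , drop = FALSE]
      o1 <- vapply(de$len - s, function(mx) sample.int(mx + 1L, 1L) - 1L,
                   integer(1))
      o2 <- vapply(ae$len - (L - s), function(mx) sample.int(mx + 1L, 1L) - 1L,
                   integer(1))
      if (kind == "exon_exon") {
        # exclude fragments abutting exactly at annotated key boundaries
        at_bound <- (o1 + s == de$len) & (o2 == 0L)
        if (any(at_bound)) {
          L <- L[!at_bound]; s <- s[!at_bound]
          o1 <- o1[!at_bound]; o2 <- o2[!at_bound]
          de <- de[!at_bound, , drop = FALSE]
          ae <- ae[!at_bound, , drop = FALSE]
        }
      }
      if (length(L) == 0L) next
      take <- seq_len(min(length(L), n - fill))
      L <- L[take]; s <- s[take]; o1 <- o1[take]; o2 <- o2[take]
      de <- de[take, , drop = FALSE]; ae <- ae[take, , drop = FALSE]
      seqs <- paste0(frag_seq(de, o1, s), frag_seq(ae, o2, L - s))
      idx <- fill + seq_along(seqs)
      out_seq[idx] <- seqs
      truth[[fill + 1L]] <- data.frame(
        idx = idx, length = L, split = s,
        donor_gene = de$gene_id, acceptor_gene = ae$gene_id,
        stringsAsFactors = FALSE)
      fill <- fill + length(seqs)
    }
    truth <- do.call(rbind, truth[!vapply(truth, is.null, logical(1))])
    truth <- truth[order(truth$idx), , drop = FALSE]
    ids <- sprintf("chimera_%s_%06d", kind, seq_len(n))
    truth$read_id <- ids
    rownames(truth) <- NULL
    list(seqs = out_seq, ids = ids, truth = truth)
  })
}
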
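#' Read a genome FASTA into a named character vector
#'
#' Sequences are uppercased on input; record ids are the first whitespace-
#' delimited token of each header.  Gzip-compressed files are read
#' transparently.
#'
#' @param path Path to a FASTA (optionally `.gz`) file.
#' @return Named character vector, one element per chromosome/contig.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">c1", "acgt"), fa)
#' read_genome(fa)
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) stop("genome FASTA not found: ", path)
  dss <- tryCatch(
    Biostrings::readDNAStringSet(path),
    error = function(e) stop("malformed FASTA '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  ids <- sub("\\s.*$", "", names(dss))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate sequence id(s) in FASTA: ", paste(dup, collapse = ", "))
  stats::setNames(toupper(as.character(dss)), ids)
}

#' Write a genome to FASTA
#'
#' @param genome Named character vector as returned by [read_genome()].
#' @param path Output path (`.gz` for compressed output).
#' @return `path`, invisibly.
#' @export
write_genome <- function(genome, path) {
  dss <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(dss, path,
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Construct / validate a gene-model table
#'
#' Gene models are held as a plain data frame of exons with columns
#' `gene_id`, `transcript_id`, `chrom`, `strand`, `start`, `end` (1-based,
#' inclusive, the GTF/IRanges convention) and a derived `exon_rank` giving
#' transcription order.  Exons within a transcript must be non-overlapping;
#' when `genome` is supplied every exon must lie within its chromosome.
#'
#' @param exons Data frame with the columns above (`exon_rank` optional,
#'   recomputed).
#' @param genome Optional named character vector for bounds checking.
#' @return The validated exon table, sorted, with class `gene_models`.
#' @export
gene_models <- function(exons, genome = NULL) {
  need <- c("gene_id", "transcript_id", "chrom", "strand", "start", "end")
  miss <- setdiff(need, names(exons))
  if (length(miss)) stop("gene model table lacks column(s): ",
                         paste(miss, collapse = ", "))
  exons <- as.data.frame(exons)[, need]
  exons$start <- as.integer(exons$start)
  exons$end <- as.integer(exons$end)
  if (any(!exons$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  if (any(exons$end < exons$start) || any(exons$start < 1L))
    stop("exon intervals must satisfy 1 <= start <= end")
  exons <- exons[order(exons$gene_id, exons$transcript_id, exons$start), ,
                 drop = FALSE]
  rownames(exons) <- NULL
  # per-transcript checks + transcription-order rank
  sp <- split(seq_len(nrow(exons)), exons$transcript_id)
  exons$exon_rank <- NA_integer_
  for (idx in sp) {
    st <- exons$start[idx]; en <- exons$end[idx]
    if (length(idx) > 1L && any(st[-1L] <= en[-length(en)]))
      stop("overlapping exons in transcript ",
           exons$transcript_id[idx[1L]])
    if (length(unique(exons$strand[idx])) != 1L ||
        length(unique(exons$chrom[idx])) != 1L)
      stop("transcript ", exons$transcript_id[idx[1L]],
           " mixes strands or chromosomes")
    exons$exon_rank[idx] <-
      if (exons$strand[idx[1L]] == "+") seq_along(idx) else rev(seq_along(idx))
  }
  if (!is.null(genome)) {
    bad <- !(exons$chrom %in% names(genome))
    if (any(bad))
      stop("chromosome(s) absent from genome: ",
           paste(unique(exons$chrom[bad]), collapse = ", "))
    lens <- nchar(genome)[exons$chrom]
    out <- exons$end > lens
    if (any(out))
      stop("exon beyond chromosome bounds in transcript ",
           exons$transcript_id[which(out)[1L]],
           " (end ", exons$end[which(out)[1L]], " > ",
           lens[which(out)[1L]], ")")
  }
  class(exons) <- c("gene_models", "data.frame")
  exons
}

#' Read gene models from a GTF file
#'
#' Exon features are read (via \pkg{rtracklayer}), grouped by transcript and
#' sorted.  Genes on chromosomes absent from `genome` are skipped with a
#' warning; exons extending beyond a chromosome raise an error naming the
#' transcript.
#'
#' @param path GTF file (optionally gzipped); `gene_id` and `transcript_id`
#'   attributes are required on exon features.
#' @param genome Named character vector from [read_genome()].
#' @return A [gene_models()] table.
#' @export
read_annotation <- function(path, genome) {
  if (!file.exists(path)) stop("annotation GTF not found: ", path)
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  if (length(gr) == 0L) stop("no exon features in ", path)
  if (is.null(gr$gene_id) || is.null(gr$transcript_id) ||
      anyNA(gr$gene_id) || anyNA(gr$transcript_id))
    stop("exon features must carry gene_id and transcript_id attributes")
  ex <- data.frame(
    gene_id = as.character(gr$gene_id),
    transcript_id = as.character(gr$transcript_id),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
  absent <- !(ex$chrom %in% names(genome))
  if (any(absent)) {
    warning("skipping ", length(unique(ex$gene_id[absent])),
            " gene(s) on chromosome(s) absent from genome: ",
            paste(unique(ex$chrom[absent]), collapse = ", "))
    ex <- ex[!absent, , drop = FALSE]
    if (nrow(ex) == 0L) stop("no exons left after chromosome filtering")
  }
  gene_models(ex, genome)
}

#' Write gene models to GTF
#'
#' Exon features only; coordinates are written in the native GTF 1-based
#' inclusive convention.  Re-reading the file with [read_annotation()]
#' reproduces the input models.
#'
#' @param genes A [gene_models()] table.
#' @param path Output GTF path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(genes, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = genes$chrom,
    ranges = IRanges::IRanges(start = genes$start, end = genes$end),
    strand = genes$strand
  )
  S4Vectors::mcols(gr)$source <- "splicekey"
  S4Vectors::mcols(gr)$type <- "exon"
  S4Vectors::mcols(gr)$gene_id <- genes$gene_id
  S4Vectors::mcols(gr)$transcript_id <- genes$transcript_id
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' Spliced transcript sequence(s)
#'
#' Concatenates exon sequences in transcription order, reverse-complementing
#' minus-strand transcripts.
#'
#' @param genes A [gene_models()] table.
#' @param genome Named character vector from [read_genome()].
#' @param transcript_ids Transcripts to extract (default: all).
#' @return Named character vector of spliced sequences.
#' @export
spliced_sequence <- function(genes, genome, transcript_ids = NULL) {
  if (is.null(transcript_ids)) transcript_ids <- unique(genes$transcript_id)
  out <- vapply(transcript_ids, function(tx) {
    e <- genes[genes$transcript_id == tx, , drop = FALSE]
    if (nrow(e) == 0L) stop("unknown transcript: ", tx)
    e <- e[order(e$start), , drop = FALSE]
    chrom <- genome[[e$chrom[1L]]]
    if (is.null(chrom)) stop("chromosome absent from genome: ", e$chrom[1L])
    s <- paste(substring(chrom, e$start, e$end), collapse = "")
    if (e$strand[1L] == "-") revcomp(s) else s
  }, character(1))
  stats::setNames(out, transcript_ids)
}

#' @export
print.gene_models <- function(x, ...) {
  cat("gene_models: ", length(unique(x$gene_id)), " gene(s), ",
      length(unique(x$transcript_id)), " transcript(s), ",
      nrow(x), " exon(s)\n", sep = "")
  print(utils::head(as.data.frame(x), 10L))
  if (nrow(x) > 10L) cat("...\n")
  invisible(x)
}

# Gene body spans (min start / max end across transcripts), used by the
# junction classifier and the homology database.
gene_spans <- function(genes) {
  sp <- split(seq_len(nrow(genes)), genes$gene_id)
  do.call(rbind, lapply(names(sp), function(g) {
    idx <- sp[[g]]
    data.frame(gene_id = g,
               chrom = genes$chrom[idx[1L]],
               strand = genes$strand[idx[1L]],
               start = min(genes$start[idx]),
               end = max(genes$end[idx]),
               stringsAsFactors = FALSE)
  }))
}

#' Read a FASTQ file
#'
#' Minimal reader for standard 4-line-per-record FASTQ (plain or gzipped);
#' qualities are ignored by the scanner and not returned.
#'
#' @param path FASTQ path.
#' @return List with `ids` and `seqs` character vectors.
#' @export
read_fastq <- function(path) {
  acc_ids <- list(); acc_seqs <- list(); i <- 0L
  stream_fastq(path, function(ids, seqs) {
    i <<- i + 1L
    acc_ids[[i]] <<- ids
    acc_seqs[[i]] <<- seqs
  })
  list(ids = unlist(acc_ids) %||% character(0),
       seqs = unlist(acc_seqs) %||% character(0))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Stream a FASTQ file in chunks, calling fun(ids, seqs) per chunk.
# Returns the total number of reads.  Errors on truncated records,
# reporting the 1-based index of the offending read.
stream_fastq <- function(path, fun, chunk_size = 20000L) {
  if (!file.exists(path)) stop("FASTQ not found: ", path)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  total <- 0L
  repeat {
    lines <- readLines(con, n = 4L * chunk_size)
    if (length(lines) == 0L) break
    if (length(lines) %% 4L != 0L)
      stop("truncated FASTQ record at read index ",
           total + length(lines) %/% 4L + 1L, " in ", path)
    hd <- lines[seq(1L, length(lines), by = 4L)]
    pl <- lines[seq(3L, length(lines), by = 4L)]
    bad <- which(!startsWith(hd, "@") | !startsWith(pl, "+"))
    if (length(bad))
      stop("malformed FASTQ record at read index ", total + bad[1L],
           " in ", path)
    ids <- sub("\\s.*$", "", substring(hd, 2L))
    seqs <- toupper(lines[seq(2L, length(lines), by = 4L)])
    fun(ids, seqs)
    total <- total + length(ids)
  }
  total
}

#' Write reads to FASTQ
#'
#' Constant placeholder qualities (`I`, Phred 40) are written; the detection
#' method does not use base qualities.
#'
#' @param seqs Character vector of read sequences.
#' @param ids Read identifiers (default `read1..readN`).
#' @param path Output path (`.gz` supported).
#' @return `path`, invisibly.
#' @export
write_fastq <- function(seqs, ids = NULL, path = tempfile(fileext = ".fq")) {
  if (is.null(ids)) ids <- paste0("read", seq_along(seqs))
  stopifnot(length(ids) == length(seqs))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  if (length(seqs)) {
    block <- rbind(paste0("@", ids), seqs, "+", strrep("I", nchar(seqs)))
    writeLines(as.vector(block), con)
  }
  invisible(path)
}
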
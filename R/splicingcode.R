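#' Extract per-intron paired exonic keys
#'
#' For every adjacent exon pair of every transcript one record is produced,
#' in transcription order: the donor key is the last `k` bases of the
#' upstream exon and the acceptor key the first `k` bases of the downstream
#' exon, both in spliced (strand-aware) orientation.  Records whose flanking
#' exon is shorter than `k` are dropped with a message reporting the count.
#'
#' `donor_coord` / `acceptor_coord` are the genomic coordinates (1-based) of
#' the junction-adjacent exon bases in transcription direction: for a plus-
#' strand gene the donor exon's `end` and the acceptor exon's `start`; for a
#' minus-strand gene the donor exon's `start` and the acceptor exon's `end`.
#'
#' @param genes A [gene_models()] table.
#' @param genome Named character vector from [read_genome()].
#' @param k Key length in bases (default 20).
#' @return Data frame of intron records with empty `flags`.
#' @export
extract_introns <- function(genes, genome, k = 20L) {
  k <- as.integer(k)
  stopifnot(k >= 1L)
  bad <- setdiff(unique(genes$chrom), names(genome))
  if (length(bad)) stop("annotation/genome mismatch, unknown chromosome(s): ",
                        paste(bad, collapse = ", "))
  sp <- split(seq_len(nrow(genes)), genes$transcript_id)
  dropped <- 0L
  recs <- lapply(sp, function(idx) {
    e <- genes[idx, , drop = FALSE]
    e <- e[order(e$start), , drop = FALSE]
    n <- nrow(e)
    if (n < 2L) return(NULL)
    minus <- e$strand[1L] == "-"
    if (minus) e <- e[rev(seq_len(n)), , drop = FALSE]  # transcription order
    chrom <- genome[[e$chrom[1L]]]
    don <- e[-n, , drop = FALSE]   # upstream exon of each intron
    acc <- e[-1L, , drop = FALSE]  # downstream exon
    wid_d <- don$end - don$start + 1L
    wid_a <- acc$end - acc$start + 1L
    keep <- wid_d >= k & wid_a >= k
    dropped <<- dropped + sum(!keep)
    if (!any(keep)) return(NULL)
    don <- don[keep, , drop = FALSE]; acc <- acc[keep, , drop = FALSE]
    if (!minus) {
      donor_key <- substring(chrom, don$end - k + 1L, don$end)
      acceptor_key <- substring(chrom, acc$start, acc$start + k - 1L)
      donor_coord <- don$end
      acceptor_coord <- acc$start
      intron_len <- acc$start - don$end - 1L
    } else {
      donor_key <- revcomp(substring(chrom, don$start, don$start + k - 1L))
      acceptor_key <- revcomp(substring(chrom, acc$end - k + 1L, acc$end))
      donor_coord <- don$start
      acceptor_coord <- acc$end
      intron_len <- don$start - acc$end - 1L
    }
    data.frame(
      gene_id = don$gene_id,
      transcript_id = don$transcript_id,
      intron_index = which(keep),
      chrom = don$chrom,
      strand = don$strand,
      donor_coord = donor_coord,
      acceptor_coord = acceptor_coord,
      intron_length = intron_len,
      donor_key = donor_key,
      acceptor_key = acceptor_key,
      flags = "",
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, recs)
  if (is.null(out))
    out <- data.frame(gene_id = character(0), transcript_id = character(0),
                      intron_index = integer(0), chrom = character(0),
                      strand = character(0), donor_coord = integer(0),
                      acceptor_coord = integer(0), intron_length = integer(0),
                      donor_key = character(0), acceptor_key = character(0),
                      flags = character(0), stringsAsFactors = FALSE)
  out <- out[order(out$gene_id, out$transcript_id, out$intron_index), ,
             drop = FALSE]
  rownames(out) <- NULL
  if (dropped > 0L)
    message("extract_introns: dropped ", dropped,
            " intron record(s) with a flanking exon shorter than k = ", k)
  attr(out, "k") <- k
  out
}

# Shannon entropy (bits) of mononucleotide frequencies of each key.
key_entropy <- function(keys) {
  vapply(keys, function(s) {
    p <- table(strsplit(s, "", fixed = TRUE)[[1L]])
    p <- p / sum(p)
    -sum(p * log2(p))
  }, numeric(1), USE.NAMES = FALSE)
}

# Longest homopolymer run in each key.
max_run <- function(keys) {
  vapply(keys, function(s) {
    r <- rle(strsplit(s, "", fixed = TRUE)[[1L]])
    max(r$lengths)
  }, numeric(1), USE.NAMES = FALSE)
}

#' Filter a splicingcode key table
#'
#' Removes, in order: records with any non-ACGT base in either key (poor
#' quality); records whose key is low-complexity (mononucleotide Shannon
#' entropy below `entropy_min` bits, or a homopolymer run of at least
#' `run_max`; highly repetitive); exact duplicates of the
#' (donor_key, acceptor_key) pair, keeping the first record in the
#' deterministic (gene_id, transcript_id, intron_index) sort — every member
#' of a duplicated group, including the kept one, is flagged `duplicate`;
#' and records whose donor or acceptor key occurs in more than
#' `max_gene_hits` distinct genes (flagged `ambiguous`).
#'
#' The operation is idempotent; raw/retained counts are recorded in the
#' `counts` attribute.
#'
#' @param records Output of [extract_introns()].
#' @param entropy_min Minimum key entropy in bits (default 1.0).
#' @param run_max Homopolymer run length treated as repetitive (default 15).
#' @param max_gene_hits Maximum distinct genes a key may occur in (default 2).
#' @return Filtered records with populated `flags`.
#' @export
filter_table <- function(records, entropy_min = 1.0, run_max = 15L,
                         max_gene_hits = 2L) {
  records <- records[order(records$gene_id, records$transcript_id,
                           records$intron_index), , drop = FALSE]
  rownames(records) <- NULL
  raw <- nrow(records)
  flags <- strsplit(records$flags, ",", fixed = TRUE)
  flags <- lapply(flags, function(f) f[nzchar(f)])
  add_flag <- function(which, flag) {
    flags[which] <<- lapply(flags[which], function(f) union(f, flag))
  }

  ambig <- grepl("[^ACGT]", records$donor_key) |
    grepl("[^ACGT]", records$acceptor_key)
  add_flag(ambig, "ambiguous_base")

  lowc <- rep(FALSE, raw)
  ok <- !ambig
  if (any(ok)) {
    lowc[ok] <- key_entropy(records$donor_key[ok]) < entropy_min |
      key_entropy(records$acceptor_key[ok]) < entropy_min |
      max_run(records$donor_key[ok]) >= run_max |
      max_run(records$acceptor_key[ok]) >= run_max
  }
  add_flag(lowc, "low_complexity")

  pair <- paste(records$donor_key, records$acceptor_key, sep = "|")
  dup_pair <- pair %in% pair[duplicated(pair)]
  add_flag(dup_pair, "duplicate")
  dup_drop <- duplicated(pair)  # keep first of each group

  # gene-level ambiguity of individual keys
  key_gene_hits <- function(keys) {
    ng <- vapply(split(records$gene_id, keys),
                 function(g) length(unique(g)), integer(1))
    ng[keys]
  }
  too_many <- key_gene_hits(records$donor_key) > max_gene_hits |
    key_gene_hits(records$acceptor_key) > max_gene_hits
  add_flag(too_many, "ambiguous")

  drop <- ambig | lowc | dup_drop | too_many
  records$flags <- vapply(flags, paste, character(1), collapse = ",")
  out <- records[!drop, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "k") <- attr(records, "k")
  attr(out, "counts") <- c(raw = raw, retained = nrow(out))
  out
}

#' Index a filtered key table for O(1) lookup
#'
#' @param records Filtered intron records ([filter_table()]).
#' @return A `splicingcode_table`: records plus donor/acceptor key indices
#'   (maps from k-mer to record row numbers) and raw/retained counts.
#' @export
build_key_index <- function(records) {
  lens <- unique(c(nchar(records$donor_key), nchar(records$acceptor_key)))
  if (length(lens) > 1L)
    stop("records have unequal key lengths: ", paste(lens, collapse = ", "))
  k <- if (length(lens)) lens else attr(records, "k") %||% 20L
  counts <- attr(records, "counts") %||%
    c(raw = nrow(records), retained = nrow(records))
  structure(list(
    k = as.integer(k),
    records = records,
    donor_index = split(seq_len(nrow(records)), records$donor_key),
    acceptor_index = split(seq_len(nrow(records)), records$acceptor_key),
    counts = counts
  ), class = "splicingcode_table")
}

#' Look up a k-mer in a key index
#'
#' @param table A `splicingcode_table`.
#' @param kmer Character vector of k-mers.
#' @param side `"donor"` or `"acceptor"`.
#' @return List of integer vectors of record row numbers (empty when absent).
#' @export
lookup_key <- function(table, kmer, side = c("donor", "acceptor")) {
  side <- match.arg(side)
  idx <- if (side == "donor") table$donor_index else table$acceptor_index
  out <- idx[kmer]
  out[vapply(out, is.null, logical(1))] <- list(integer(0))
  stats::setNames(out, kmer)
}

#' Build a ready-to-scan splicingcode table
#'
#' Runs [extract_introns()], [filter_table()] and [build_key_index()], then
#' attaches the spliced sequence context needed by flank extension: for each
#' record, the spliced transcript prefix ending at the donor junction and the
#' spliced suffix starting at the acceptor exon.
#'
#' @inheritParams extract_introns
#' @inheritParams filter_table
#' @return A `splicingcode_table` ready for [scan_reads()].
#' @export
build_splicingcode <- function(genes, genome, k = 20L, entropy_min = 1.0,
                               run_max = 15L, max_gene_hits = 2L) {
  rec <- extract_introns(genes, genome, k = k)
  rec <- filter_table(rec, entropy_min = entropy_min, run_max = run_max,
                      max_gene_hits = max_gene_hits)
  tab <- build_key_index(rec)
  tab$genes <- genes
  tab$genome_lengths <- nchar(genome)
  if (nrow(rec)) {
    txs <- unique(rec$transcript_id)
    seqs <- spliced_sequence(genes, genome, txs)
    # spliced offset of each donor junction = cumulative exon length through
    # the donor exon (transcription order)
    pref <- character(nrow(rec)); suff <- character(nrow(rec))
    for (tx in txs) {
      e <- genes[genes$transcript_id == tx, , drop = FALSE]
      e <- e[order(e$exon_rank), , drop = FALSE]
      cum <- cumsum(e$end - e$start + 1L)
      ri <- which(rec$transcript_id == tx)
      off <- cum[rec$intron_index[ri]]
      pref[ri] <- substring(seqs[[tx]], 1L, off)
      suff[ri] <- substring(seqs[[tx]], off + 1L, nchar(seqs[[tx]]))
    }
    tab$donor_prefix <- pref
    tab$acceptor_suffix <- suff
  } else {
    tab$donor_prefix <- character(0)
    tab$acceptor_suffix <- character(0)
  }
  tab
}

#' @export
print.splicingcode_table <- function(x, ...) {
  cat("splicingcode_table: k = ", x$k, "; ", nrow(x$records),
      " retained intron record(s) (raw ", x$counts[["raw"]], ")\n", sep = "")
  cat("  ", length(x$donor_index), " distinct donor key(s), ",
      length(x$acceptor_index), " distinct acceptor key(s)\n", sep = "")
  invisible(x)
}

#' Serialize a splicingcode table to TSV (+ JSON sidecar)
#'
#' @param table A `splicingcode_table`.
#' @param path Output TSV path; `<path>.json` receives `k` and the
#'   raw/retained counts.
#' @return `path`, invisibly.
#' @export
write_splicingcode <- function(table, path) {
  utils::write.table(table$records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(
    list(k = table$k,
         raw = unname(table$counts[["raw"]]),
         retained = unname(table$counts[["retained"]])),
    paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read a serialized splicingcode table
#'
#' Restores records and indices; spliced sequence context (needed for
#' scanning) is re-attached when `genes` and `genome` are supplied.
#'
#' @param path TSV written by [write_splicingcode()].
#' @param genes,genome Optional annotation/genome to re-attach scan context.
#' @return A `splicingcode_table`.
#' @export
read_splicingcode <- function(path, genes = NULL, genome = NULL) {
  rec <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = c(flags = "character"))
  rec$flags[is.na(rec$flags)] <- ""
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side)
    attr(rec, "k") <- as.integer(meta$k)
    attr(rec, "counts") <- c(raw = as.integer(meta$raw),
                             retained = as.integer(meta$retained))
  }
  if (!is.null(genes) && !is.null(genome)) {
    tab <- build_splicingcode(genes, genome,
                              k = attr(rec, "k") %||% 20L)
    return(tab)
  }
  build_key_index(rec)
}
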
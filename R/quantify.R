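#' Aggregate accepted calls into unique fusion junctions
#'
#' Junction identity is the 4-tuple (donor gene, donor genomic junction
#' coordinate, acceptor gene, acceptor genomic junction coordinate), so
#' novel isoforms are first-class.  With `dedup_identical_reads` on,
#' byte-identical read sequences within a sample contribute once (PCR
#' duplicates); default off, reporting raw counts.
#'
#' @param calls Accepted rows of a `junction_calls` data frame (a
#'   `sample_id` column is added as `"sample1"` when absent).
#' @param dedup_identical_reads Collapse byte-identical reads (default
#'   FALSE).
#' @return Data frame of class `fusion_junctions`: one row per unique
#'   junction with `support` (total reads); the `per_sample` attribute holds
#'   the long-format per-sample counts.
#' @export
aggregate_junctions <- function(calls, dedup_identical_reads = FALSE) {
  calls <- as.data.frame(calls)
  if (nrow(calls) && !is.null(calls$verdict))
    calls <- calls[calls$verdict == "accepted", , drop = FALSE]
  if (is.null(calls$sample_id)) calls$sample_id <- rep("sample1", nrow(calls))
  if (dedup_identical_reads && nrow(calls)) {
    calls <- calls[!duplicated(paste(calls$sample_id, calls$donor_gene,
                                     calls$donor_coord, calls$acceptor_gene,
                                     calls$acceptor_coord, calls$read_seq)), ,
                   drop = FALSE]
  }
  if (nrow(calls) == 0L) {
    out <- data.frame(junction_id = character(0), donor_gene = character(0),
                      donor_coord = integer(0), acceptor_gene = character(0),
                      acceptor_coord = integer(0), support = integer(0),
                      stringsAsFactors = FALSE)
    attr(out, "per_sample") <- data.frame(junction_id = character(0),
                                          sample_id = character(0),
                                          count = integer(0))
    class(out) <- c("fusion_junctions", "data.frame")
    return(out)
  }
  jid <- paste(calls$donor_gene, calls$donor_coord, calls$acceptor_gene,
               calls$acceptor_coord, sep = ":")
  per <- as.data.frame(table(junction_id = jid, sample_id = calls$sample_id),
                       stringsAsFactors = FALSE)
  names(per)[3L] <- "count"
  per <- per[per$count > 0L, , drop = FALSE]
  rownames(per) <- NULL
  first <- !duplicated(jid)
  out <- data.frame(junction_id = jid[first],
                    donor_gene = calls$donor_gene[first],
                    donor_coord = calls$donor_coord[first],
                    acceptor_gene = calls$acceptor_gene[first],
                    acceptor_coord = calls$acceptor_coord[first],
                    stringsAsFactors = FALSE)
  supp <- table(jid)
  out$support <- as.integer(supp[out$junction_id])
  out <- out[order(-out$support, out$junction_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "per_sample") <- per
  class(out) <- c("fusion_junctions", "data.frame")
  out
}

#' @export
print.fusion_junctions <- function(x, ...) {
  cat("fusion_junctions: ", nrow(x), " unique junction(s), total support ",
      sum(x$support), "\n", sep = "")
  print(as.data.frame(x))
  invisible(x)
}

#' Splice junctions per million reads (NSJMR)
#'
#' `count * 1e6 / total_reads`; exactly scale-invariant under proportional
#' scaling of both arguments.
#'
#' @param count Junction support count (vectorized).
#' @param total_reads Total reads in the sample (>= 1).
#' @return Reads-per-million value(s).
#' @examples
#' nsjmr(5, 1e7)    # 0.5
#' nsjmr(14, 2e7)   # 0.7
#' @export
nsjmr <- function(count, total_reads) {
  if (any(total_reads < 1)) stop("total_reads must be >= 1")
  count * 1e6 / total_reads
}

#' Minimum-depth sample gate
#'
#' Samples below the read-depth gate are unreliable for presence/absence
#' typing of a low-abundance fusion and are excluded from cohort statistics.
#'
#' @param total_reads Total reads per sample (vectorized).
#' @param gate Minimum total reads (default 2e7).
#' @return Logical vector: passes the gate.
#' @export
passes_depth_gate <- function(total_reads, gate = 2e7) {
  total_reads >= gate
}

#' Per-sample NSJMR matrix
#'
#' @param junctions A `fusion_junctions` object from [aggregate_junctions()].
#' @param total_reads Named numeric vector of per-sample total read counts.
#' @return Numeric matrix, junctions x samples, of NSJMR values.
#' @export
nsjmr_matrix <- function(junctions, total_reads) {
  per <- attr(junctions, "per_sample")
  samples <- names(total_reads)
  m <- matrix(0, nrow = nrow(junctions), ncol = length(samples),
              dimnames = list(junctions$junction_id, samples))
  if (nrow(per)) {
    per <- per[per$sample_id %in% samples, , drop = FALSE]
    m[cbind(per$junction_id, per$sample_id)] <- per$count
  }
  sweep(m, 2L, total_reads, function(cnt, tot) nsjmr(cnt, tot))
}

#' Translate the longest open reading frame of a fusion transcript
#'
#' Scans the three forward frames for ATG...stop ORFs (standard genetic
#' code); returns the longest peptide, ties broken by the leftmost start;
#' empty string when no complete ORF exists.
#'
#' @param seq DNA sequence over ACGT.
#' @return Single-letter amino-acid string (stop excluded).
#' @examples
#' translate_fusion_orf("ATGAAATAG")  # "MK"
#' @export
translate_fusion_orf <- function(seq) {
  seq <- toupper(seq)
  if (grepl("[^ACGT]", seq)) stop("sequence contains non-ACGT base(s)")
  n <- nchar(seq)
  best_len <- -1L; best_pos <- NA_integer_; best_pep <- ""
  gc <- Biostrings::GENETIC_CODE
  for (frame in 0:2) {
    ncod <- (n - frame) %/% 3L
    if (ncod < 2L) next
    starts0 <- frame + 3L * (seq_len(ncod) - 1L) + 1L
    codons <- substring(seq, starts0, starts0 + 2L)
    aa <- gc[codons]
    is_start <- codons == "ATG"
    is_stop <- aa == "*"
    stop_idx <- which(is_stop)
    for (st in which(is_start)) {
      nxt <- stop_idx[stop_idx > st]
      if (length(nxt) == 0L) next
      len <- nxt[1L] - st  # codons in peptide
      pos <- starts0[st]   # genomic position of the ATG
      if (len > best_len || (len == best_len && pos < best_pos)) {
        best_len <- len; best_pos <- pos
        best_pep <- paste(aa[st:(nxt[1L] - 1L)], collapse = "")
      }
    }
  }
  best_pep
}
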
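#' Scanner parameters
#'
#' @param k Key length; must match the splicingcode table.
#' @param max_mismatch_extension Mismatches tolerated during flank extension
#'   (default 0: every compared base must be identical).
#' @param scan_revcomp Also scan the reverse complement of each read.
#' @param min_read_length Reads shorter than this are skipped (counted, not
#'   an error); must be at least `2 * k`.
#' @param require_distinct_genes Only report candidates whose donor and
#'   acceptor genes differ (default TRUE).
#' @param max_pairings A read matching more than this many distinct gene
#'   pairs at maximal matched length is ambiguous and returns no candidates.
#' @param anchor_at_read_start Restrict the donor key to the start of the
#'   read (the stricter anchoring variant; default FALSE scans all offsets).
#' @return List of class `scan_params`.
#' @export
scan_params <- function(k = 20L, max_mismatch_extension = 0L,
                        scan_revcomp = TRUE, min_read_length = 2L * k,
                        require_distinct_genes = TRUE, max_pairings = 4L,
                        anchor_at_read_start = FALSE) {
  k <- as.integer(k)
  min_read_length <- as.integer(min_read_length)
  if (min_read_length < 2L * k)
    stop("min_read_length must be at least 2 * k")
  structure(list(k = k,
                 max_mismatch_extension = as.integer(max_mismatch_extension),
                 scan_revcomp = isTRUE(scan_revcomp),
                 min_read_length = min_read_length,
                 require_distinct_genes = isTRUE(require_distinct_genes),
                 max_pairings = as.integer(max_pairings),
                 anchor_at_read_start = isTRUE(anchor_at_read_start)),
            class = "scan_params")
}

empty_candidates <- function() {
  data.frame(read_id = character(0), orientation = character(0),
             split_offset = integer(0),
             donor_gene = character(0), donor_transcript = character(0),
             donor_intron = integer(0), donor_coord = integer(0),
             acceptor_gene = character(0), acceptor_transcript = character(0),
             acceptor_intron = integer(0), acceptor_coord = integer(0),
             L5 = integer(0), L3 = integer(0), L = integer(0),
             p_random = numeric(0), read_seq = character(0),
             stringsAsFactors = FALSE)
}

# Count mismatches between two equal-length strings.
n_mismatch <- function(a, b) {
  if (nchar(a) != nchar(b)) stop("length mismatch")
  sum(charToRaw(a) != charToRaw(b))
}

#' Extend a key-anchored split across both flanks
#'
#' The read prefix before the donor key is compared base-by-base against the
#' spliced donor-transcript sequence upstream of the junction (crossing that
#' transcript's internal splice junctions as needed); the suffix after the
#' acceptor key is compared downstream along the spliced acceptor transcript.
#' Extension must consume the entire read; with
#' `max_mismatch_extension = 0` every compared base must be identical.
#' Running past a transcript end with read bases remaining is a failure,
#' not an error.
#'
#' @param read_seq The read sequence (oriented as matched).
#' @param split_offset Position in the read where the acceptor side begins
#'   minus one, i.e. the donor side is `read[1..split_offset]`.
#' @param donor_row,acceptor_row Record row numbers in `table$records`.
#' @param table A `splicingcode_table` from [build_splicingcode()].
#' @param params [scan_params()].
#' @return `c(L5, L3)` on success, `NULL` on failure.
#' @export
extend_candidate <- function(read_seq, split_offset, donor_row, acceptor_row,
                             table, params = scan_params(k = table$k)) {
  if (is.null(table$donor_prefix))
    stop("table lacks spliced sequence context; build it with ",
         "build_splicingcode()")
  len <- nchar(read_seq)
  pre <- substring(read_seq, 1L, split_offset)
  suf <- substring(read_seq, split_offset + 1L, len)
  dp <- table$donor_prefix[donor_row]
  as <- table$acceptor_suffix[acceptor_row]
  if (nchar(dp) < nchar(pre) || nchar(as) < nchar(suf)) return(NULL)
  m <- params$max_mismatch_extension
  if (m == 0L) {
    ok <- endsWith(dp, pre) && startsWith(as, suf)
  } else {
    mm <- n_mismatch(substring(dp, nchar(dp) - nchar(pre) + 1L, nchar(dp)),
                     pre) +
      n_mismatch(substring(as, 1L, nchar(suf)), suf)
    ok <- mm <= m
  }
  if (!ok) return(NULL)
  c(L5 = split_offset, L3 = len - split_offset)
}

# Vectorized core: scan a character vector of read sequences.
scan_core <- function(seqs, ids, table, params) {
  k <- table$k
  if (!is.null(params$k) && params$k != k)
    stop("params$k (", params$k, ") does not match table k (", k, ")")
  stats <- c(total = length(seqs), skipped_short = 0L, ambiguous = 0L,
             candidates = 0L)
  if (length(seqs) == 0L || nrow(table$records) == 0L)
    return(list(candidates = empty_candidates(), stats = stats))
  lens <- nchar(seqs)
  short <- lens < params$min_read_length
  stats[["skipped_short"]] <- sum(short)
  keep <- which(!short)
  if (length(keep) == 0L)
    return(list(candidates = empty_candidates(), stats = stats))

  dkeys <- names(table$donor_index)
  akeys <- names(table$acceptor_index)
  orientations <- c("forward", if (params$scan_revcomp) "revcomp")
  hits <- vector("list", 64L); nh <- 0L
  for (orient in orientations) {
    s2 <- if (orient == "revcomp") revcomp(seqs[keep]) else seqs[keep]
    maxlen <- max(lens[keep])
    shifts <- if (params$anchor_at_read_start) 1L else
      seq_len(maxlen - 2L * k + 1L)
    for (sh in shifts) {
      full <- lens[keep] >= sh + 2L * k - 1L
      if (!any(full)) next
      dwin <- substring(s2, sh, sh + k - 1L)
      awin <- substring(s2, sh + k, sh + 2L * k - 1L)
      di <- match(dwin, dkeys)
      ai <- match(awin, akeys)
      hit <- full & !is.na(di) & !is.na(ai)
      if (any(hit)) {
        w <- which(hit)
        nh <- nh + 1L
        if (nh > length(hits)) hits <- c(hits, vector("list", length(hits)))
        hits[[nh]] <- data.frame(ri = keep[w], orient = orient,
                                 split = sh + k - 1L,
                                 di = di[w], ai = ai[w],
                                 seq = s2[w], stringsAsFactors = FALSE)
      }
    }
  }
  if (nh == 0L)
    return(list(candidates = empty_candidates(), stats = stats))
  hits <- do.call(rbind, hits[seq_len(nh)])

  rec <- table$records
  out <- vector("list", nrow(hits)); no <- 0L
  for (i in seq_len(nrow(hits))) {
    drows <- table$donor_index[[dkeys[hits$di[i]]]]
    arows <- table$acceptor_index[[akeys[hits$ai[i]]]]
    for (dr in drows) for (ar in arows) {
      if (params$require_distinct_genes &&
          rec$gene_id[dr] == rec$gene_id[ar]) next
      ext <- extend_candidate(hits$seq[i], hits$split[i], dr, ar,
                              table, params)
      if (is.null(ext)) next
      no <- no + 1L
      out[[no]] <- data.frame(
        read_id = ids[hits$ri[i]], orientation = hits$orient[i],
        split_offset = hits$split[i],
        donor_gene = rec$gene_id[dr],
        donor_transcript = rec$transcript_id[dr],
        donor_intron = rec$intron_index[dr],
        donor_coord = rec$donor_coord[dr],
        acceptor_gene = rec$gene_id[ar],
        acceptor_transcript = rec$transcript_id[ar],
        acceptor_intron = rec$intron_index[ar],
        acceptor_coord = rec$acceptor_coord[ar],
        L5 = unname(ext[1L]), L3 = unname(ext[2L]),
        L = unname(ext[1L] + ext[2L]),
        p_random = as.numeric(random_match_probability(ext[1L] + ext[2L])),
        read_seq = seqs[hits$ri[i]],
        stringsAsFactors = FALSE)
    }
  }
  if (no == 0L)
    return(list(candidates = empty_candidates(), stats = stats))
  cand <- do.call(rbind, out[seq_len(no)])

  # per read: keep maximal-L candidates, deduplicate junction/transcript
  # multiplicity, apply the ambiguity cap, order deterministically
  res <- vector("list", length(unique(cand$read_id))); nr <- 0L
  for (ri in split(seq_len(nrow(cand)), cand$read_id)) {
    cc <- cand[ri, , drop = FALSE]
    cc <- cc[cc$L == max(cc$L), , drop = FALSE]
    key <- paste(cc$orientation, cc$split_offset, cc$donor_gene,
                 cc$donor_coord, cc$acceptor_gene, cc$acceptor_coord)
    cc <- cc[order(cc$donor_gene, cc$acceptor_gene, cc$split_offset,
                   cc$donor_transcript, cc$acceptor_transcript), ,
             drop = FALSE]
    cc <- cc[!duplicated(paste(cc$orientation, cc$split_offset,
                               cc$donor_gene, cc$donor_coord,
                               cc$acceptor_gene, cc$acceptor_coord)), ,
             drop = FALSE]
    npairs <- length(unique(paste(cc$donor_gene, cc$acceptor_gene)))
    if (npairs > params$max_pairings) {
      stats[["ambiguous"]] <- stats[["ambiguous"]] + 1L
      next
    }
    nr <- nr + 1L
    res[[nr]] <- cc
  }
  cands <- if (nr) do.call(rbind, res[seq_len(nr)]) else empty_candidates()
  rownames(cands) <- NULL
  stats[["candidates"]] <- nrow(cands)
  list(candidates = cands, stats = stats)
}

#' Scan reads for junction-spanning fusion evidence
#'
#' At every read offset `p` the scanner looks up `read[p-k+1..p]` in the
#' donor key index and `read[p+1..p+k]` in the acceptor key index; each
#' (donor record, acceptor record) combination with distinct genes is
#' subjected to exact flank extension ([extend_candidate()]).  Only
#' candidates of maximal total matched length `L` are kept; reads matching
#' more than `max_pairings` distinct gene pairs are dropped as ambiguous.
#' The reverse complement is scanned identically when `scan_revcomp`.
#'
#' @param seqs Character vector of read sequences.
#' @param table A `splicingcode_table` from [build_splicingcode()].
#' @param params [scan_params()].
#' @param ids Read identifiers (default `read1..readN`).
#' @return List with `candidates` (data frame, one row per candidate) and
#'   `stats` (total, skipped_short, ambiguous, candidates).
#' @export
scan_reads <- function(seqs, table, params = scan_params(k = table$k),
                       ids = NULL) {
  if (is.null(ids)) ids <- paste0("read", seq_along(seqs))
  stopifnot(length(ids) == length(seqs))
  scan_core(toupper(seqs), ids, table, params)
}

#' Scan a single read
#'
#' @inheritParams scan_reads
#' @param seq A single read sequence.
#' @param id Read identifier.
#' @return Candidate data frame (possibly empty).
#' @export
scan_read <- function(seq, table, params = scan_params(k = table$k),
                      id = "read1") {
  scan_reads(seq, table, params, ids = id)$candidates
}

#' Scan a FASTQ file
#'
#' Streams the file in chunks (constant memory in read count); deterministic
#' for a fixed input.  A truncated record raises an error reporting the read
#' index.
#'
#' @param path FASTQ path (4-line records; `.gz` supported).
#' @param table A `splicingcode_table`.
#' @param params [scan_params()].
#' @param chunk_size Reads per chunk.
#' @return List with `candidates` and `stats` as in [scan_reads()].
#' @export
scan_fastq <- function(path, table, params = scan_params(k = table$k),
                       chunk_size = 20000L) {
  acc <- list(); st <- c(total = 0L, skipped_short = 0L, ambiguous = 0L,
                         candidates = 0L)
  stream_fastq(path, function(ids, seqs) {
    r <- scan_core(seqs, ids, table, params)
    if (nrow(r$candidates)) acc[[length(acc) + 1L]] <<- r$candidates
    st <<- st + r$stats
  }, chunk_size = chunk_size)
  cands <- if (length(acc)) do.call(rbind, acc) else empty_candidates()
  rownames(cands) <- NULL
  list(candidates = cands, stats = st)
}
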
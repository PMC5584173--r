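#' Run the full fusion-detection pipeline
#'
#' Convenience wrapper: scan reads against a splicingcode table, screen
#' candidates with the contiguous-locus homology filter, classify the
#' survivors, and return the calls with scan statistics.
#'
#' @param seqs Character vector of read sequences (or `NULL` with `fastq`).
#' @param table A `splicingcode_table` from [build_splicingcode()].
#' @param genes A [gene_models()] table.
#' @param genome Named character vector from [read_genome()].
#' @param ids Read identifiers.
#' @param fastq Optional FASTQ path scanned instead of `seqs`.
#' @param params [scan_params()].
#' @param db Optional prebuilt [build_homology_db()] (rebuilt otherwise).
#' @param max_mismatch_homology Homology mismatch budget (default 2).
#' @param read_through_gap See [classify_junction()].
#' @return List with `calls` (a `junction_calls` data frame, verdict +
#'   category), `accepted` (the accepted subset) and `stats`.
#' @export
detect_fusions <- function(seqs = NULL, table, genes, genome, ids = NULL,
                           fastq = NULL, params = scan_params(k = table$k),
                           db = NULL, max_mismatch_homology = 2L,
                           read_through_gap = 1e5) {
  scan <- if (!is.null(fastq)) scan_fastq(fastq, table, params)
  else scan_reads(seqs, table, params, ids = ids)
  if (is.null(db)) db <- build_homology_db(genes, genome)
  calls <- filter_candidates(scan$candidates, db, genes,
                             max_mismatch = max_mismatch_homology,
                             read_through_gap = read_through_gap)
  list(calls = calls,
       accepted = calls[calls$verdict == "accepted", , drop = FALSE],
       stats = scan$stats)
}
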
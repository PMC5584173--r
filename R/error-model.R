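#' Random-match probability of an L-base identical alignment
#'
#' Probability that a uniform random read reproduces a fixed L-base target
#' exactly, `0.25^L`, evaluated in log space so that large L (fully matched
#' 75-101 bp reads) does not underflow prematurely.
#'
#' @param L Matched length in bases (non-negative; vectorized).
#' @return Numeric vector of probabilities; the `log10` attribute carries
#'   the base-10 logarithms.
#' @examples
#' random_match_probability(40)   # two exact 20-bp keys, ~8.3e-25
#' @export
random_match_probability <- function(L) {
  if (any(is.na(L)) || any(L < 0)) stop("L must be non-negative")
  l10 <- -L * log10(4)
  p <- 10^l10
  p[L == 0] <- 1  # exact at L = 0
  attr(p, "log10") <- l10
  p
}

#' Dataset-level random-error summary
#'
#' `max_error` is the random-match probability at the minimum matched length
#' over candidates (the weakest accepted call); `median_error` uses the
#' median matched length (lower median for even counts).
#'
#' @param candidates A candidate data frame with an `L` column, or a numeric
#'   vector of matched lengths.
#' @return List with `min_L`, `median_L`, `max_error`, `median_error`,
#'   `n_candidates`.
#' @export
dataset_error_summary <- function(candidates) {
  L <- if (is.data.frame(candidates)) candidates$L else candidates
  if (length(L) == 0L) stop("no candidates: error summary undefined")
  L <- sort(as.numeric(L))
  med <- L[(length(L) + 1L) %/% 2L]  # lower median
  list(
    min_L = L[1L],
    median_L = med,
    max_error = as.numeric(random_match_probability(L[1L])),
    median_error = as.numeric(random_match_probability(med)),
    n_candidates = length(L)
  )
}

#' Expected number of random false fusion calls
#'
#' Linear expectation bound `n_reads * 0.25^L_min` for random-sequence
#' chimeras against a fixed minimal accepted match length.
#'
#' @param n_reads Number of reads screened.
#' @param L_min Minimal accepted matched length (e.g. `2 * k` = 40).
#' @return Expected count (numeric).
#' @export
expected_false_calls <- function(n_reads, L_min) {
  if (any(n_reads < 0)) stop("n_reads must be non-negative")
  n_reads * as.numeric(random_match_probability(L_min))
}
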
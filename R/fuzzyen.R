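#' Fuzzy entropy of a time series
#'
#' Complexity measure based on the similarity of mean-removed embedding
#' vectors: windows of size `m` (and `m + 1`) are compared with the Chebyshev
#' distance, similarity is graded by the smooth membership
#' \eqn{\exp(-\ln 2 \, (d/r)^2)}, and the entropy is
#' \eqn{\ln \Phi^m - \ln \Phi^{m+1}} where \eqn{\Phi} averages the pairwise
#' similarities. Regular, quasi-periodic signals (ECG) score low;
#' broadband noise-like signals (sEMG, white noise) score high. With the
#' default relative tolerance the measure is scale-invariant.
#'
#' @param x Numeric series (length >= m + 2).
#' @param m Embedding window size (default 2).
#' @param r_factor Tolerance as a multiple of `sd(x)` (default 0.2).
#' @param r Absolute tolerance; overrides `r_factor` when given.
#' @param window If non-`NULL`, the entropy is computed on a centered
#'   contiguous window of at most this many samples (keeps the O(N^2)
#'   pairwise computation tractable on long records).
#' @return Non-negative entropy value. A constant series (zero tolerance)
#'   returns 0 with a warning: all distances vanish, all memberships are 1.
#' @export
fuzzy_entropy <- function(x, m = 2L, r_factor = 0.2, r = NULL, window = NULL) {
  x <- as.numeric(x)
  m <- as.integer(m)
  if (m < 1L) stop_input("m must be >= 1")
  if (!is.null(window) && length(x) > window) {
    start <- (length(x) - window) %/% 2L + 1L
    x <- x[seq.int(start, length.out = window)]
  }
  if (length(x) < m + 2L) stop_input("series shorter than m + 2")
  if (is.null(r)) {
    s <- stats::sd(x)
    if (s == 0) {
      warning("constant series: tolerance degenerates, returning 0",
              call. = FALSE)
      return(0)
    }
    r <- r_factor * s
  }
  if (r <= 0) stop_input("tolerance r must be positive")
  fuzzyen_cpp(x, m, r)
}
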
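#' Pearson correlation coefficient
#'
#' \eqn{CC = \mathrm{Cov}(x, y) / \sqrt{\mathrm{Var}(x)\mathrm{Var}(y)}}.
#'
#' @param x,y Equal-length numeric vectors, both non-constant.
#' @return Value in \[-1, 1\].
#' @export
correlation_coefficient <- function(x, y) {
  if (length(x) != length(y)) stop_input("vectors must have equal length")
  if (length(x) < 2L) stop_input("need at least 2 samples")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop_input("correlation undefined for a constant input")
  }
  stats::cor(x, y)
}

#' Root mean square error
#'
#' @param estimate,reference Equal-length numeric vectors.
#' @return \eqn{\sqrt{N^{-1} \sum_i (S'_i - S_i)^2}}.
#' @export
rmse <- function(estimate, reference) {
  if (length(estimate) != length(reference)) {
    stop_input("vectors must have equal length")
  }
  sqrt(mean((estimate - reference)^2))
}

#' Signal-to-noise ratio in decibels
#'
#' This package's definition (reported alongside every use):
#' \eqn{10 \log_{10}( \sum s^2 / \sum (s - \hat{s})^2 )}, the ratio of
#' reference power to residual power.
#'
#' @param signal_ref Reference signal.
#' @param estimate Estimate of the reference.
#' @return Decibels; `Inf` (with attribute `zero_residual = TRUE`) when the
#'   estimate matches the reference exactly.
#' @export
snr_db <- function(signal_ref, estimate) {
  if (length(signal_ref) != length(estimate)) {
    stop_input("vectors must have equal length")
  }
  p_ref <- sum(signal_ref^2)
  if (p_ref == 0) stop_input("SNR undefined: reference has zero power")
  p_res <- sum((signal_ref - estimate)^2)
  if (p_res == 0) {
    return(structure(Inf, zero_residual = TRUE))
  }
  10 * log10(p_ref / p_res)
}

#' Relative error
#'
#' This package's definition: \eqn{\|\hat{s} - s\|_2 / \|s\|_2}, a
#' scale-free residual norm ratio.
#'
#' @param estimate,reference Equal-length vectors; `reference` non-zero.
#' @return Non-negative value.
#' @export
relative_error <- function(estimate, reference) {
  if (length(estimate) != length(reference)) {
    stop_input("vectors must have equal length")
  }
  nref <- sqrt(sum(reference^2))
  if (nref == 0) stop_input("relative error undefined: zero reference")
  sqrt(sum((estimate - reference)^2)) / nref
}

#' Amari separation performance index
#'
#' For `P = W_est %*% A_true` (in whitened space), measures the distance of
#' `P` from a scaled permutation:
#' \deqn{\frac{1}{2n}\left[\sum_i\left(\sum_j \frac{|p_{ij}|}{\max_k |p_{ik}|} - 1\right)
#'  + \sum_j\left(\sum_i \frac{|p_{ij}|}{\max_k |p_{kj}|} - 1\right)\right]}
#' Zero iff `P` is a scaled permutation; order-`n` for a maximally mixed
#' matrix.
#'
#' @param P Square numeric matrix.
#' @return Value in \[0, ~n\].
#' @export
amari_index <- function(P) {
  P <- as.matrix(P)
  if (nrow(P) != ncol(P)) stop_input("P must be square")
  ap <- abs(P)
  n <- nrow(P)
  rows <- rowSums(ap) / apply(ap, 1, max) - 1
  cols <- colSums(ap) / apply(ap, 2, max) - 1
  (sum(rows) + sum(cols)) / (2 * n)
}

#' Per-channel evaluation report
#'
#' @param estimate,reference `mc_record`s of identical shape.
#' @param reference_kind What the reference is: `"ground_truth"` (simulation)
#'   or `"pre_cleaning"`.
#' @return Data frame with one row per channel: `channel`, `cc`, `rmse`,
#'   `snr_db`, `re`, `reference_kind`.
#' @export
evaluate_record <- function(estimate, reference,
                            reference_kind = c("ground_truth", "pre_cleaning")) {
  reference_kind <- match.arg(reference_kind)
  stopifnot(inherits(estimate, "mc_record"), inherits(reference, "mc_record"))
  if (!all(dim(estimate$samples) == dim(reference$samples))) {
    stop_input("estimate and reference have different shapes")
  }
  rows <- lapply(seq_len(nrow(estimate$samples)), function(i) {
    e <- estimate$samples[i, ]
    r <- reference$samples[i, ]
    data.frame(channel = estimate$labels[i],
               cc = correlation_coefficient(e, r),
               rmse = rmse(e, r),
               snr_db = as.numeric(snr_db(r, e)),
               re = relative_error(e, r),
               reference_kind = reference_kind,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
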
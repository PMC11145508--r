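# Independent brute-force oracles, deliberately written as plain R loops and
# kept free of the package's computational kernels.

# fuzzy entropy via the definition: mean-removed embeddings, Chebyshev
# distance, exp(-ln2 (d/r)^2) membership, averaged over all pairs i != j
fuzzyen_oracle <- function(x, m, r) {
  phi <- function(mm, nv) {
    emb <- matrix(0, nv, mm)
    for (i in seq_len(nv)) {
      seg <- x[i:(i + mm - 1)]
      emb[i, ] <- seg - mean(seg)
    }
    tot <- 0
    for (i in seq_len(nv)) {
      for (j in seq_len(nv)) {
        if (i == j) next
        d <- max(abs(emb[i, ] - emb[j, ]))
        tot <- tot + exp(-log(2) * (d / r)^2)
      }
    }
    tot / (nv * (nv - 1))
  }
  N <- length(x)
  log(phi(m, N - m + 1)) - log(phi(m + 1, N - m))
}

# textbook Amari performance index as an explicit double loop
amari_oracle <- function(P) {
  n <- nrow(P)
  ap <- abs(P)
  tot <- 0
  for (i in seq_len(n)) {
    tot <- tot + sum(ap[i, ]) / max(ap[i, ]) - 1
  }
  for (j in seq_len(n)) {
    tot <- tot + sum(ap[, j]) / max(ap[, j]) - 1
  }
  tot / (2 * n)
}

# fraction of periodogram power inside a frequency band
band_power_fraction <- function(x, fs, band) {
  n <- length(x)
  p <- abs(fft(x))^2
  f <- (seq_len(n) - 1) * fs / n
  half <- f <= fs / 2
  inband <- half & f >= band[1] & f <= band[2]
  sum(p[inband]) / sum(p[half])
}

# sample peak positions above a relative threshold (local maxima)
find_peaks <- function(x, rel_height = 0.5) {
  thr <- rel_height * max(x)
  idx <- which(diff(sign(diff(x))) == -2) + 1L
  idx[x[idx] > thr]
}
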
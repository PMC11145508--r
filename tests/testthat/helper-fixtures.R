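# Seeded fixtures built in code at test time.

# three independent non-Gaussian-dominated sources (ECG train, band-limited
# Gaussian, uniform noise) mixed by a random well-conditioned square matrix
make_ica_fixture <- function(seed, n = 20000, fs = 1000) {
  dur <- n / fs
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max, 4)
  ecg <- generate_ecg(dur, fs, 72, rr_jitter_sd = 0.01, seed = seeds[1])
  bln <- generate_semg(dur, fs, c(20, 250), seed = seeds[2])
  set.seed(seeds[3])
  uni <- runif(n, -1, 1)
  S <- rbind(ecg$samples / sd(ecg$samples),
             bln$samples / sd(bln$samples),
             uni / sd(uni))
  set.seed(seeds[4])
  repeat {
    A <- matrix(rnorm(9), 3, 3)
    if (kappa(A) < 10) break
  }
  list(S = S, A = A, X = A %*% S, ecg = ecg$samples)
}

# contamination-free mixture (sEMG + two noise sources): the classifier
# should usually flag nothing
make_negative_control <- function(seed, duration = 60, fs = 1000) {
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max, 3)
  n <- duration * fs
  semg <- generate_semg(duration, fs,
                        bursts = data.frame(start = c(5, 30) * duration / 60,
                                            end = c(20, 50) * duration / 60,
                                            peak = 1),
                        seed = seeds[1])
  semg$samples <- semg$samples / sd(semg$samples)
  set.seed(seeds[2])
  g <- rnorm(n, 0, 0.5)
  set.seed(seeds[3])
  u <- runif(n, -0.5, 0.5)
  A <- matrix(c(1, 0.6, 0.4, 0.8, 1, 0.6, 0.3, 0.4, 1), 3, 3)
  mix_sources(list(semg = semg,
                   gauss = semgclean:::new_source_signal(g, fs, "noise", list()),
                   unif = semgclean:::new_source_signal(u, fs, "noise", list())),
              A)
}

# per-channel mean correlation with a reference source
mean_channel_cor <- function(mat, ref) {
  mean(vapply(seq_len(nrow(mat)), function(i) cor(mat[i, ], ref), numeric(1)))
}
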
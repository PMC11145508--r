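new_source_signal <- function(samples, fs, kind, params) {
  structure(list(samples = as.numeric(samples), fs = fs, kind = kind,
                 params = params),
            class = "source_signal")
}

#' @export
print.source_signal <- function(x, ...) {
  cat(sprintf("<source_signal:%s> %d samples @ %g Hz, sd = %.4g\n",
              x$kind, length(x$samples), x$fs, stats::sd(x$samples)))
  invisible(x)
}

# raised-cosine burst envelope; rest_level between bursts, `peak` inside each
burst_envelope <- function(n, fs, bursts, rest_level, ramp = 0.15) {
  env <- rep(rest_level, n)
  for (b in seq_len(nrow(bursts))) {
    i0 <- max(1L, round(bursts$start[b] * fs) + 1L)
    i1 <- min(n, round(bursts$end[b] * fs))
    if (i1 <= i0) next
    peak <- bursts$peak[b]
    nr <- min(round(ramp * fs), (i1 - i0) %/% 2L)
    seg <- rep(peak, i1 - i0 + 1L)
    if (nr > 0L) {
      up <- rest_level + (peak - rest_level) *
        (1 - cos(pi * seq_len(nr) / nr)) / 2
      seg[seq_len(nr)] <- up
      seg[seq.int(length(seg) - nr + 1L, length(seg))] <- rev(up)
    }
    env[i0:i1] <- seg
  }
  env
}

#' Generate a surrogate surface-EMG source
#'
#' Band-limited Gaussian noise (zero-phase Butterworth band-pass filtered)
#' whose amplitude is modulated by smooth raised-cosine burst envelopes,
#' emulating contraction bursts over a resting baseline. The result is
#' exactly zero-mean.
#'
#' @param duration Length in seconds.
#' @param fs Sampling rate in Hz (default 1000).
#' @param passband `c(low, high)` in Hz, `0 < low < high < fs/2`
#'   (default `c(20, 250)`, the conventional sEMG band).
#' @param bursts Data frame with columns `start`, `end` (seconds) and `peak`
#'   (relative amplitude), or `NULL` for a continuous (unmodulated) signal.
#'   Bursts must not overlap.
#' @param rest_level Relative amplitude between bursts (default 0.15).
#' @param order Butterworth order (default 4).
#' @param seed Optional RNG seed for reproducibility.
#' @return A `source_signal` of kind `"semg"`.
#' @export
generate_semg <- function(duration, fs = 1000, passband = c(20, 250),
                          bursts = NULL, rest_level = 0.15, order = 4,
                          seed = NULL) {
  if (fs <= 0 || duration <= 0) stop_input("duration and fs must be positive")
  if (length(passband) != 2L || passband[1] <= 0 ||
      passband[2] <= passband[1] || passband[2] >= fs / 2) {
    stop_input("passband must satisfy 0 < low < high < fs/2")
  }
  n <- round(duration * fs)
  if (!is.null(bursts)) {
    bursts <- as.data.frame(bursts)
    if (!all(c("start", "end", "peak") %in% names(bursts))) {
      stop_input("bursts needs columns start, end, peak")
    }
    if (any(bursts$start < 0) || any(bursts$end > duration) ||
        any(bursts$end <= bursts$start)) {
      stop_input("bursts must lie within [0, duration] with end > start")
    }
    o <- order(bursts$start)
    if (nrow(bursts) > 1L &&
        any(bursts$start[o][-1] < bursts$end[o][-nrow(bursts)])) {
      stop_input("bursts must not overlap")
    }
  }
  x <- with_seed(seed, stats::rnorm(n))
  bf <- signal::butter(order, passband / (fs / 2), type = "pass")
  x <- as.numeric(signal::filtfilt(bf, x))
  env <- if (is.null(bursts)) rep(1, n) else
    burst_envelope(n, fs, bursts, rest_level)
  x <- x * env
  x <- x - mean(x)
  new_source_signal(x, fs, "semg",
                   list(duration = duration, passband = passband,
                        bursts = bursts, rest_level = rest_level, seed = seed))
}

default_pqrst <- function() {
  data.frame(row.names = c("P", "Q", "R", "S", "T"),
             amplitude = c(0.12, -0.10, 1.00, -0.15, 0.30),
             width     = c(0.025, 0.010, 0.012, 0.010, 0.040),
             offset    = c(-0.18, -0.045, 0.00, 0.045, 0.28))
}

#' Generate a synthetic ECG source
#'
#' A quasi-periodic beat train in which each beat is the sum of five Gaussian
#' bumps (P, Q, R, S, T waves) at fixed time offsets from the R peak; beat
#' times are spaced by the RR interval `60 / heart_rate` with optional
#' Gaussian jitter. The train is regular and smooth, hence markedly lower in
#' fuzzy entropy than sEMG or broadband noise.
#'
#' @param duration Seconds.
#' @param fs Sampling rate in Hz (> 200; default 1000).
#' @param heart_rate Beats per minute, in \[20, 220\] (default 72).
#' @param wave_params Data frame with rows P,Q,R,S,T and columns `amplitude`
#'   (relative to R), `width` (Gaussian SD, seconds) and `offset` (seconds
#'   from the R peak). Defaults to a textbook-shaped morphology.
#' @param rr_jitter_sd SD of the per-beat timing jitter in seconds
#'   (default 0).
#' @param seed Optional RNG seed (used by the jitter).
#' @return A `source_signal` of kind `"ecg"`.
#' @export
generate_ecg <- function(duration, fs = 1000, heart_rate = 72,
                         wave_params = default_pqrst(), rr_jitter_sd = 0,
                         seed = NULL) {
  if (fs <= 200) stop_input("fs must exceed 200 Hz for ECG synthesis")
  if (heart_rate < 20 || heart_rate > 220) {
    stop_input("heart_rate must be within [20, 220] bpm")
  }
  if (any(wave_params$width <= 0)) stop_input("wave widths must be positive")
  n <- round(duration * fs)
  t <- (seq_len(n) - 1L) / fs
  rr <- 60 / heart_rate
  beats <- seq(0.3 * rr, duration, by = rr)
  if (rr_jitter_sd > 0) {
    beats <- beats + with_seed(seed, stats::rnorm(length(beats), 0, rr_jitter_sd))
  }
  x <- numeric(n)
  for (b in beats) {
    for (wv in seq_len(nrow(wave_params))) {
      a <- wave_params$amplitude[wv]
      if (a == 0) next
      w <- wave_params$width[wv]
      o <- wave_params$offset[wv]
      x <- x + a * exp(-0.5 * ((t - b - o) / w)^2)
    }
  }
  new_source_signal(x, fs, "ecg",
                   list(duration = duration, heart_rate = heart_rate,
                        wave_params = wave_params,
                        rr_jitter_sd = rr_jitter_sd, seed = seed))
}

#' Generate interference sources
#'
#' Returns three sources: a pure sinusoid at the mains frequency, a slow
#' sinusoid emulating baseline wander, and white Gaussian sensor noise.
#'
#' @param duration Seconds.
#' @param fs Sampling rate in Hz.
#' @param mains_freq Mains frequency in Hz (default 50; must be < fs/2).
#' @param mains_amp,wander_amp Peak amplitudes (0 disables).
#' @param wander_freq Baseline-wander frequency in Hz (default 0.3).
#' @param noise_sd White-noise standard deviation (0 disables).
#' @param seed Optional RNG seed (noise only).
#' @return Named list of `source_signal`s: `mains`, `wander`, `noise`.
#' @export
generate_interference <- function(duration, fs = 1000, mains_freq = 50,
                                  mains_amp = 1, wander_freq = 0.3,
                                  wander_amp = 1, noise_sd = 1, seed = NULL) {
  if (mains_freq >= fs / 2) stop_input("mains_freq must be below fs/2")
  if (wander_freq >= fs / 2) stop_input("wander_freq must be below fs/2")
  n <- round(duration * fs)
  t <- (seq_len(n) - 1L) / fs
  noise <- if (noise_sd > 0) {
    with_seed(seed, stats::rnorm(n, 0, noise_sd))
  } else numeric(n)
  list(
    mains = new_source_signal(mains_amp * sin(2 * pi * mains_freq * t), fs,
                              "mains", list(freq = mains_freq, amp = mains_amp)),
    wander = new_source_signal(wander_amp * sin(2 * pi * wander_freq * t), fs,
                               "wander", list(freq = wander_freq, amp = wander_amp)),
    noise = new_source_signal(noise, fs, "noise",
                              list(sd = noise_sd, seed = seed))
  )
}

#' Mix sources into an observed multichannel record
#'
#' Forms the instantaneous linear mixture `observed = mixing %*% sources`
#' plus optional iid Gaussian sensor noise, keeping the ground truth
#' (sources and mixing matrix) alongside the observation.
#'
#' @param sources List of `source_signal`s with equal length and sampling
#'   rate.
#' @param mixing Numeric matrix, `n_channels x n_sources` with
#'   `n_channels >= n_sources`. A rank-deficient matrix triggers a warning
#'   but is kept.
#' @param sensor_noise_sd SD of additive channel noise (default 0).
#' @param seed Optional RNG seed for the sensor noise.
#' @return An object of class `synthetic_ground_truth`: `sources`, `mixing`,
#'   `observed` (an `mc_record`), `sensor_noise_sd`.
#' @export
mix_sources <- function(sources, mixing, sensor_noise_sd = 0, seed = NULL) {
  if (!length(sources)) stop_input("sources must be non-empty")
  lens <- vapply(sources, function(s) length(s$samples), integer(1))
  fss <- vapply(sources, function(s) s$fs, numeric(1))
  if (length(unique(lens)) != 1L || length(unique(fss)) != 1L) {
    stop_input("all sources must share length and sampling rate")
  }
  mixing <- as.matrix(mixing)
  if (ncol(mixing) != length(sources)) {
    stop_input("mixing must have one column per source")
  }
  if (nrow(mixing) < ncol(mixing)) {
    stop_input("need at least as many channels as sources")
  }
  if (qr(mixing)$rank < ncol(mixing)) {
    warning("mixing matrix is rank-deficient; sources are not identifiable",
            call. = FALSE)
  }
  S <- do.call(rbind, lapply(sources, function(s) s$samples))
  X <- mixing %*% S
  if (sensor_noise_sd > 0) {
    X <- X + with_seed(seed, matrix(stats::rnorm(length(X), 0, sensor_noise_sd),
                                    nrow(X), ncol(X)))
  }
  kinds <- vapply(sources, function(s) s$kind, character(1))
  structure(list(sources = sources, mixing = mixing,
                 observed = new_record(X, fss[1],
                                       provenance = paste0("mix_sources(",
                                                           paste(kinds, collapse = "+"),
                                                           ")")),
                 sensor_noise_sd = sensor_noise_sd),
            class = "synthetic_ground_truth")
}

#' Simulate an ECG-contaminated sEMG recording with ground truth
#'
#' The package's reference simulation: three sources (bursting band-limited
#' sEMG, a 72 bpm ECG train, white noise) mixed into three channels by a
#' fixed full-rank matrix. The sEMG source is normalised to unit variance
#' and the ECG source is rescaled so that, averaged over the mixing weights,
#' the ECG contribution sits `contamination_db` decibels below the sEMG
#' contribution (0 dB = equal power, heavy contamination).
#'
#' @param seed RNG seed (fans out deterministically to the per-source
#'   generators).
#' @param duration Seconds (default 60, a typical contraction-protocol
#'   recording length).
#' @param fs Hz (default 1000).
#' @param contamination_db sEMG-to-ECG power ratio in dB (default 0).
#' @param noise_sd Relative SD of the white-noise source (default 0.3).
#' @param heart_rate ECG rate in bpm (default 72).
#' @param passband sEMG band in Hz (default `c(20, 250)`).
#' @return A `synthetic_ground_truth`; the ECG-free observation (mixture
#'   with the ECG column zeroed) is available via [ecg_free_channels()].
#' @export
simulate_contaminated <- function(seed = NULL, duration = 60, fs = 1000,
                                  contamination_db = 0, noise_sd = 0.3,
                                  heart_rate = 72, passband = c(20, 250)) {
  seeds <- derive_seeds(seed, 3L)
  bursts <- data.frame(start = c(0.5, 3.0) * duration / 6,
                       end = c(2.0, 5.0) * duration / 6,
                       peak = c(1, 1))
  semg <- generate_semg(duration, fs, passband, bursts, seed = seeds[[1]])
  semg$samples <- semg$samples / stats::sd(semg$samples)
  ecg <- generate_ecg(duration, fs, heart_rate, rr_jitter_sd = 0.01,
                      seed = seeds[[2]])
  A <- matrix(c(1.0, 0.6, 0.4,
                0.8, 1.0, 0.6,
                0.3, 0.4, 1.0), 3, 3)
  # equalise total mixed power: sum_i a_ecg,i^2 s^2 = 10^(-db/10) sum_i a_semg,i^2
  scale_ecg <- sqrt(10^(-contamination_db / 10) * sum(A[, 1]^2) / sum(A[, 2]^2))
  ecg$samples <- ecg$samples / stats::sd(ecg$samples) * scale_ecg
  noise <- new_source_signal(with_seed(seeds[[3]], stats::rnorm(round(duration * fs), 0, noise_sd)),
                             fs, "noise", list(sd = noise_sd, seed = seeds[[3]]))
  mix_sources(list(semg = semg, ecg = ecg, noise = noise), A)
}

#' ECG-free ground-truth channels of a simulated mixture
#'
#' Applies the mixing matrix with the columns of the named kinds zeroed,
#' giving the per-channel signal that an ideal artifact remover would
#' recover.
#'
#' @param gt A `synthetic_ground_truth`.
#' @param drop_kinds Source kinds to remove (default `"ecg"`).
#' @return Channels-by-samples matrix.
#' @export
ecg_free_channels <- function(gt, drop_kinds = "ecg") {
  stopifnot(inherits(gt, "synthetic_ground_truth"))
  A <- gt$mixing
  kinds <- vapply(gt$sources, function(s) s$kind, character(1))
  A[, kinds %in% drop_kinds] <- 0
  S <- do.call(rbind, lapply(gt$sources, function(s) s$samples))
  A %*% S
}
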
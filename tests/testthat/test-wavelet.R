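test_that("decomposition shape matches the level count and linearity holds", {
  set.seed(1)
  x <- rnorm(4096)
  d <- dwt_decompose(x, "db4", 9)
  expect_s3_class(d, "wavelet_decomposition")
  expect_length(d$details, 9)
  expect_equal(d$levels, 9)
  expect_equal(d$original_length, 4096)
  z <- dwt_decompose(rep(0, 512), "db4", 5)
  expect_true(all(unlist(z$details) == 0) && all(z$approx == 0))
})

test_that("infeasible level requests fail naming the maximum", {
  expect_error(dwt_decompose(rnorm(64), "db8", 9), "at most 2")
  expect_error(dwt_decompose(rnorm(100), "nosuch"), "unsupported wavelet")
})

test_that("forward/inverse transform round-trips within 1e-8", {
  set.seed(2)
  for (wav in c("db2", "db4", "db8")) {
    for (n in c(300, 1000, 4096)) {
      x <- rnorm(n)
      lev <- min(9L, dwt_max_level(n, wav))
      for (L in unique(c(1L, lev %/% 2L, lev))) {
        if (L < 1L) next
        xr <- dwt_reconstruct(dwt_decompose(x, wav, L))
        expect_lt(sqrt(sum((xr - x)^2) / sum(x^2)), 1e-8)
      }
    }
  }
})

test_that("universal threshold estimation tracks the noise scale", {
  d <- dwt_decompose(rep(0, 1024), "db4", 3)
  spec <- estimate_lambda(d)
  expect_equal(spec$lambdas, rep(0, 3))
  # sigma-hat converges to the true noise SD
  for (seed in 1:3) {
    set.seed(seed)
    d2 <- dwt_decompose(rnorm(2^17), "db1", 1)
    # db1 level-1 details of white N(0,1) noise are N(0,1)
    s2 <- estimate_lambda(d2)
    expect_lt(abs(s2$sigma - 1), 0.05)
  }
  d3 <- dwt_decompose(rnorm(512), "db4", 4)
  s3 <- estimate_lambda(d3, "manual", lambdas = 0.7)
  expect_identical(s3$lambdas, rep(0.7, 4))
  expect_error(estimate_lambda(d3, "manual"), "lambdas")
})

test_that("threshold rules reproduce their defining values", {
  expect_equal(apply_threshold(2, 1, "soft"), 1)
  expect_equal(apply_threshold(2, 1, "hard"), 2)
  expect_equal(apply_threshold(-2, 1, "soft"), -1)
  for (rule in c("hard", "soft", "improved")) {
    expect_equal(apply_threshold(0, 1, rule), 0)
  }
  # improved rule: exactly zero at the threshold, known value beyond it
  expect_equal(apply_threshold(1, 1, "improved"), 0)
  expect_equal(apply_threshold(3, 1, "improved"), 3 - 2 / (1 + exp(2)),
               tolerance = 1e-12)
  expect_equal(apply_threshold(3, 1, "improved"), 2.76159, tolerance = 1e-5)
  expect_error(apply_threshold(1, -0.5, "soft"), ">= 0")
})

test_that("improved rule is odd, continuous, dead-zoned and asymptotically unbiased", {
  set.seed(3)
  w <- runif(1e4, -20, 20)
  lam <- 1.3
  f <- apply_threshold(w, lam, "improved")
  expect_equal(f, -apply_threshold(-w, lam, "improved"), tolerance = 1e-14)
  expect_true(all(f[abs(w) < lam] == 0))
  # continuity at +/- lambda
  expect_lt(abs(apply_threshold(lam + 1e-9, lam, "improved")), 1e-6 * lam)
  expect_lt(abs(apply_threshold(-lam - 1e-9, lam, "improved")), 1e-6 * lam)
  # shrinkage vanishes far from the threshold
  expect_lt(abs((lam + 12) - apply_threshold(lam + 12, lam, "improved")),
            0.01 * lam)
  # energy never increases (soft and improved)
  for (rule in c("soft", "improved")) {
    fw <- apply_threshold(w, lam, rule)
    expect_lte(sum(fw^2), sum(w^2))
    expect_true(all(abs(fw) <= abs(w) + 1e-12))
  }
})

test_that("as-printed improved variant keeps a constant large-amplitude bias", {
  lam <- 1
  f <- apply_threshold(lam + 12, lam, "improved", variant = "as_printed")
  expect_equal((lam + 12) - f, 2 * lam, tolerance = 1e-4)
  expect_equal(apply_threshold(lam, lam, "improved", variant = "as_printed"), 0)
})

test_that("level selection honours its contract", {
  # zero threshold: denoising is the identity, baseline is maximal
  set.seed(4)
  x <- rnorm(1024)
  expect_equal(select_level(x, "db4", 6, lambda_method = "manual", lambdas = 0),
               1L)
  # huge manual threshold kills every detail: nothing beats level 1 -> fallback
  expect_equal(select_level(x, "db4", 6, lambda_method = "manual", lambdas = 50),
               6L)
  # estimated-SNR contract on a sinusoid in noise
  t <- (0:4095) / 1000
  y <- sin(2 * pi * 5 * t) + rnorm(4096, 0, 0.5)
  L <- select_level(y, "db4", 9)
  expect_gte(L, 1L)
  snr_est <- function(lev) {
    d <- semgclean:::denoise_signal(y, "db4", lev)
    10 * log10(sum(d^2) / sum((y - d)^2))
  }
  if (L < 9L) expect_gt(snr_est(L), snr_est(1L))
})

test_that("record denoising is the identity at zero threshold and output length is preserved", {
  set.seed(5)
  rec <- new_record(matrix(rnorm(3 * 2000), 3), 1000)
  out <- wavelet_denoise(rec, levels = 5, rule = "hard",
                         lambda_method = "manual", lambdas = 0)
  expect_lt(max(abs(out$samples - rec$samples)), 1e-8)
  expect_equal(dim(out$samples), dim(rec$samples))
  expect_match(tail(out$provenance, 1), "wavelet_denoise")
  # error propagation names the channel
  tiny <- new_record(matrix(rnorm(2 * 40), 2), 1000, labels = c("bicep", "tricep"))
  expect_error(wavelet_denoise(tiny, levels = 9), "bicep")
})

test_that("denoising brings a noisy sinusoid closer to the clean signal", {
  t <- (0:4095) / 1000
  clean <- sin(2 * pi * 5 * t)
  for (seed in 1:5) {
    set.seed(seed)
    noisy <- clean + rnorm(4096, 0, 0.5)
    den <- semgclean:::denoise_signal(noisy, "db4", 9, "improved")
    expect_gt(cor(den, clean), cor(noisy, clean))
  }
})
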
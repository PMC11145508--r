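test_that("centering removes per-channel means and round-trips exactly", {
  cen <- center_channels(matrix(c(1, 2, 3), 1))
  expect_equal(cen$X, matrix(c(-1, 0, 1), 1))
  expect_equal(cen$mean, 2)
  set.seed(1)
  X <- matrix(rnorm(5 * 200), 5)
  cen2 <- center_channels(X)
  expect_true(all(abs(rowMeans(cen2$X)) <= 1e-12))
  expect_equal(cen2$X + cen2$mean, X, tolerance = 1e-15)
  # idempotence on already-centered data
  cen3 <- center_channels(cen2$X)
  expect_equal(cen3$X, cen2$X, tolerance = 1e-12)
  expect_error(center_channels(matrix(1, 1, 1)), "2 samples")
})

test_that("whitening produces identity covariance and sensible eigensystems", {
  # diagonal covariance: closed-form whitening scales
  set.seed(2)
  n <- 20000
  X <- rbind(sqrt(2) * rnorm(n), sqrt(0.5) * rnorm(n))
  X <- X - rowMeans(X)
  wz <- pca_whiten(X)
  covz <- tcrossprod(wz$Z) / n
  expect_lt(max(abs(covz - diag(2))), 1e-8)
  expect_true(all(diff(wz$model$eigvals) <= 0))
  expect_equal(sort(abs(diag(wz$model$whiten %*% wz$model$dewhiten))), c(1, 1),
               tolerance = 1e-8)
  # rank-1 two-channel input collapses to one dimension
  x1 <- rnorm(1000)
  r1 <- pca_whiten(rbind(x1, 2 * x1) - rowMeans(rbind(x1, 2 * x1)), var_floor = 1e-6)
  expect_equal(r1$model$kept_dims, 1L)
  expect_error(pca_whiten(matrix(0, 2, 100)), "degenerate")
})

test_that("whitening invariant holds across random fixtures", {
  for (seed in 1:20) {
    set.seed(seed)
    k <- sample(2:5, 1)
    X <- matrix(rnorm(k * 3000), k) * runif(k, 0.5, 3)
    X <- X - rowMeans(X)
    wz <- pca_whiten(X)
    covz <- tcrossprod(wz$Z) / ncol(X)
    expect_lt(max(abs(covz - diag(nrow(covz)))), 1e-8)
  }
})

test_that("fixed-point update returns unit vectors and respects fixed points", {
  fx <- make_ica_fixture(11, n = 20000)
  cen <- center_channels(fx$X)
  wz <- pca_whiten(cen$X)
  set.seed(3)
  w <- semgclean:::normalize(rnorm(3))
  w1 <- fastica_update(w, wz$Z)
  expect_equal(sum(w1^2), 1, tolerance = 1e-12)
  # iterate to convergence, then one extra update must not move the vector
  for (i in 1:100) {
    w2 <- fastica_update(w, wz$Z)
    if (abs(sum(w2 * w)) >= 1 - 1e-12) break
    w <- w2
  }
  w_star <- fastica_update(w2, wz$Z)
  expect_gte(abs(sum(w_star * w2)), 1 - 1e-9)
})

test_that("gradient refinement is a no-op at zero steps and never lowers the surrogate", {
  fx <- make_ica_fixture(12, n = 10000)
  wz <- pca_whiten(center_channels(fx$X)$X)
  set.seed(4)
  w0 <- semgclean:::normalize(rnorm(3))
  expect_identical(as.vector(gradient_refine(w0, wz$Z, steps = 0)), w0)
  wr <- gradient_refine(w0, wz$Z, steps = 5)
  path <- attr(wr, "surrogate_path")
  expect_true(all(diff(path) >= 0))
  expect_equal(sum(wr^2), 1, tolerance = 1e-12)
})

test_that("refined starts do not need more fixed-point iterations than raw starts", {
  iters <- sapply(1:20, function(seed) {
    fx <- make_ica_fixture(seed, n = 5000)
    wz <- pca_whiten(center_channels(fx$X)$X)
    a <- extract_components(wz$Z, seed = seed, grad_refine_steps = 5)
    b <- extract_components(wz$Z, seed = seed, grad_refine_steps = 0)
    c(refined = mean(a$n_iter), raw = mean(b$n_iter))
  })
  expect_lte(mean(iters["refined", ]), mean(iters["raw", ]))
})

test_that("deflation separates a square non-Gaussian mixture", {
  fx <- make_ica_fixture(11, n = 20000)
  wz <- pca_whiten(center_channels(fx$X)$X)
  um <- extract_components(wz$Z, seed = 11)
  expect_true(all(um$converged))
  expect_lt(max(abs(tcrossprod(um$W) - diag(3))), 1e-6)
  C <- abs(cor(t(um$sources), t(fx$S)))
  expect_true(all(apply(C, 2, max) >= 0.95))
  expect_lte(amari_index(um$W %*% wz$model$whiten %*% fx$A), 0.1)
  # identical seed, identical result
  um2 <- extract_components(wz$Z, seed = 11)
  expect_identical(um$W, um2$W)
})

test_that("a single source is recovered up to sign and scale", {
  set.seed(6)
  src <- matrix(rexp(20000) * sign(rnorm(20000)), 1)  # Laplacian-like
  wz <- pca_whiten(center_channels(src)$X)
  um <- extract_components(wz$Z, n_components = 1, seed = 6)
  expect_gte(abs(cor(um$sources[1, ], src[1, ])), 0.999)
})

test_that("channel permutation leaves best-match separation scores unchanged", {
  fx <- make_ica_fixture(13, n = 20000)
  score <- function(X) {
    wz <- pca_whiten(center_channels(X)$X)
    um <- extract_components(wz$Z, seed = 13)
    sort(apply(abs(cor(t(um$sources), t(fx$S))), 2, max))
  }
  s1 <- score(fx$X)
  s2 <- score(fx$X[c(3, 1, 2), ])
  expect_equal(s1, s2, tolerance = 1e-6)
})

test_that("component reconstruction inverts, masks and improves channels", {
  fx <- make_ica_fixture(14, n = 10000)
  cen <- center_channels(fx$X)
  wz <- pca_whiten(cen$X, mean = cen$mean)
  um <- extract_components(wz$Z, seed = 14)
  keep_all <- reconstruct_channels(um, rep(TRUE, 3), wz$model)
  expect_lt(sqrt(sum((keep_all - fx$X)^2) / sum(fx$X^2)), 1e-6)
  keep_none <- reconstruct_channels(um, rep(FALSE, 3), wz$model)
  expect_equal(keep_none, matrix(cen$mean, 3, ncol(fx$X)), tolerance = 1e-9)
  expect_error(reconstruct_channels(um, c(TRUE, FALSE), wz$model), "length")
  # dropping the ECG-matched component moves channels toward the ECG-free truth
  iecg <- which.max(abs(cor(t(um$sources), fx$ecg)))
  dropped <- reconstruct_channels(um, seq_len(3) != iecg, wz$model)
  ecg_free <- fx$X - fx$A[, 1, drop = FALSE] %*% fx$S[1, , drop = FALSE]
  for (ch in 1:3) {
    expect_gte(cor(dropped[ch, ], ecg_free[ch, ]),
               cor(fx$X[ch, ], ecg_free[ch, ]))
  }
})
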
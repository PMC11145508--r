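#' Remove the per-channel mean
#'
#' @param X Channels-by-samples numeric matrix (a vector is one channel).
#' @return List with `X` (centered matrix) and `mean` (per-channel means);
#'   `X + mean` reproduces the input exactly.
#' @export
center_channels <- function(X) {
  if (is.vector(X)) X <- matrix(X, nrow = 1L)
  if (!is.numeric(X) || length(X) == 0L || ncol(X) < 2L) {
    stop_input("X must be a numeric matrix with at least 2 samples")
  }
  mu <- rowMeans(X)
  list(X = X - mu, mean = mu)
}

#' PCA whitening
#'
#' Eigendecomposes the sample covariance \eqn{C = X X^T / m} of the centered
#' data and rescales each principal axis to unit variance, so the whitened
#' data `Z = whiten %*% X` has identity covariance. Directions whose
#' eigenvalue falls below `var_floor` times the largest are dropped
#' (dimension reduction for degenerate inputs).
#'
#' @param X Centered channels-by-samples matrix.
#' @param var_floor Relative eigenvalue cutoff (default 1e-9).
#' @param mean Optional per-channel mean recorded in the model (for later
#'   reconstruction; default zeros).
#' @return List with `Z` (whitened matrix, `kept_dims` rows) and `model`, a
#'   `whitening_model` holding `mean`, `eigvecs`, `eigvals` (descending),
#'   `whiten`, `dewhiten` and `kept_dims`.
#' @export
pca_whiten <- function(X, var_floor = 1e-9, mean = NULL) {
  if (is.vector(X)) X <- matrix(X, nrow = 1L)
  m <- ncol(X)
  C <- tcrossprod(X) / m
  eg <- eigen(C, symmetric = TRUE)
  vals <- pmax(eg$values, 0)
  if (vals[1] <= 0) stop_input("degenerate input: all eigenvalues are zero")
  keep <- which(vals >= var_floor * vals[1])
  U <- eg$vectors[, keep, drop = FALSE]
  lam <- vals[keep]
  whiten <- diag(1 / sqrt(lam), length(keep)) %*% t(U)
  dewhiten <- U %*% diag(sqrt(lam), length(keep))
  if (is.null(mean)) mean <- numeric(nrow(X))
  model <- structure(list(mean = mean, eigvecs = eg$vectors, eigvals = vals,
                          whiten = whiten, dewhiten = dewhiten,
                          kept_dims = length(keep)),
                     class = "whitening_model")
  list(Z = whiten %*% X, model = model)
}

logcosh <- function(u) abs(u) + log1p(exp(-2 * abs(u))) - log(2)

# E[log cosh(v)], v ~ N(0,1), by Gauss-Hermite quadrature (deterministic)
egv_gauss <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      gh <- pracma::gaussHermite(32)
      cache <<- sum(gh$w * logcosh(sqrt(2) * gh$x)) / sqrt(pi)
    }
    cache
  }
})

normalize <- function(w) {
  nrm <- sqrt(sum(w^2))
  if (nrm < 1e-12) stop_input("degenerate (zero-norm) update vector")
  w / nrm
}

#' One FastICA fixed-point update
#'
#' The tanh-contrast Newton step on whitened data:
#' `normalize(E[Z g(w'Z)] - E[g'(w'Z)] w)` with `g = tanh`,
#' `g' = 1 - tanh^2`, expectations taken as sample means.
#'
#' @param w Unit-norm weight vector (length = rows of `Z`).
#' @param Z Whitened channels-by-samples matrix.
#' @return Updated unit-norm weight vector.
#' @export
fastica_update <- function(w, Z) {
  u <- as.vector(crossprod(w, Z))
  gu <- tanh(u)
  normalize(as.vector(Z %*% gu) / ncol(Z) - mean(1 - gu^2) * w)
}

negentropy_surrogate <- function(w, Z) {
  abs(mean(logcosh(as.vector(crossprod(w, Z)))) - egv_gauss())
}

#' Steepest-descent refinement of an initial unmixing vector
#'
#' Performs up to `steps` accepted updates
#' `w <- normalize(w + step * E[Z g(w'Z)])`, with the step size chosen by a
#' backtracking line search (start 1, halve, at most 10 halvings) so the
#' negentropy surrogate `|E[G(w'Z)] - E[G(v)]|` never decreases. Used to
#' polish random starting vectors before the fixed-point iterations, which
#' reduces sensitivity to the initial value.
#'
#' @param w Unit-norm start vector.
#' @param Z Whitened data matrix.
#' @param steps Maximum refinement steps (default 5; 0 is a no-op).
#' @return Refined unit-norm vector, with attribute `surrogate_path` giving
#'   the surrogate value at the start and after each accepted step.
#' @export
gradient_refine <- function(w, Z, steps = 5L) {
  path <- negentropy_surrogate(w, Z)
  for (s in seq_len(steps)) {
    u <- as.vector(crossprod(w, Z))
    grad <- as.vector(Z %*% tanh(u)) / ncol(Z)
    step <- 1
    accepted <- FALSE
    for (h in 1:10) {
      cand <- normalize(w + step * grad)
      j <- negentropy_surrogate(cand, Z)
      if (j >= path[length(path)]) {
        w <- cand
        path <- c(path, j)
        accepted <- TRUE
        break
      }
      step <- step / 2
    }
    if (!accepted) break
  }
  attr(w, "surrogate_path") <- path
  w
}

#' Deflationary FastICA component extraction
#'
#' Extracts `n_components` independent components sequentially from whitened
#' data. Each component starts from a seeded random unit vector, is refined
#' by [gradient_refine()], then iterated with [fastica_update()] under
#' Gram-Schmidt re-orthogonalisation against the rows already found, until
#' successive vectors align to within `tol` or `max_iter` is reached
#' (non-convergence is flagged, not fatal).
#'
#' @param Z Whitened channels-by-samples matrix.
#' @param n_components Number of components (default: all rows of `Z`).
#' @param tol Convergence tolerance on `1 - |<w_new, w_old>|`
#'   (default 1e-6).
#' @param max_iter Maximum fixed-point iterations per component
#'   (default 200).
#' @param grad_refine_steps Refinement steps before the fixed-point loop
#'   (default 5; 0 disables).
#' @param mode `"refine_fixed_point"` (default) or `"gradient_only"`, which
#'   skips the Newton step and iterates the steepest-descent update to
#'   convergence.
#' @param seed Optional RNG seed for the random starts.
#' @param whitening Optional `whitening_model`; when given, the estimated
#'   mixing matrix is expressed in original channel space.
#' @return An `unmixing_model`: `W` (rows unit-norm, pairwise orthogonal),
#'   `sources` (`W %*% Z`), `mixing_est`, `n_iter`, `converged`.
#' @export
extract_components <- function(Z, n_components = nrow(Z), tol = 1e-6,
                               max_iter = 200L, grad_refine_steps = 5L,
                               mode = c("refine_fixed_point", "gradient_only"),
                               seed = NULL, whitening = NULL) {
  mode <- match.arg(mode)
  if (is.vector(Z)) Z <- matrix(Z, nrow = 1L)
  k <- nrow(Z)
  if (n_components > k) stop_input("n_components exceeds whitened dimensionality")
  W <- matrix(0, n_components, k)
  n_iter <- integer(n_components)
  converged <- logical(n_components)
  with_seed(seed, {
    for (comp in seq_len(n_components)) {
      for (attempt in 1:5) {
        w <- tryCatch({
          w0 <- stats::rnorm(k)
          if (comp > 1L) {
            w0 <- w0 - t(W[seq_len(comp - 1L), , drop = FALSE]) %*%
              (W[seq_len(comp - 1L), , drop = FALSE] %*% w0)
          }
          w0 <- normalize(w0)
          if (mode == "refine_fixed_point" && grad_refine_steps > 0L) {
            w0 <- as.vector(gradient_refine(w0, Z, grad_refine_steps))
            if (comp > 1L) {
              w0 <- w0 - t(W[seq_len(comp - 1L), , drop = FALSE]) %*%
                (W[seq_len(comp - 1L), , drop = FALSE] %*% w0)
            }
            w0 <- normalize(w0)
          }
          it <- 0L
          ok <- FALSE
          repeat {
            it <- it + 1L
            wn <- if (mode == "gradient_only") {
              u <- as.vector(crossprod(w0, Z))
              normalize(w0 + as.vector(Z %*% tanh(u)) / ncol(Z))
            } else {
              fastica_update(w0, Z)
            }
            if (comp > 1L) {
              wn <- wn - t(W[seq_len(comp - 1L), , drop = FALSE]) %*%
                (W[seq_len(comp - 1L), , drop = FALSE] %*% wn)
              wn <- normalize(wn)
            }
            aligned <- abs(sum(wn * w0))
            w0 <- as.vector(wn)
            if (aligned >= 1 - tol) { ok <- TRUE; break }
            if (it >= max_iter) break
          }
          n_iter[comp] <- it
          converged[comp] <- ok
          w0
        }, error = function(e) NULL)
        if (!is.null(w)) break
      }
      if (is.null(w)) {
        stop_input("component ", comp, ": repeated numerical degeneracy")
      }
      W[comp, ] <- w
    }
  })
  mixing_est <- if (is.null(whitening)) t(W) else whitening$dewhiten %*% t(W)
  structure(list(W = W, sources = W %*% Z, mixing_est = mixing_est,
                 n_iter = n_iter, converged = converged),
            class = "unmixing_model")
}

#' Map selected components back to channel space
#'
#' Zeroes the dropped components and inverts the unmixing and whitening
#' transforms: `X_hat = dewhiten %*% t(W) %*% diag(keep) %*% sources + mean`.
#' With every component kept this reproduces the pre-whitening input (up to
#' any variance discarded by dimension reduction).
#'
#' @param model An `unmixing_model`.
#' @param keep Logical vector, one entry per component (`TRUE` = keep).
#' @param whitening The `whitening_model` used to produce `Z`.
#' @return Channels-by-samples matrix in the original space.
#' @export
reconstruct_channels <- function(model, keep, whitening) {
  stopifnot(inherits(model, "unmixing_model"),
            inherits(whitening, "whitening_model"))
  if (length(keep) != nrow(model$W)) {
    stop_input("keep mask length must equal the number of components")
  }
  S <- model$sources * as.numeric(keep)
  whitening$dewhiten %*% crossprod(model$W, S) + whitening$mean
}
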
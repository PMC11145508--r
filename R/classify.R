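#' Identify ECG components from sorted fuzzy entropies
#'
#' Sorts the per-component entropies ascending and scans for the smallest
#' boundary index `k` (2..n-1) at which the consecutive gap shrinks,
#' `phi[k+1] - phi[k] < phi[k] - phi[k-1]`, i.e. the first component that
#' sits just past a dominant entropy jump. In the default `"exclusive"`
#' boundary mode the `k - 1` components below the jump are flagged as ECG;
#' `"literal"` mode also flags the boundary component itself. If no index
#' satisfies the strict inequality, nothing is flagged. The result depends
#' only on the sorted values, never on the input ordering.
#'
#' @param entropies Numeric vector of per-component fuzzy entropies
#'   (>= 3 values; with fewer, classification is skipped with a warning and
#'   nothing is flagged).
#' @param boundary_mode `"exclusive"` (default) or `"literal"`.
#' @return A `component_classification`: `entropies`, `order` (ascending
#'   permutation), `k` (boundary index or `NA`), `ecg_flags` (logical, in
#'   the original component order), `boundary_mode`.
#' @export
classify_components <- function(entropies,
                                boundary_mode = c("exclusive", "literal")) {
  boundary_mode <- match.arg(boundary_mode)
  n <- length(entropies)
  ord <- order(entropies)
  flags <- logical(n)
  k <- NA_integer_
  if (n < 3L) {
    warning("need at least 3 components for the entropy-gap rule; ",
            "no components flagged", call. = FALSE)
  } else {
    se <- entropies[ord]
    for (kk in 2:(n - 1L)) {
      if (se[kk + 1L] - se[kk] < se[kk] - se[kk - 1L]) {
        k <- kk
        break
      }
    }
    if (!is.na(k)) {
      n_flag <- if (boundary_mode == "exclusive") k - 1L else k
      if (n_flag > 0L) flags[ord[seq_len(n_flag)]] <- TRUE
    }
  }
  structure(list(entropies = entropies, order = ord, k = k,
                 ecg_flags = flags, boundary_mode = boundary_mode),
            class = "component_classification")
}

#' @export
print.component_classification <- function(x, ...) {
  cat("<component_classification>\n")
  cat("  entropies:", paste(signif(x$entropies, 4), collapse = ", "), "\n")
  cat("  boundary k:", ifelse(is.na(x$k), "none", x$k),
      sprintf("(%s mode)\n", x$boundary_mode))
  cat("  ECG components:",
      if (any(x$ecg_flags)) paste(which(x$ecg_flags), collapse = ", ")
      else "none", "\n")
  invisible(x)
}
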
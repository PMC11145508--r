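# Daubechies scaling (reconstruction low-pass) filters db1..db10, standard
# published coefficients; each sums to sqrt(2).
.db_scaling <- list(
  db1 = c(0.7071067811865476, 0.7071067811865476),
  db2 = c(0.48296291314453416, 0.8365163037378079, 0.2241438680420134,
          -0.12940952255126037),
  db3 = c(0.33267055295008263, 0.8068915093110925, 0.45987750211849154,
          -0.13501102001025458, -0.08544127388202666, 0.03522629188570953),
  db4 = c(0.2303778133088965, 0.7148465705529157, 0.6308807679298589,
          -0.027983769416859854, -0.18703481171909309, 0.030841381835560764,
          0.0328830116668852, -0.010597401785069032),
  db5 = c(0.16010239797419293, 0.6038292697971896, 0.7243085284377729,
          0.13842814590132074, -0.24229488706638203, -0.032244869584638375,
          0.07757149384004572, -0.006241490212798274, -0.012580751999081999,
          0.0033357252854737712),
  db6 = c(0.11154074335010947, 0.49462389039845306, 0.7511339080210954,
          0.31525035170919763, -0.22626469396543983, -0.12976686756726194,
          0.09750160558732304, 0.027522865530305727, -0.03158203931748603,
          0.0005538422011614961, 0.004777257510945511, -0.0010773010853084796),
  db7 = c(0.07785205408500918, 0.3965393194819173, 0.7291320908462351,
          0.4697822874051931, -0.14390600392856498, -0.22403618499387498,
          0.07130921926683026, 0.08061260915108308, -0.03802993693501441,
          -0.01657454163066688, 0.01255099855609984, 0.0004295779729213665,
          -0.0018016407040474908, 0.00035371379997452024),
  db8 = c(0.05441584224310401, 0.31287159091429995, 0.6756307362972898,
          0.5853546836542067, -0.015829105256349306, -0.2840155429615469,
          0.0004724845739132828, 0.12874742662047847, -0.017369301001807547,
          -0.044088253930794755, 0.013981027917398282, 0.008746094047405777,
          -0.004870352993451574, -0.00039174037337694705, 0.0006754494064505693,
          -0.00011747678412476953),
  db9 = c(0.038077947363878345, 0.24383467461259034, 0.6048231236901112,
          0.6572880780513005, 0.13319738582500756, -0.2932737832791749,
          -0.09684078322297646, 0.14854074933810638, 0.03072568147933338,
          -0.06763282906132997, 0.00025094711483145197, 0.022361662123679096,
          -0.004723204757751397, -0.00428150368246343, 0.0018476468830562265,
          0.00023038576352319597, -0.0002519631889427101, 3.93473203162716e-05),
  db10 = c(0.026670057900555554, 0.1881768000776915, 0.5272011889317256,
           0.6884590394536035, 0.2811723436605775, -0.24984642432731538,
           -0.19594627437737705, 0.12736934033579325, 0.09305736460357235,
           -0.07139414716639708, -0.029457536821875813, 0.033212674059341,
           0.0036065535669561697, -0.010733175483330575, 0.001395351747052901,
           0.001992405295185056, -0.0006858566949597116, -0.00011646685512928545,
           9.358867032006959e-05, -1.3264202894521244e-05)
)

#' Quadrature-mirror filter bank for a Daubechies wavelet
#'
#' Returns the four finite impulse response filters of the two-channel
#' analysis/synthesis bank: decomposition low/high pass (used with
#' downsampling to produce approximation and detail coefficients) and
#' reconstruction low/high pass.
#'
#' @param wavelet Wavelet name, one of `"db1"` to `"db10"`.
#' @return A list with elements `dec_lo`, `dec_hi`, `rec_lo`, `rec_hi`
#'   (numeric filter taps) and `length` (filter length).
#' @export
wavelet_filters <- function(wavelet = "db4") {
  h <- .db_scaling[[wavelet]]
  if (is.null(h)) {
    stop_input("unsupported wavelet '", wavelet, "' (supported: ",
               paste(names(.db_scaling), collapse = ", "), ")")
  }
  L <- length(h)
  rec_hi <- (-1)^(seq_len(L) - 1) * rev(h)
  list(dec_lo = rev(h), dec_hi = rev(rec_hi),
       rec_lo = h, rec_hi = rec_hi, length = L)
}

#' Maximum feasible decomposition level
#'
#' @param n Signal length in samples.
#' @param wavelet Wavelet name.
#' @return Largest level for which the coarsest approximation still holds
#'   more samples than the filter support.
#' @export
dwt_max_level <- function(n, wavelet = "db4") {
  L <- wavelet_filters(wavelet)$length
  if (n < L) return(0L)
  as.integer(floor(log2(n / (L - 1))))
}

# linear convolution (full), FFT-based
conv_full <- function(x, f) {
  stats::convolve(x, rev(f), type = "open")
}

# symmetric (half-point) extension by e samples on each side
sym_extend <- function(x, e) {
  n <- length(x)
  left <- rev(x[seq_len(min(e, n))])
  right <- rev(x[seq.int(n - min(e, n) + 1L, n)])
  while (length(left) < e) left <- c(rev(left), left)[seq_len(e)]
  c(left, x, right)
}

# one analysis step: returns approximation and detail coefficient vectors of
# length floor((n + L - 1) / 2)
dwt_step <- function(x, filt) {
  L <- filt$length
  n <- length(x)
  ext <- sym_extend(x, L - 1L)
  outlen <- (n + L - 1L) %/% 2L
  idx <- seq.int(L + 1L, by = 2L, length.out = outlen)
  list(approx = conv_full(ext, filt$dec_lo)[idx],
       detail = conv_full(ext, filt$dec_hi)[idx])
}

# one synthesis step, truncated to target_len
idwt_step <- function(approx, detail, filt, target_len) {
  L <- filt$length
  la <- length(approx)
  up_a <- numeric(2L * la - 1L)
  up_d <- numeric(2L * la - 1L)
  up_a[seq.int(1L, by = 2L, length.out = la)] <- approx
  up_d[seq.int(1L, by = 2L, length.out = la)] <- detail
  full <- conv_full(up_a, filt$rec_lo) + conv_full(up_d, filt$rec_hi)
  if (L > 2L) full <- full[seq.int(L - 1L, length(full) - (L - 2L))]
  full[seq_len(target_len)]
}

#' Multi-level discrete wavelet decomposition
#'
#' Cascaded two-channel filter bank with downsampling: at each level the
#' current approximation is split by the low-pass filter into the next
#' approximation and by the high-pass filter into a detail vector. Signals of
#' arbitrary length are handled by half-point symmetric boundary extension.
#'
#' @param x Numeric sample vector.
#' @param wavelet Wavelet name (`"db1"`..`"db10"`; default `"db4"`).
#' @param levels Number of decomposition levels (default 9).
#' @return An object of class `wavelet_decomposition`: `approx` (coarsest
#'   approximation), `details` (list of detail vectors, finest first, i.e.
#'   `details[[1]]` is level 1), `wavelet`, `levels`, `original_length`, and
#'   `level_lengths` (input length at each level, used for exact
#'   reconstruction truncation).
#' @seealso [dwt_reconstruct()]
#' @export
dwt_decompose <- function(x, wavelet = "db4", levels = 9L) {
  x <- as.numeric(x)
  levels <- as.integer(levels)
  if (levels < 1L) stop_input("levels must be >= 1")
  maxlev <- dwt_max_level(length(x), wavelet)
  if (levels > maxlev) {
    stop_input("signal of length ", length(x), " supports at most ", maxlev,
               " decomposition levels with wavelet ", wavelet,
               " (requested ", levels, ")")
  }
  filt <- wavelet_filters(wavelet)
  details <- vector("list", levels)
  level_lengths <- integer(levels)
  a <- x
  for (j in seq_len(levels)) {
    level_lengths[j] <- length(a)
    st <- dwt_step(a, filt)
    details[[j]] <- st$detail
    a <- st$approx
  }
  structure(list(approx = a, details = details, wavelet = wavelet,
                 levels = levels, original_length = length(x),
                 level_lengths = level_lengths),
            class = "wavelet_decomposition")
}

#' Inverse multi-level discrete wavelet transform
#'
#' Reconstructs the signal from a [dwt_decompose()] object by running the
#' synthesis bank from the coarsest level upward, truncating at every level
#' to the recorded analysis length so the round trip is exact to numerical
#' precision.
#'
#' @param dec A `wavelet_decomposition` object.
#' @return Numeric vector of length `dec$original_length`.
#' @export
dwt_reconstruct <- function(dec) {
  stopifnot(inherits(dec, "wavelet_decomposition"))
  filt <- wavelet_filters(dec$wavelet)
  a <- dec$approx
  for (j in rev(seq_len(dec$levels))) {
    a <- idwt_step(a, dec$details[[j]], filt, dec$level_lengths[j])
  }
  a
}
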
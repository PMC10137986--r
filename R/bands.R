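# Five-band decomposition of the hemodynamic signal with a multilevel
# orthogonal DWT. The dyadic filter bank is implemented directly (db5
# analysis/synthesis filters, symmetric or periodized boundary handling);
# level j details occupy approximately [fs/2^(j+1), fs/2^j].

# db5 quadrature-mirror filter bank (Daubechies, 5 vanishing moments),
# standard coefficients to 17 significant digits.
DB5_DEC_LO <- c(
  0.0033357252854737712, -0.012580751999081999, -0.006241490212798274,
  0.07757149384004572, -0.032244869584638375, -0.24229488706638203,
  0.13842814590132074, 0.7243085284377729, 0.6038292697971896,
  0.16010239797419293)
DB5_DEC_HI <- c(
  -0.16010239797419293, 0.6038292697971896, -0.7243085284377729,
  0.13842814590132074, 0.24229488706638203, -0.032244869584638375,
  -0.07757149384004572, -0.006241490212798274, 0.012580751999081999,
  0.0033357252854737712)
DB5_REC_LO <- rev(DB5_DEC_LO)
DB5_REC_HI <- rev(DB5_DEC_HI)

wavelet_filters <- function(name) {
  if (!identical(name, "db5"))
    stop(sprintf("unknown wavelet '%s' (db5 is the supported basis)", name))
  list(dec_lo = DB5_DEC_LO, dec_hi = DB5_DEC_HI,
       rec_lo = DB5_REC_LO, rec_hi = DB5_REC_HI, len = 10L)
}

#' Wavelet decomposition settings
#'
#' @param wavelet orthogonal wavelet name; `"db5"` (Daubechies, 5 vanishing
#'   moments) is the basis used throughout.
#' @param levels decomposition depth J (default 9; at 10 Hz this reaches the
#'   endothelial band around 0.01 Hz).
#' @param padding boundary handling: `"symmetric"` (default, least edge
#'   distortion on finite epochs) or `"periodization"` (orthogonal circular
#'   transform; conserves energy exactly on lengths divisible by `2^levels`).
#' @return list of class `wavelet_spec`.
#' @export
wavelet_spec <- function(wavelet = "db5", levels = 9,
                         padding = c("symmetric", "periodization")) {
  padding <- match.arg(padding)
  wavelet_filters(wavelet)  # validates the name
  if (!is.numeric(levels) || length(levels) != 1L || levels < 1 ||
      levels != round(levels))
    stop("levels must be a positive integer")
  structure(list(wavelet = wavelet, levels = as.integer(levels),
                 padding = padding),
            class = "wavelet_spec")
}

# Half-point symmetric boundary index: positions outside 1..n reflect with
# edge repetition ( ... x2 x1 | x1 x2 ... xn | xn x(n-1) ... ).
sym_index <- function(i, n) {
  i <- (i - 1) %% (2 * n)
  ifelse(i < n, i + 1, 2 * n - i)
}

# One analysis step. Returns approximation and detail coefficient vectors.
# Symmetric mode yields floor((n + 9) / 2) coefficients (redundant boundary
# coefficients keep the step exactly invertible); periodization yields
# ceiling(n / 2) (odd inputs are even-extended by repeating the last sample).
dwt_step <- function(x, filt, mode) {
  F <- filt$len
  if (mode == "periodization") {
    n0 <- length(x)
    if (n0 %% 2 == 1) x <- c(x, x[n0])
    n <- length(x)
    half <- n %/% 2L
    pos <- 2 * seq_len(half)
    cA <- numeric(half); cD <- numeric(half)
    for (k in seq_len(F)) {
      idx <- ((pos + 5 - k - 1) %% n) + 1
      xk <- x[idx]
      cA <- cA + filt$dec_lo[k] * xk
      cD <- cD + filt$dec_hi[k] * xk
    }
  } else {
    n <- length(x)
    m <- (n + F - 1) %/% 2L
    pos <- 2 * seq_len(m)
    cA <- numeric(m); cD <- numeric(m)
    for (k in seq_len(F)) {
      xk <- x[sym_index(pos + 1 - k, n)]
      cA <- cA + filt$dec_lo[k] * xk
      cD <- cD + filt$dec_hi[k] * xk
    }
  }
  list(cA = cA, cD = cD)
}

# One synthesis step; `out_len` is the length of the signal that produced
# (cA, cD), to which the reconstruction is trimmed.
idwt_step <- function(cA, cD, filt, mode, out_len) {
  F <- filt$len
  la <- length(cA)
  n <- 2L * la
  nzA <- any(cA != 0)
  nzD <- any(cD != 0)  # zero branches are skipped (band reconstruction zeroes most)
  if (mode == "periodization") {
    y <- numeric(n)
    if (nzA) { up_a <- numeric(n); up_a[seq(1, n, 2)] <- cA }
    if (nzD) { up_d <- numeric(n); up_d[seq(1, n, 2)] <- cD }
    t <- seq_len(n)
    for (k in seq_len(F)) {
      idx <- ((t - k + 5 - 1) %% n) + 1
      if (nzA) y <- y + filt$rec_lo[k] * up_a[idx]
      if (nzD) y <- y + filt$rec_hi[k] * up_d[idx]
    }
  } else {
    # out[m] = sum_k rec[k] * up[m + 9 - k], up implicitly zero-padded;
    # equivalent to the full upsample-convolve with F-2 boundary samples dropped
    out_n <- n - F + 2L
    pad <- F - 1L
    y <- numeric(out_n)
    m <- seq_len(out_n)
    if (nzA) { up_a <- numeric(n + pad); up_a[pad + seq(1, n, 2)] <- cA }
    if (nzD) { up_d <- numeric(n + pad); up_d[pad + seq(1, n, 2)] <- cD }
    for (k in seq_len(F)) {
      idx <- m + 9L - k + pad
      if (nzA) y <- y + filt$rec_lo[k] * up_a[idx]
      if (nzD) y <- y + filt$rec_hi[k] * up_d[idx]
    }
  }
  y[seq_len(out_len)]
}

#' Multilevel discrete wavelet transform
#'
#' Decomposes a real sequence into `spec$levels` detail coefficient vectors
#' `d1..dJ` plus the level-J approximation. The transform is exactly
#' invertible by [dwt_reconstruct()].
#'
#' @param x numeric sequence of length at least `2^spec$levels`.
#' @param spec a [wavelet_spec()].
#' @return list of class `dwt_coeffs` with elements `approx`, `details`
#'   (list `d1..dJ`), `input_lens` (per-level signal lengths used for exact
#'   trimming on reconstruction), `n`, and `spec`.
#' @export
#' @examples
#' x <- sin(2 * pi * 1.0 * (0:999) / 10)
#' co <- dwt_decompose(x, wavelet_spec(levels = 5))
#' max(abs(dwt_reconstruct(co) - x)) < 1e-8
dwt_decompose <- function(x, spec = wavelet_spec()) {
  if (!inherits(spec, "wavelet_spec")) stop("spec must be a wavelet_spec")
  x <- as.numeric(x)
  if (any(!is.finite(x))) stop("input contains non-finite values")
  if (length(x) < 2^spec$levels)
    stop(sprintf("input too short: %d samples < 2^%d", length(x), spec$levels))
  filt <- wavelet_filters(spec$wavelet)
  details <- vector("list", spec$levels)
  input_lens <- integer(spec$levels)
  a <- x
  for (j in seq_len(spec$levels)) {
    input_lens[j] <- length(a)
    st <- dwt_step(a, filt, spec$padding)
    details[[j]] <- st$cD
    a <- st$cA
  }
  names(details) <- paste0("d", seq_len(spec$levels))
  structure(list(approx = a, details = details, input_lens = input_lens,
                 n = length(x), spec = spec),
            class = "dwt_coeffs")
}

#' @rdname dwt_decompose
#' @param coeffs a `dwt_coeffs` object (possibly with modified coefficients).
#' @return `dwt_reconstruct` returns the length-`n` inverse transform.
#' @export
dwt_reconstruct <- function(coeffs) {
  if (!inherits(coeffs, "dwt_coeffs")) stop("coeffs must be dwt_coeffs")
  spec <- coeffs$spec
  filt <- wavelet_filters(spec$wavelet)
  a <- coeffs$approx
  for (j in rev(seq_len(spec$levels))) {
    a <- idwt_step(a, coeffs$details[[j]], filt, spec$padding,
                   coeffs$input_lens[j])
  }
  a
}

#' Dyadic frequency edges of a detail level
#'
#' Level-j detail coefficients of an orthogonal dyadic DWT occupy the ideal
#' sub-band `[fs / 2^(j+1), fs / 2^j]`.
#'
#' @param fs sampling rate in Hz.
#' @param j detail level (>= 1).
#' @return numeric `c(f_low, f_high)` in Hz.
#' @export
#' @examples
#' detail_band_edges(10, 3)  # 0.625 1.25
detail_band_edges <- function(fs, j) {
  stopifnot_scalar_num(fs, "fs", positive = TRUE)
  if (!is.numeric(j) || length(j) != 1L || j < 1 || j != round(j))
    stop("detail level j must be a positive integer")
  c(fs / 2^(j + 1), fs / 2^j)
}

#' The five physiological frequency bands
#'
#' Default band table for prefrontal hemodynamic signals: cardiac (I),
#' respiratory (II), myogenic (III), neurogenic (IV), and endothelial
#' metabolic (V) activity.
#'
#' @return data frame with columns `name`, `f_low_hz`, `f_high_hz`,
#'   `physiology`.
#' @export
band_table <- function() {
  data.frame(
    name = c("I", "II", "III", "IV", "V"),
    f_low_hz = c(0.6, 0.145, 0.052, 0.021, 0.0095),
    f_high_hz = c(2.0, 0.6, 0.145, 0.052, 0.021),
    physiology = c("heart rate activity", "respiratory activity",
                   "myogenic activity", "neurogenic activity",
                   "endothelial cell metabolic activity"),
    stringsAsFactors = FALSE)
}

#' Map analysis bands to DWT detail levels
#'
#' Each band is assigned the detail level whose own dyadic sub-band
#' `[fs/2^(j+1), fs/2^j]` has the largest fraction of its width contained in
#' the band (ties favor the finer, smaller-j level). The assignment fails if
#' any band's best containment is below 0.5, or if two bands collide. At
#' fs = 10 Hz with the default [band_table()] and 9 levels the mapping is
#' I:3, II:5, III:6, IV:8, V:9.
#'
#' @param fs sampling rate in Hz; must exceed twice the highest band edge
#'   (Nyquist).
#' @param bands band table as from [band_table()].
#' @param levels decomposition depth to map into.
#' @return named integer vector, one detail level per band.
#' @export
#' @examples
#' assign_levels_to_bands(10, band_table(), 9)
assign_levels_to_bands <- function(fs, bands = band_table(), levels = 9) {
  stopifnot_scalar_num(fs, "fs", positive = TRUE)
  if (any(bands$f_low_hz >= bands$f_high_hz))
    stop("band edges must satisfy f_low < f_high")
  if (fs <= 2 * max(bands$f_high_hz))
    stop(sprintf(
      "sampling rate %g Hz violates the Nyquist requirement fs > 2 x %g Hz",
      fs, max(bands$f_high_hz)))
  mapping <- integer(nrow(bands))
  for (b in seq_len(nrow(bands))) {
    frac <- vapply(seq_len(levels), function(j) {
      e <- detail_band_edges(fs, j)
      overlap <- max(0, min(e[2], bands$f_high_hz[b]) -
                        max(e[1], bands$f_low_hz[b]))
      overlap / (e[2] - e[1])
    }, numeric(1))
    best <- which.max(frac)  # ties resolve to the finer (smaller j) level
    if (frac[best] < 0.5)
      stop(sprintf(
        "band %s (%g-%g Hz) has no detail level with >= 50%% containment at %d levels",
        bands$name[b], bands$f_low_hz[b], bands$f_high_hz[b], levels))
    mapping[b] <- best
  }
  if (anyDuplicated(mapping))
    stop("band-to-level mapping is not injective; increase levels or revise bands")
  names(mapping) <- bands$name
  mapping
}

#' Reconstruct a single detail level as a band-limited time series
#'
#' Inverse DWT with every other detail level and the approximation zeroed;
#' the result is the band-limited component of the input at the original
#' length and sampling rate.
#'
#' @param coeffs a `dwt_coeffs` object from [dwt_decompose()].
#' @param level detail level to retain.
#' @param spec ignored if `coeffs` carries its spec (kept for call-site
#'   clarity).
#' @return numeric sequence of length `coeffs$n`.
#' @export
reconstruct_band <- function(coeffs, level, spec = coeffs$spec) {
  if (!inherits(coeffs, "dwt_coeffs")) stop("coeffs must be dwt_coeffs")
  J <- coeffs$spec$levels
  if (!is.numeric(level) || length(level) != 1L || level < 1 || level > J ||
      level != round(level))
    stop(sprintf("level must be in 1..%d", J))
  kept <- coeffs
  kept$approx <- numeric(length(coeffs$approx))
  for (j in seq_len(J)) {
    if (j != level)
      kept$details[[j]] <- numeric(length(coeffs$details[[j]]))
  }
  dwt_reconstruct(kept)
}

#' Decompose a series into the five physiological bands
#'
#' Convenience wrapper: multilevel DWT, band-to-level assignment, and one
#' band-limited reconstruction per band.
#'
#' @param x numeric sequence (a single channel's concentration-change series).
#' @param fs sampling rate in Hz.
#' @param spec a [wavelet_spec()].
#' @param bands band table as from [band_table()].
#' @return list of class `band_decomposition`: `mapping`, `band_series`
#'   (named list, one series per band at full length), `sampling_rate_hz`.
#' @export
decompose_bands <- function(x, fs, spec = wavelet_spec(),
                            bands = band_table()) {
  mapping <- assign_levels_to_bands(fs, bands, spec$levels)
  coeffs <- dwt_decompose(x, spec)
  series <- lapply(mapping, function(j) reconstruct_band(coeffs, j))
  structure(list(mapping = mapping, band_series = series,
                 sampling_rate_hz = fs),
            class = "band_decomposition")
}
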
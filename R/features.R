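#' Two-sided power spectrum of a discrete sequence
#'
#' The periodogram `S_x(k) = |X(k)|^2 / N`, `k = 0..N-1`, where `X` is the
#' unnormalized DFT. With this normalization the energy identity
#' `sum_k S_x(k) = sum_n x_n^2` (Parseval) holds exactly.
#'
#' @param x numeric sequence, length >= 2.
#' @return list of class `power_spectrum` with `s` (nonnegative reals, length
#'   N) and `n`.
#' @export
#' @examples
#' power_spectrum(c(1, 1, 1, 1))$s  # 4 0 0 0
power_spectrum <- function(x) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 2) stop("power spectrum needs at least 2 samples")
  if (any(!is.finite(x))) stop("non-finite values in input")
  s <- Mod(stats::fft(x))^2 / n
  structure(list(s = s, n = n), class = "power_spectrum")
}

#' Power-spectral entropy
#'
#' Treats the normalized power spectrum `p_k = S_x(k) / sum(S_x)` as a
#' probability distribution and returns its Shannon entropy
#' `F_SE = -sum p_k log2 p_k` (bits, with `0 log 0 = 0`) together with the
#' normalized entropy `F_PSE = F_SE / log2 N`, which lies in `[0, 1]`:
#' 1 for an exactly uniform spectrum, 0 when a single bin carries all power.
#'
#' @param spec a [power_spectrum()].
#' @return list with `f_se` (bits) and `f_pse` (dimensionless, in `[0, 1]`).
#' @export
#' @examples
#' pse(power_spectrum(c(1, -1, 1, -1)))$f_pse  # 0: single-bin spectrum
pse <- function(spec) {
  if (!inherits(spec, "power_spectrum")) stop("spec must be a power_spectrum")
  total <- sum(spec$s)
  if (total <= 0) stop("undefined entropy: all-zero power spectrum")
  p <- spec$s / total
  nz <- p > 0
  f_se <- -sum(p[nz] * log2(p[nz]))
  f_pse <- f_se / log2(spec$n)
  list(f_se = max(0, f_se), f_pse = min(1, max(0, f_pse)))
}

#' Per-band normalized spectral entropy of one epoch
#'
#' Decomposes the selected channel's HbO series into the five physiological
#' bands and returns the normalized power-spectral entropy of each
#' band-limited series, in band order I to V. An optional Hann window can be
#' applied before the DFT (off by default; the plain periodogram is the
#' reference definition).
#'
#' @param epoch a [hemo_recording()] holding one epoch.
#' @param channel channel index to analyze.
#' @param spec a [wavelet_spec()].
#' @param bands band table as from [band_table()].
#' @param window `"none"` (default) or `"hann"`.
#' @return list of class `pse_features`: `values` (named numeric, I..V),
#'   `f_se` (raw entropies in bits), `channel`, `subject_id`.
#' @export
extract_features <- function(epoch, channel, spec = wavelet_spec(),
                             bands = band_table(),
                             window = c("none", "hann")) {
  window <- match.arg(window)
  if (!inherits(epoch, "hemo_recording")) stop("epoch must be a hemo_recording")
  if (channel < 1 || channel > nrow(epoch$delta_hbo))
    stop("channel index out of range")
  x <- epoch$delta_hbo[channel, ]
  dec <- decompose_bands(x, epoch$sampling_rate_hz, spec, bands)
  vals <- numeric(length(dec$band_series))
  raw <- numeric(length(dec$band_series))
  for (b in seq_along(dec$band_series)) {
    y <- dec$band_series[[b]]
    if (window == "hann") {
      n <- length(y)
      y <- y * 0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / (n - 1)))
    }
    ent <- pse(power_spectrum(y))
    vals[b] <- ent$f_pse
    raw[b] <- ent$f_se
  }
  names(vals) <- names(dec$band_series)
  names(raw) <- names(dec$band_series)
  structure(list(values = vals, f_se = raw, channel = as.integer(channel),
                 subject_id = epoch$subject_id),
            class = "pse_features")
}
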
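#' Extinction coefficients and optical geometry for the modified Beer-Lambert law
#'
#' Bundles the 2x2 molar extinction matrix (rows = wavelengths, columns =
#' HbO, HbR; units cm^-1 mM^-1), the source-detector pathlength, and the
#' differential pathlength factor (DPF) per wavelength. The defaults are
#' representative literature values for 730/850 nm and adult forehead
#' geometry; any published tabulation may be substituted.
#'
#' @param epsilon 2x2 numeric matrix `eps[wavelength, species]`, species
#'   ordered (HbO, HbR), all entries > 0, nonsingular.
#' @param pathlength_cm source-detector separation in cm.
#' @param dpf differential pathlength factor, length 1 (shared) or 2 (per
#'   wavelength).
#' @return list of class `extinction_matrix`.
#' @export
extinction_matrix <- function(epsilon = matrix(c(0.390, 1.058,
                                                 1.102, 0.691),
                                               nrow = 2,
                                               dimnames = list(c("w1", "w2"),
                                                               c("HbO", "HbR"))),
                              pathlength_cm = 3, dpf = c(6, 6)) {
  epsilon <- as.matrix(epsilon)
  if (!all(dim(epsilon) == c(2L, 2L)) || any(epsilon <= 0))
    stop("epsilon must be a 2x2 matrix of positive extinction coefficients")
  if (abs(det(epsilon)) < 1e-12 * max(abs(epsilon))^2)
    stop("singular extinction matrix: wavelength rows are proportional")
  stopifnot_scalar_num(pathlength_cm, "pathlength_cm", positive = TRUE)
  if (!length(dpf) %in% c(1L, 2L) || any(dpf <= 0))
    stop("dpf must be one or two positive reals")
  if (length(dpf) == 1L) dpf <- rep(dpf, 2)
  structure(list(epsilon = epsilon, pathlength_cm = pathlength_cm,
                 dpf = as.numeric(dpf)),
            class = "extinction_matrix")
}

#' Preprocessing settings
#'
#' @param trim_initial_s settling time discarded from the start of each
#'   session, in seconds (default 300: the first five minutes).
#' @param mean_window,median_window odd filter window lengths in samples
#'   (default 5, i.e. 0.5 s at 10 Hz: suppresses sample noise without eroding
#'   the cardiac band).
#' @param mas_wavelet,mas_levels wavelet basis and decomposition depth for
#'   motion-artifact suppression.
#' @param mas_threshold_k robust threshold multiplier: per-level threshold is
#'   `k * 1.4826 * median(|d - median(d)|)`.
#' @param epoch_s epoch length in seconds aligned to the rating interval
#'   (default 300).
#' @return list of class `preprocess_config`.
#' @export
preprocess_config <- function(trim_initial_s = 300, mean_window = 5,
                              median_window = 5, mas_wavelet = "db5",
                              mas_levels = 5, mas_threshold_k = 3,
                              epoch_s = 300) {
  stopifnot_scalar_num(trim_initial_s, "trim_initial_s", nonneg = TRUE)
  if (!is_odd_window(mean_window) || !is_odd_window(median_window))
    stop("filter windows must be odd positive integers")
  stopifnot_scalar_num(mas_threshold_k, "mas_threshold_k", positive = TRUE)
  stopifnot_scalar_num(epoch_s, "epoch_s", positive = TRUE)
  structure(list(trim_initial_s = trim_initial_s,
                 mean_window = as.integer(mean_window),
                 median_window = as.integer(median_window),
                 mas_wavelet = mas_wavelet,
                 mas_levels = as.integer(mas_levels),
                 mas_threshold_k = mas_threshold_k,
                 epoch_s = epoch_s),
            class = "preprocess_config")
}

#' Discard the initial settling segment of a recording
#'
#' The first minutes of a session (subject seated, vehicle stationary) are
#' excluded before any analysis.
#'
#' @param rec a [raw_recording()].
#' @param seconds nonnegative trim length; `floor(seconds * fs)` samples are
#'   removed from every channel and wavelength.
#' @return the trimmed [raw_recording()].
#' @export
trim_initial <- function(rec, seconds = 300) {
  validate_raw_recording(rec)
  stopifnot_scalar_num(seconds, "seconds", nonneg = TRUE)
  drop_n <- floor(seconds * rec$sampling_rate_hz)
  if (drop_n >= n_samples(rec))
    stop(sprintf("recording too short to trim %g s (%d samples available)",
                 seconds, n_samples(rec)))
  if (drop_n == 0) return(rec)
  rec$intensities <- rec$intensities[, , -(seq_len(drop_n)), drop = FALSE]
  rec
}

#' Sliding mean and median filters
#'
#' `mean_filter` averages over a centered window, truncated at the sequence
#' boundaries (so output length equals input length and edge samples average
#' over the available part of the window). `median_filter` takes the running
#' median over a centered window with edge-replication padding.
#'
#' @param x numeric sequence.
#' @param window odd positive integer, at most `length(x)`.
#' @return filtered sequence of the same length.
#' @export
#' @examples
#' mean_filter(c(1, 2, 3, 4, 5), 3)    # 1.5 2 3 4 4.5
#' median_filter(c(1, 9, 2, 9, 1), 3)  # 1 2 9 2 1
mean_filter <- function(x, window) {
  if (!is_odd_window(window)) stop("window must be an odd positive integer")
  n <- length(x)
  if (window > n) stop("window larger than sequence")
  if (window == 1) return(as.numeric(x))
  h <- (window - 1) %/% 2
  cs <- cumsum(c(0, as.numeric(x)))
  i <- seq_len(n)
  lo <- pmax(i - h, 1L)
  hi <- pmin(i + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' @rdname mean_filter
#' @export
median_filter <- function(x, window) {
  if (!is_odd_window(window)) stop("window must be an odd positive integer")
  n <- length(x)
  if (window > n) stop("window larger than sequence")
  if (window == 1) return(as.numeric(x))
  h <- (window - 1) %/% 2
  padded <- c(rep(x[1], h), as.numeric(x), rep(x[n], h))
  out <- stats::runmed(padded, window, endrule = "keep")
  out[(h + 1L):(h + n)]
}

#' Wavelet-threshold motion-artifact suppression
#'
#' Movement of the optical probe produces spikes and baseline shifts far
#' larger than the hemodynamic signal. The sequence is decomposed with a
#' multilevel DWT; within each detail level, coefficients whose magnitude
#' exceeds a robust threshold `tau_j = k * 1.4826 * MAD(d_j)` are clipped to
#' `sign(d) * tau_j`; the inverse transform returns the corrected sequence.
#' On artifact-free signals (no coefficient above threshold) the operation is
#' an exact no-op up to reconstruction error.
#'
#' @param x numeric sequence of length at least `2^cfg$mas_levels`.
#' @param cfg a [preprocess_config()] (fields `mas_wavelet`, `mas_levels`,
#'   `mas_threshold_k` are used).
#' @return corrected sequence of the same length.
#' @export
suppress_motion_artifacts <- function(x, cfg = preprocess_config()) {
  spec <- wavelet_spec(cfg$mas_wavelet, cfg$mas_levels, "symmetric")
  if (length(x) < 2^spec$levels)
    stop(sprintf("input too short for %d-level artifact suppression",
                 spec$levels))
  co <- dwt_decompose(x, spec)
  for (j in seq_len(spec$levels)) {
    d <- co$details[[j]]
    tau <- cfg$mas_threshold_k * 1.4826 * stats::median(abs(d - stats::median(d)))
    over <- abs(d) > tau
    if (any(over)) d[over] <- sign(d[over]) * tau
    co$details[[j]] <- d
  }
  dwt_reconstruct(co)
}

#' Hemoglobin concentration-change recording
#'
#' @param delta_hbo,delta_hbr channel x time matrices of concentration
#'   changes (mM by default).
#' @param sampling_rate_hz sampling rate in Hz.
#' @param subject_id identifier.
#' @return list of class `hemo_recording`.
#' @export
hemo_recording <- function(delta_hbo, delta_hbr, sampling_rate_hz,
                           subject_id = "S01") {
  delta_hbo <- as.matrix(delta_hbo); delta_hbr <- as.matrix(delta_hbr)
  if (!all(dim(delta_hbo) == dim(delta_hbr)))
    stop("delta_hbo and delta_hbr must have identical dimensions")
  if (any(!is.finite(delta_hbo)) || any(!is.finite(delta_hbr)))
    stop("non-finite concentration values")
  stopifnot_scalar_num(sampling_rate_hz, "sampling_rate_hz", positive = TRUE)
  structure(list(subject_id = subject_id,
                 sampling_rate_hz = sampling_rate_hz,
                 delta_hbo = delta_hbo, delta_hbr = delta_hbr),
            class = "hemo_recording")
}

#' Modified Beer-Lambert conversion of intensities to concentration changes
#'
#' Per channel and wavelength, the optical-density change is
#' `dA(lambda, t) = -ln(I(lambda, t) / I0(lambda))` with the baseline
#' `I0` taken as the per-channel mean intensity over the first
#' `baseline_s` seconds. The 2x2 linear system
#' `dA(lambda) = sum_s eps[lambda, s] * dC_s * L * DPF(lambda)` is solved at
#' the two wavelengths for `(dC_HbO, dC_HbR)` at every sample.
#'
#' @param rec a [raw_recording()].
#' @param ext an [extinction_matrix()].
#' @param baseline_s baseline-averaging window in seconds (default 30).
#' @return a [hemo_recording()] in the concentration units implied by the
#'   extinction coefficients (mM for the defaults).
#' @export
mbll_convert <- function(rec, ext, baseline_s = 30) {
  validate_raw_recording(rec)
  if (!inherits(ext, "extinction_matrix")) stop("ext must be an extinction_matrix")
  nch <- n_channels(rec); n <- n_samples(rec)
  nb <- max(1L, min(n, floor(baseline_s * rec$sampling_rate_hz)))
  # effective coefficient matrix: M[w, s] = eps[w, s] * L * DPF(w)
  M <- ext$epsilon * (ext$pathlength_cm * ext$dpf)
  Minv <- solve(M)
  hbo <- matrix(NA_real_, nch, n)
  hbr <- matrix(NA_real_, nch, n)
  for (ch in seq_len(nch)) {
    I <- rec$intensities[ch, , , drop = TRUE]  # 2 x n
    I0 <- rowMeans(I[, seq_len(nb), drop = FALSE])
    dA <- -log(I / I0)
    C <- Minv %*% dA
    hbo[ch, ] <- C[1, ]
    hbr[ch, ] <- C[2, ]
  }
  hemo_recording(hbo, hbr, rec$sampling_rate_hz, rec$subject_id)
}

#' Split a hemodynamic recording into rating-aligned epochs
#'
#' Consecutive non-overlapping windows of `floor(epoch_s * fs)` samples, each
#' paired with the subjective rating reported at the window's end (ratings
#' record the state at the current time point). A trailing partial window is
#' dropped. Rating times are seconds from the start of the (already trimmed)
#' recording and must sit at the epoch boundaries to within one sample.
#'
#' @param hemo a [hemo_recording()].
#' @param ratings data frame with `time_s`, `score` (see [read_ratings()]).
#' @param epoch_s epoch length in seconds.
#' @return list of elements `list(hemo = <epoch hemo_recording>,
#'   rating = <one-row data frame>)`, one per complete epoch with a rating.
#' @export
segment_epochs <- function(hemo, ratings, epoch_s = 300) {
  if (!inherits(hemo, "hemo_recording")) stop("hemo must be a hemo_recording")
  ratings <- validate_ratings(ratings)
  stopifnot_scalar_num(epoch_s, "epoch_s", positive = TRUE)
  fs <- hemo$sampling_rate_hz
  len <- floor(epoch_s * fs)
  n <- ncol(hemo$delta_hbo)
  n_ep <- n %/% len
  if (n_ep < 1) stop("no complete epoch in recording")
  out <- vector("list", 0L)
  for (e in seq_len(n_ep)) {
    t_end <- e * epoch_s
    k <- which(abs(ratings$time_s - t_end) * fs <= 1)
    if (length(k) == 0) {
      miss <- which(ratings$time_s > (e - 1) * epoch_s &
                      ratings$time_s < t_end + epoch_s / 2)
      if (length(miss))
        stop(sprintf(
          "rating at %g s is misaligned with the %g-s epoch grid by more than one sample",
          ratings$time_s[miss[1]], epoch_s))
      next  # no rating for this window
    }
    idx <- ((e - 1) * len + 1):(e * len)
    ep <- hemo_recording(hemo$delta_hbo[, idx, drop = FALSE],
                         hemo$delta_hbr[, idx, drop = FALSE],
                         fs, hemo$subject_id)
    out[[length(out) + 1L]] <- list(hemo = ep, rating = ratings[k[1], ])
  }
  if (!length(out)) stop("no epoch could be paired with a rating")
  out
}
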
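#' Synthetic-study settings
#'
#' Defines a simulated multi-subject fNIRS riding study with the statistical
#' structure the analysis assumes: per epoch, the HbO series is a sum of five
#' frequency-jittered band components (cardiac, respiratory, myogenic,
#' neurogenic, endothelial) plus 1/f background noise; the sick state widens
#' the within-band frequency jitter (raising the band's spectral entropy,
#' which is what the features measure and is amplitude-invariant), most
#' strongly in band I and progressively less toward band V. Concentration
#' series are forward-projected to dual-wavelength light intensities through
#' the Beer-Lambert model and contaminated with Poisson-placed motion
#' artifacts.
#'
#' @param n_subjects number of subjects (default 13).
#' @param epochs_per_subject rated epochs per session (default 6, i.e. a
#'   30-minute ride rated every 5 minutes).
#' @param fs_hz sampling rate (default 10).
#' @param epoch_s epoch length in seconds (default 300).
#' @param band_freq_hz center frequency of each band component, bands I..V.
#' @param band_amplitude_mm component amplitudes in mM; low-frequency
#'   vasomotor components are larger than the cardiac pulsation, as in real
#'   prefrontal recordings.
#' @param jitter_frac baseline relative frequency-jitter bandwidth (fraction
#'   of the center frequency) per band.
#' @param effect_size per-band multiplier by which the sick state widens the
#'   jitter bandwidth (`jitter * (1 + effect_size * label)`); strongest in
#'   band I, weakest in band V.
#' @param label_prevalence probability an epoch is a sick (label 1) epoch.
#' @param artifact_rate_per_min expected motion artifacts per minute per
#'   channel.
#' @param artifact_magnitude relative intensity excursion of an artifact
#'   (must be < 1 to keep intensities positive).
#' @param noise_sd standard deviation of the 1/f background, in mM.
#' @param hbr_ratio ΔHbR is `hbr_ratio * ΔHbO` plus independent noise
#'   (physiological anticorrelation).
#' @param dominant_gain amplitude multiplier of the designated dominant
#'   channel relative to the other five.
#' @param baseline_intensity resting light intensity in device units.
#' @param extinction an [extinction_matrix()] used by the forward model.
#' @param seed integer seed; everything the generator does is a deterministic
#'   function of (config, seed).
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_subjects = 13, epochs_per_subject = 6,
                             fs_hz = 10, epoch_s = 300,
                             band_freq_hz = c(1.1, 0.25, 0.09, 0.032, 0.014),
                             band_amplitude_mm = c(0.4, 0.5, 0.6, 0.8, 1.0) * 1e-3,
                             jitter_frac = rep(0.04, 5),
                             effect_size = c(1.5, 1.0, 0.6, 0.35, 0.2),
                             label_prevalence = 0.5,
                             artifact_rate_per_min = 0.5,
                             artifact_magnitude = 0.2,
                             noise_sd = 0.3e-3,
                             hbr_ratio = -0.3,
                             dominant_gain = 5,
                             baseline_intensity = 1000,
                             extinction = extinction_matrix(),
                             seed = 1) {
  if (n_subjects < 1 || epochs_per_subject < 1)
    stop("need at least one subject and one epoch")
  stopifnot_scalar_num(fs_hz, "fs_hz", positive = TRUE)
  stopifnot_scalar_num(epoch_s, "epoch_s", positive = TRUE)
  if (length(band_freq_hz) != 5 || length(band_amplitude_mm) != 5 ||
      length(jitter_frac) != 5 || length(effect_size) != 5)
    stop("band parameter vectors must have length 5 (bands I..V)")
  if (any(band_amplitude_mm < 0) || any(jitter_frac < 0))
    stop("amplitudes and jitter fractions must be nonnegative")
  if (label_prevalence <= 0 || label_prevalence >= 1)
    stop("label_prevalence must lie in (0, 1)")
  stopifnot_scalar_num(artifact_rate_per_min, "artifact_rate_per_min", nonneg = TRUE)
  if (artifact_magnitude >= 1 || artifact_magnitude < 0)
    stop("artifact_magnitude must lie in [0, 1)")
  stopifnot_scalar_num(noise_sd, "noise_sd", nonneg = TRUE)
  stopifnot_scalar_num(baseline_intensity, "baseline_intensity", positive = TRUE)
  structure(list(n_subjects = as.integer(n_subjects),
                 epochs_per_subject = as.integer(epochs_per_subject),
                 fs_hz = fs_hz, epoch_s = epoch_s,
                 band_freq_hz = band_freq_hz,
                 band_amplitude_mm = band_amplitude_mm,
                 jitter_frac = jitter_frac, effect_size = effect_size,
                 label_prevalence = label_prevalence,
                 artifact_rate_per_min = artifact_rate_per_min,
                 artifact_magnitude = artifact_magnitude,
                 noise_sd = noise_sd, hbr_ratio = hbr_ratio,
                 dominant_gain = dominant_gain,
                 baseline_intensity = baseline_intensity,
                 extinction = extinction, seed = as.integer(seed)),
            class = "synthetic_config")
}

# 1/f-amplitude ("pink") noise of length n, unit standard deviation.
pink_noise <- function(n) {
  w <- stats::rnorm(n)
  W <- stats::fft(w)
  k <- seq_len(n) - 1
  f <- pmin(k, n - k)          # two-sided frequency index
  scale <- c(0, 1 / sqrt(f[-1]))
  x <- Re(stats::fft(W * scale, inverse = TRUE)) / n
  s <- stats::sd(x)
  if (s > 0) x / s else x
}

#' Simulate one epoch of hemodynamic concentration changes
#'
#' The HbO series is a sum over the five bands of a sinusoid whose
#' instantaneous frequency wanders around the band center (an AR(1)-smoothed
#' deviation with relative bandwidth `jitter_frac`, widened by
#' `1 + effect_size` under label 1), plus 1/f background noise. ΔHbR is an
#' anticorrelated copy with independent noise.
#'
#' @param cfg a [synthetic_config()].
#' @param label 0 (well) or 1 (sick).
#' @param seed integer seed; identical seeds give identical sequences.
#' @param amplitude_gain optional overall multiplier on the band amplitudes
#'   (used for the dominant channel).
#' @return list with `delta_hbo` and `delta_hbr`, each of length
#'   `epoch_s * fs_hz`.
#' @export
simulate_hemo_epoch <- function(cfg, label, seed, amplitude_gain = 1) {
  if (!label %in% c(0, 1)) stop("label must be 0 or 1")
  n <- floor(cfg$epoch_s * cfg$fs_hz)
  local_seed(seed, {
    hbo <- numeric(n)
    for (b in 1:5) {
      fc <- cfg$band_freq_hz[b]
      amp <- cfg$band_amplitude_mm[b] * amplitude_gain
      if (amp == 0) next
      jit <- cfg$jitter_frac[b] * (1 + cfg$effect_size[b] * label)
      # AR(1)-smoothed frequency deviation; correlation time ~ 3 band periods
      alpha <- exp(-fc / (3 * cfg$fs_hz))
      e <- stats::rnorm(n)
      z <- as.numeric(stats::filter(sqrt(1 - alpha^2) * e, alpha,
                                    method = "recursive"))
      f_inst <- fc * (1 + jit * z)
      phase <- 2 * pi * cumsum(f_inst) / cfg$fs_hz + stats::runif(1, 0, 2 * pi)
      hbo <- hbo + amp * sin(phase)
    }
    if (cfg$noise_sd > 0) hbo <- hbo + cfg$noise_sd * pink_noise(n)
    hbr <- cfg$hbr_ratio * hbo
    if (cfg$noise_sd > 0) hbr <- hbr + 0.5 * cfg$noise_sd * pink_noise(n)
    list(delta_hbo = hbo, delta_hbr = hbr)
  })
}

#' Forward Beer-Lambert projection of concentration changes to intensities
#'
#' Inverse of the conversion performed by [mbll_convert()]:
#' `I(lambda, t) = baseline * exp(-(eps[lambda, HbO] dHbO(t) +
#' eps[lambda, HbR] dHbR(t)) * L * DPF(lambda))`. Output intensities are
#' strictly positive.
#'
#' @param hbo,hbr concentration-change sequences (same length, mM).
#' @param ext an [extinction_matrix()].
#' @param baseline resting intensity, scalar or one value per wavelength.
#' @return `2 x n` matrix of intensities (rows = wavelengths).
#' @export
hbo_to_intensity_forward <- function(hbo, hbr, ext, baseline) {
  if (length(hbo) != length(hbr)) stop("hbo and hbr must have equal length")
  if (any(baseline <= 0)) stop("nonpositive baseline intensity")
  if (length(baseline) == 1) baseline <- rep(baseline, 2)
  M <- ext$epsilon * (ext$pathlength_cm * ext$dpf)
  dA <- M %*% rbind(hbo, hbr)   # 2 x n optical-density changes
  baseline * exp(-dA)
}

#' Inject motion artifacts into a recording
#'
#' Poisson-placed events per channel: short spikes (1-3 samples) and
#' transient baseline shifts (the probe displaces and settles back after a
#' few seconds; duration drawn uniformly from 2-10 s), each multiplying the
#' intensity of both wavelengths by `1 +/- magnitude`.
#'
#' @param rec a [raw_recording()].
#' @param rate_per_min expected events per minute per channel.
#' @param magnitude relative excursion, in `[0, 1)`.
#' @param seed integer seed.
#' @return list with `recording` (contaminated copy) and `artifacts`
#'   (data frame: `channel`, `index`, `type`, `factor`).
#' @export
inject_artifacts <- function(rec, rate_per_min, magnitude, seed) {
  validate_raw_recording(rec)
  if (magnitude >= 1) stop("magnitude must be < 1 to keep intensities positive")
  n <- n_samples(rec)
  minutes <- n / rec$sampling_rate_hz / 60
  events <- list()
  if (rate_per_min > 0 && magnitude > 0) {
    local_seed(seed, {
      for (ch in seq_len(n_channels(rec))) {
        k <- stats::rpois(1, rate_per_min * minutes)
        if (k == 0) next
        pos <- sort(sample.int(n, min(k, n)))
        type <- sample(c("spike", "shift"), length(pos), replace = TRUE)
        sgn <- sample(c(-1, 1), length(pos), replace = TRUE)
        width <- sample(1:3, length(pos), replace = TRUE)
        shift_len <- pmax(1L, round(stats::runif(length(pos), 2, 10) *
                                      rec$sampling_rate_hz))
        for (i in seq_along(pos)) {
          fac <- 1 + sgn[i] * magnitude
          idx <- if (type[i] == "spike")
            pos[i]:min(n, pos[i] + width[i] - 1)
          else pos[i]:min(n, pos[i] + shift_len[i] - 1L)
          rec$intensities[ch, , idx] <- rec$intensities[ch, , idx] * fac
          events[[length(events) + 1L]] <-
            data.frame(channel = ch, index = pos[i], type = type[i],
                       factor = fac)
        }
      }
    })
  }
  artifacts <- if (length(events)) do.call(rbind, events)
  else data.frame(channel = integer(), index = integer(),
                  type = character(), factor = numeric())
  list(recording = rec, artifacts = artifacts)
}

#' Generate a full synthetic study
#'
#' Produces `n_subjects` sessions. Each session starts with a stationary
#' settling segment of `trim_s` seconds (background noise only, so the
#' initial-trim stage has something real to discard), followed by
#' `epochs_per_subject` labeled epochs. One designated channel per subject
#' (rotating across subjects) carries the band signal at `dominant_gain`
#' times the amplitude of the other five channels; ratings are reported at
#' epoch ends on the 6-point scale.
#'
#' @param cfg a [synthetic_config()].
#' @param trim_s length of the stationary pre-segment in seconds
#'   (default 300, matched to the default preprocessing trim).
#' @return list with `recordings` (list of [raw_recording()]), `ratings`
#'   (list of data frames, times in seconds from ride onset), and
#'   `ground_truth` (`epochs` data frame with per-epoch label/score and the
#'   dominant channel; `artifacts` per subject).
#' @export
generate_study <- function(cfg = synthetic_config(), trim_s = 300) {
  n_ep_samples <- floor(cfg$epoch_s * cfg$fs_hz)
  n_pre <- floor(trim_s * cfg$fs_hz)
  recordings <- vector("list", cfg$n_subjects)
  ratings <- vector("list", cfg$n_subjects)
  gt_rows <- list()
  gt_art <- vector("list", cfg$n_subjects)
  for (s in seq_len(cfg$n_subjects)) {
    subject_id <- sprintf("S%02d", s)
    dominant <- ((s - 1L) %% 6L) + 1L
    labels <- local_seed(derive_seed(cfg$seed, s, 777),
                         as.integer(stats::runif(cfg$epochs_per_subject) <
                                      cfg$label_prevalence))
    scores <- local_seed(derive_seed(cfg$seed, s, 778), {
      vapply(labels, function(l)
        if (l == 1) sample(2:5, 1) else sample(0:1, 1), integer(1))
    })
    n_total <- n_pre + cfg$epochs_per_subject * n_ep_samples
    arr <- array(NA_real_, c(6L, 2L, n_total))
    for (ch in 1:6) {
      gain <- if (ch == dominant) cfg$dominant_gain else 1
      hbo <- numeric(n_total); hbr <- numeric(n_total)
      if (n_pre > 0) {
        pre <- local_seed(derive_seed(cfg$seed, s, ch, 999), {
          list(hbo = cfg$noise_sd * pink_noise(n_pre),
               hbr = 0.5 * cfg$noise_sd * pink_noise(n_pre))
        })
        hbo[seq_len(n_pre)] <- pre$hbo
        hbr[seq_len(n_pre)] <- pre$hbr
      }
      for (e in seq_len(cfg$epochs_per_subject)) {
        idx <- n_pre + ((e - 1L) * n_ep_samples + 1L):(e * n_ep_samples)
        ep <- simulate_hemo_epoch(cfg, labels[e],
                                  seed = derive_seed(cfg$seed, s, ch, e),
                                  amplitude_gain = gain)
        hbo[idx] <- ep$delta_hbo
        hbr[idx] <- ep$delta_hbr
      }
      arr[ch, , ] <- hbo_to_intensity_forward(hbo, hbr, cfg$extinction,
                                              cfg$baseline_intensity)
    }
    rec <- raw_recording(arr, sampling_rate_hz = cfg$fs_hz,
                         subject_id = subject_id)
    inj <- inject_artifacts(rec, cfg$artifact_rate_per_min,
                            cfg$artifact_magnitude,
                            seed = derive_seed(cfg$seed, s, 555))
    recordings[[s]] <- inj$recording
    gt_art[[s]] <- inj$artifacts
    ratings[[s]] <- data.frame(time_s = cfg$epoch_s * seq_len(cfg$epochs_per_subject),
                               score = scores)
    gt_rows[[s]] <- data.frame(subject_id = subject_id,
                               epoch_id = seq_len(cfg$epochs_per_subject),
                               score = scores, label = labels,
                               dominant_channel = dominant)
  }
  names(recordings) <- names(ratings) <- names(gt_art) <-
    vapply(recordings, function(r) r$subject_id, character(1))
  list(recordings = recordings, ratings = ratings,
       ground_truth = list(epochs = do.call(rbind, gt_rows),
                           artifacts = gt_art, config = unclass(cfg)))
}

#' Write a synthetic study to disk
#'
#' One recording CSV and one ratings CSV per subject, plus
#' `ground_truth.json`, in the formats read by [read_recording()] and
#' [read_ratings()].
#'
#' @param study result of [generate_study()].
#' @param dir output directory (created if missing).
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (id in names(study$recordings)) {
    write_recording(study$recordings[[id]],
                    file.path(dir, paste0(id, ".csv")))
    write_ratings(study$ratings[[id]],
                  file.path(dir, paste0(id, "_ratings.csv")))
  }
  jsonlite::write_json(
    list(epochs = study$ground_truth$epochs,
         artifacts = study$ground_truth$artifacts),
    file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
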
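#' Construct a raw fNIRS recording
#'
#' A raw recording holds the light-intensity time series of a multi-channel,
#' dual-wavelength fNIRS session in arbitrary device units. Intensities are
#' stored as a `channel x wavelength x time` array and must be strictly
#' positive (light is either received or the sample is invalid).
#'
#' @param intensities numeric array of dimension
#'   `c(n_channels, n_wavelengths, n_samples)` with strictly positive entries.
#' @param sampling_rate_hz sampling rate in Hz (device default 10).
#' @param wavelengths_nm the two source wavelengths in nm (default 730, 850).
#' @param subject_id identifier string.
#' @return An object of class `raw_recording`.
#' @export
#' @examples
#' rec <- raw_recording(array(100, c(6, 2, 50)))
#' dim(rec$intensities)
raw_recording <- function(intensities, sampling_rate_hz = 10,
                          wavelengths_nm = c(730, 850),
                          subject_id = "S01") {
  rec <- structure(
    list(subject_id = as.character(subject_id),
         sampling_rate_hz = sampling_rate_hz,
         wavelengths_nm = as.numeric(wavelengths_nm),
         intensities = intensities),
    class = "raw_recording")
  validate_raw_recording(rec)
}

#' @rdname raw_recording
#' @param rec object to validate.
#' @export
validate_raw_recording <- function(rec) {
  if (!inherits(rec, "raw_recording")) stop("not a raw_recording")
  stopifnot_scalar_num(rec$sampling_rate_hz, "sampling_rate_hz", positive = TRUE)
  if (length(rec$wavelengths_nm) != 2L || any(rec$wavelengths_nm <= 0))
    stop("wavelengths_nm must be an ordered pair of positive reals")
  x <- rec$intensities
  if (!is.array(x) || length(dim(x)) != 3L)
    stop("intensities must be a channel x wavelength x time array")
  if (dim(x)[2] != 2L) stop("intensities must have two wavelength slices")
  if (any(!is.finite(x)) || any(x <= 0))
    stop("nonpositive intensity in recording")
  rec
}

#' @rdname raw_recording
#' @export
n_channels <- function(rec) dim(rec$intensities)[1]

#' @rdname raw_recording
#' @export
n_samples <- function(rec) dim(rec$intensities)[3]

#' @export
print.raw_recording <- function(x, ...) {
  cat(sprintf("<raw_recording> subject %s: %d channels x 2 wavelengths (%g/%g nm), %d samples @ %g Hz\n",
              x$subject_id, n_channels(x), x$wavelengths_nm[1],
              x$wavelengths_nm[2], n_samples(x), x$sampling_rate_hz))
  invisible(x)
}

#' Read and write recordings in the package CSV dialect
#'
#' The on-disk format is a plain-text CSV with one comment header line:
#' `# fs_hz=<float> wavelengths_nm=<w1>,<w2> channels=<n>` followed by one row
#' per sample `t_s,ch1_w1,ch1_w2,...,chN_w1,chN_w2`. UTF-8, '.' decimal
#' separator. Values are written with 17 significant digits so a
#' write/read/write cycle is byte-identical and numeric round trips are exact
#' to better than 1e-12.
#'
#' @param path file path.
#' @param subject_id subject identifier to attach on read (the dialect does not
#'   store it; defaults to the file's base name).
#' @return `read_recording` returns a [raw_recording()]; `write_recording`
#'   returns `path` invisibly.
#' @export
read_recording <- function(path, subject_id = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 2L) stop(sprintf("parse error at line 1 in %s: empty recording", path))
  hd <- lines[1]
  m <- regmatches(hd, regexec(
    "^#\\s*fs_hz=([0-9.eE+-]+)\\s+wavelengths_nm=([0-9.eE+-]+),([0-9.eE+-]+)\\s+channels=([0-9]+)\\s*$",
    hd))[[1]]
  if (length(m) != 5L)
    stop(sprintf("parse error at line 1 in %s: malformed header", path))
  fs <- as.numeric(m[2]); wl <- as.numeric(m[3:4]); nch <- as.integer(m[5])
  body <- lines[-1]
  body <- body[nzchar(body)]
  n <- length(body)
  ncol_expect <- 1L + 2L * nch
  mat <- matrix(NA_real_, nrow = n, ncol = ncol_expect)
  for (i in seq_len(n)) {
    f <- strsplit(body[i], ",", fixed = TRUE)[[1]]
    if (length(f) != ncol_expect)
      stop(sprintf("parse error at line %d in %s: expected %d fields, got %d",
                   i + 1L, path, ncol_expect, length(f)))
    v <- suppressWarnings(as.numeric(f))
    if (any(is.na(v)))
      stop(sprintf("parse error at line %d in %s: non-numeric field", i + 1L, path))
    mat[i, ] <- v
  }
  vals <- mat[, -1, drop = FALSE]
  if (any(vals <= 0)) {
    bad <- which(rowSums(vals <= 0) > 0)[1]
    stop(sprintf("nonpositive intensity at line %d in %s", bad + 1L, path))
  }
  arr <- array(NA_real_, c(nch, 2L, n))
  for (ch in seq_len(nch)) {
    arr[ch, 1, ] <- vals[, 2L * ch - 1L]
    arr[ch, 2, ] <- vals[, 2L * ch]
  }
  raw_recording(arr, sampling_rate_hz = fs, wavelengths_nm = wl,
                subject_id = subject_id %||% sub("\\.[^.]*$", "", basename(path)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname read_recording
#' @param rec a [raw_recording()].
#' @export
write_recording <- function(rec, path) {
  validate_raw_recording(rec)
  nch <- n_channels(rec); n <- n_samples(rec)
  hd <- sprintf("# fs_hz=%s wavelengths_nm=%s,%s channels=%d",
                fmt17(rec$sampling_rate_hz), fmt17(rec$wavelengths_nm[1]),
                fmt17(rec$wavelengths_nm[2]), nch)
  t_s <- (seq_len(n) - 1) / rec$sampling_rate_hz
  cols <- vector("list", 1L + 2L * nch)
  cols[[1]] <- fmt17(t_s)
  for (ch in seq_len(nch)) {
    cols[[2L * ch]] <- fmt17(rec$intensities[ch, 1, ])
    cols[[2L * ch + 1L]] <- fmt17(rec$intensities[ch, 2, ])
  }
  rows <- do.call(paste, c(cols, sep = ","))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(hd, rows), con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

fmt17 <- function(x) sprintf("%.17g", x)

#' Read per-epoch subjective motion-sickness ratings
#'
#' Ratings are integers on a 6-point scale (0 = no motion sickness at all,
#' 5 = unbearable), reported at fixed intervals during the ride. Times are
#' seconds from ride onset (i.e. after the discarded settling segment) and
#' must be strictly increasing.
#'
#' @param path CSV file with header `time_s,score`.
#' @return data frame with columns `time_s`, `score`, sorted as given.
#' @export
read_ratings <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- utils::read.csv(path)
  if (!all(c("time_s", "score") %in% names(df)))
    stop(sprintf("parse error in %s: expected columns time_s,score", path))
  validate_ratings(df[, c("time_s", "score")])
}

#' @rdname read_ratings
#' @param ratings data frame with columns `time_s`, `score`.
#' @export
validate_ratings <- function(ratings) {
  t <- ratings$time_s; s <- ratings$score
  if (any(!is.finite(t)) || any(t < 0)) stop("rating times must be nonnegative")
  if (any(diff(t) <= 0)) stop("rating times not increasing")
  if (any(s != round(s)) || any(s < 0) || any(s > 5))
    stop("rating score outside 0-5 scale")
  ratings$score <- as.integer(ratings$score)
  ratings
}

#' @rdname read_ratings
#' @export
write_ratings <- function(ratings, path) {
  validate_ratings(ratings)
  utils::write.csv(ratings[, c("time_s", "score")], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
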
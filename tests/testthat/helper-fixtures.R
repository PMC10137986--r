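# Builders shared across test files. All fixtures are generated in code.

make_recording <- function(n = 400, nch = 6, fs = 10, seed = 1,
                           baseline = 1000) {
  set.seed(seed)
  arr <- array(NA_real_, c(nch, 2, n))
  t <- (seq_len(n) - 1) / fs
  for (ch in seq_len(nch)) for (w in 1:2) {
    arr[ch, w, ] <- baseline * exp(0.01 * sin(2 * pi * 0.1 * t + ch + w) +
                                     0.001 * rnorm(n))
  }
  raw_recording(arr, sampling_rate_hz = fs, subject_id = sprintf("T%02d", seed))
}

make_hemo <- function(hbo, fs = 10) {
  hbo <- rbind(hbo)
  hemo_recording(hbo, -0.3 * hbo, fs)
}

# Direct DFT power spectrum, written independently of the package internals.
dft_power_oracle <- function(x) {
  n <- length(x)
  k <- 0:(n - 1)
  sapply(k, function(kk) {
    Mod(sum(x * exp(-2i * pi * kk * (0:(n - 1)) / n)))^2 / n
  })
}
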
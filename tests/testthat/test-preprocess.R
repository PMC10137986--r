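test_that("initial trim removes exactly the settling segment", {
  rec <- make_recording(n = 21000, nch = 2)  # 35 min at 10 Hz
  out <- trim_initial(rec, 300)
  expect_equal(n_samples(out), 18000)        # 30 min retained
  expect_equal(out$intensities, rec$intensities[, , -(1:3000)])

  expect_identical(trim_initial(rec, 0), rec)
  short <- make_recording(n = 100)
  expect_error(trim_initial(short, 300), "too short")
})

test_that("mean filter averages a truncated centered window", {
  expect_equal(mean_filter(c(5, 5, 5), 3), c(5, 5, 5))
  expect_equal(mean_filter(c(1, 2, 3, 4, 5), 3), c(1.5, 2, 3, 4, 4.5))
  expect_error(mean_filter(1:10, 4), "odd")
  expect_error(mean_filter(1:3, 5), "larger than sequence")

  # direct truncated-window summation oracle on random input
  set.seed(11)
  x <- rnorm(50)
  for (w in c(1, 3, 7)) {
    h <- (w - 1) / 2
    oracle <- sapply(seq_along(x), function(i)
      mean(x[max(1, i - h):min(length(x), i + h)]))
    expect_equal(mean_filter(x, w), oracle)
  }
  expect_identical(mean_filter(x, 1), x)
})

test_that("median filter slides over edge-replicated padding", {
  expect_equal(median_filter(c(1, 2, 3), 3), c(1, 2, 3))
  expect_equal(median_filter(c(1, 9, 2, 9, 1), 3), c(1, 2, 9, 2, 1))
  expect_error(median_filter(1:10, 2), "odd")

  set.seed(12)
  x <- rnorm(60)
  for (w in c(3, 5, 9)) {
    h <- (w - 1) / 2
    padded <- c(rep(x[1], h), x, rep(x[length(x)], h))
    oracle <- sapply(seq_along(x), function(i) median(padded[i:(i + w - 1)]))
    expect_equal(median_filter(x, w), oracle)
    expect_equal(median_filter(rep(2, 30), w), rep(2, 30))  # constant invariance
  }
  expect_identical(median_filter(x, 1), x)
})

test_that("motion-artifact suppression clips spikes and spares clean signal", {
  cfg <- preprocess_config()
  expect_equal(suppress_motion_artifacts(numeric(3000), cfg), numeric(3000))

  # a clean multi-tone with dense content at every detail level keeps all
  # coefficients under the robust threshold, so correction is a no-op
  t <- (0:2999) / 10
  clean <- sin(2 * pi * 3.75 * t) + sin(2 * pi * 1.875 * t + 1) +
    sin(2 * pi * 0.94 * t + 2) + sin(2 * pi * 0.47 * t + 3) +
    sin(2 * pi * 0.23 * t + 4)
  expect_lt(max(abs(suppress_motion_artifacts(clean, cfg) - clean)), 1e-8)

  spiked <- clean
  spiked[1500] <- spiked[1500] + 50
  corrected <- suppress_motion_artifacts(spiked, cfg)
  expect_lt(max(abs(corrected - clean)), max(abs(spiked - clean)))
  expect_equal(length(corrected), length(spiked))

  expect_error(suppress_motion_artifacts(rnorm(16), cfg), "too short")
})

test_that("modified Beer-Lambert conversion inverts the forward model", {
  ext <- extinction_matrix()
  n <- 1200
  fs <- 10
  # baseline window (first 30 s) at zero, then a concentration step
  hbo <- c(numeric(300), rep(1.0, n - 300))
  hbr <- c(numeric(300), rep(0.5, n - 300))
  I <- hbo_to_intensity_forward(hbo, hbr, ext, baseline = 500)
  arr <- array(NA_real_, c(1, 2, n))
  arr[1, , ] <- I
  rec <- raw_recording(arr, sampling_rate_hz = fs)
  hemo <- mbll_convert(rec, ext)
  expect_lt(max(abs(hemo$delta_hbo[1, ] - hbo)), 1e-9)
  expect_lt(max(abs(hemo$delta_hbr[1, ] - hbr)), 1e-9)

  # constant intensities give identically zero concentration changes
  rec0 <- raw_recording(array(250, c(3, 2, 400)))
  h0 <- mbll_convert(rec0, ext)
  expect_equal(max(abs(h0$delta_hbo)), 0)
  expect_equal(max(abs(h0$delta_hbr)), 0)

  # proportional wavelength rows are singular
  expect_error(extinction_matrix(matrix(c(1, 2, 2, 4), 2)), "singular")
})

test_that("epoch segmentation pairs windows with end-of-window ratings", {
  fs <- 10
  ratings <- data.frame(time_s = 300 * (1:6), score = c(0, 1, 2, 3, 4, 5))

  hemo <- make_hemo(matrix(rnorm(2 * 18000), 2), fs)   # 30 min
  eps <- segment_epochs(hemo, ratings, 300)
  expect_length(eps, 6)
  expect_true(all(vapply(eps, function(e) ncol(e$hemo$delta_hbo), 0) == 3000))
  expect_equal(vapply(eps, function(e) e$rating$score, 0L), 0:5)
  # windows are consecutive and non-overlapping
  expect_equal(eps[[2]]$hemo$delta_hbo[, 1], hemo$delta_hbo[, 3001])

  hemo31 <- make_hemo(matrix(rnorm(18600), 1), fs)     # 31 min
  expect_length(segment_epochs(hemo31, ratings, 300), 6)  # remainder dropped

  hemo4 <- make_hemo(matrix(rnorm(2400), 1), fs)       # 4 min
  expect_error(segment_epochs(hemo4, ratings, 300), "no complete epoch")

  misaligned <- data.frame(time_s = c(290, 600), score = c(1, 2))
  expect_error(segment_epochs(hemo, misaligned, 300), "misaligned")
})
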
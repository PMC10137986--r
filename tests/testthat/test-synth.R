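test_that("epoch simulation is deterministic and label-sensitive by design", {
  cfg <- synthetic_config()
  a <- simulate_hemo_epoch(cfg, 1, seed = 71)
  b <- simulate_hemo_epoch(cfg, 1, seed = 71)
  expect_identical(a, b)
  expect_length(a$delta_hbo, 3000)

  # a noise-free, jitter-free single band-I component is nearly a pure tone
  pure <- synthetic_config(band_amplitude_mm = c(1e-3, 0, 0, 0, 0),
                           jitter_frac = rep(0, 5), noise_sd = 0)
  ep <- simulate_hemo_epoch(pure, 0, seed = 72)
  f <- extract_features(make_hemo(ep$delta_hbo, pure$fs_hz), 1)
  expect_lt(f$values[["I"]], 0.3)
})

test_that("zero effect size makes the two label classes indistinguishable", {
  cfg <- synthetic_config(effect_size = rep(0, 5))
  pse_I <- matrix(NA_real_, 50, 2)
  for (r in 1:50) {
    for (lab in 0:1) {
      ep <- simulate_hemo_epoch(cfg, lab, seed = 7300 + 2 * r + lab)
      f <- extract_features(make_hemo(ep$delta_hbo, cfg$fs_hz), 1)
      pse_I[r, lab + 1] <- f$values[["I"]]
    }
  }
  ks <- suppressWarnings(ks.test(pse_I[, 1], pse_I[, 2]))
  expect_gt(ks$p.value, 0.01)
})

test_that("forward intensity projection is positive, monotone, and invertible", {
  ext <- extinction_matrix()
  I0 <- hbo_to_intensity_forward(numeric(100), numeric(100), ext, 800)
  expect_true(all(I0 == 800))

  # more HbO absorbs more strongly at the 850 nm-dominant wavelength
  I1 <- hbo_to_intensity_forward(rep(1e-3, 10), numeric(10), ext, 800)
  expect_true(all(I1[2, ] < 800))
  expect_true(all(I1 > 0))
  expect_error(hbo_to_intensity_forward(1, 0.5, ext, 0), "nonpositive baseline")
})

test_that("artifact injection is seeded Poisson with the configured rate", {
  rec <- make_recording(n = 18000, nch = 1)  # 30 min at 10 Hz

  none <- inject_artifacts(rec, 0, 0.2, seed = 1)
  expect_identical(none$recording$intensities, rec$intensities)
  expect_identical(nrow(none$artifacts), 0L)

  a <- inject_artifacts(rec, 2, 0.2, seed = 42)
  b <- inject_artifacts(rec, 2, 0.2, seed = 42)
  expect_identical(a$artifacts, b$artifacts)
  expect_identical(a$recording$intensities, b$recording$intensities)
  expect_error(inject_artifacts(rec, 1, 1.0, seed = 1), "magnitude")

  # rate 2/min for 30 min: counts concentrate in the central Poisson mass
  counts <- vapply(1:100, function(s)
    nrow(inject_artifacts(rec, 2, 0.2, seed = s)$artifacts), 0L)
  expect_gte(mean(counts >= 40 & counts <= 80), 0.95)
  expect_gt(mean(counts), 50)
  expect_lt(mean(counts), 70)
})

test_that("a generated study has consistent labels, ratings, and geometry", {
  cfg <- synthetic_config(n_subjects = 2, epochs_per_subject = 3, seed = 9)
  study <- generate_study(cfg, trim_s = 60)
  expect_length(study$recordings, 2)
  expect_equal(n_samples(study$recordings[[1]]), 600 + 3 * 3000)
  expect_true(all(study$recordings[[1]]$intensities > 0))

  gt <- study$ground_truth$epochs
  expect_equal(nrow(gt), 6)
  expect_identical(gt$label, binarize_score(gt$score))
  expect_true(all(gt$dominant_channel %in% 1:6))
  expect_equal(study$ratings[[1]]$time_s, c(300, 600, 900))
  expect_identical(study$ratings[[1]]$score, gt$score[gt$subject_id == "S01"])

  # deterministic given (config, seed)
  study2 <- generate_study(cfg, trim_s = 60)
  expect_identical(study$recordings[[2]]$intensities,
                   study2$recordings[[2]]$intensities)
  expect_identical(study$ground_truth$epochs, study2$ground_truth$epochs)
})

test_that("a synthetic study round-trips through disk", {
  cfg <- synthetic_config(n_subjects = 1, epochs_per_subject = 2, seed = 3)
  study <- generate_study(cfg, trim_s = 30)
  dir <- withr::local_tempdir()
  write_study(study, dir)
  expect_true(file.exists(file.path(dir, "S01.csv")))
  back <- read_recording(file.path(dir, "S01.csv"))
  expect_equal(back$intensities, study$recordings[[1]]$intensities,
               tolerance = 1e-12)
  expect_equal(read_ratings(file.path(dir, "S01_ratings.csv")),
               study$ratings[[1]])
})
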
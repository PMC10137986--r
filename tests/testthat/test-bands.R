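test_that("single-step analysis matches the independent wavelet oracle", {
  for (nm in names(dwt_oracle)) {
    o <- dwt_oracle[[nm]]
    cs <- dwt_decompose(o$x, wavelet_spec(levels = 1, padding = "symmetric"))
    expect_equal(cs$approx, o$sym_cA, tolerance = 1e-12)
    expect_equal(unname(cs$details$d1), o$sym_cD, tolerance = 1e-12)
    cp <- dwt_decompose(o$x, wavelet_spec(levels = 1, padding = "periodization"))
    expect_equal(cp$approx, o$per_cA, tolerance = 1e-12)
    expect_equal(unname(cp$details$d1), o$per_cD, tolerance = 1e-12)
  }
})

test_that("multilevel transform reconstructs perfectly for all padding modes", {
  set.seed(21)
  for (padding in c("symmetric", "periodization")) {
    for (n in c(600, 1537, 3000)) {
      x <- rnorm(n)
      spec <- wavelet_spec(levels = 9, padding = padding)
      co <- dwt_decompose(x, spec)
      err <- max(abs(dwt_reconstruct(co) - x))
      expect_lt(err, 1e-8)
    }
  }
})

test_that("periodized transform conserves energy on dyadic lengths", {
  set.seed(22)
  x <- rnorm(4096)
  co <- dwt_decompose(x, wavelet_spec(levels = 9, padding = "periodization"))
  e_coef <- sum(co$approx^2) + sum(vapply(co$details, function(d) sum(d^2), 0))
  expect_lt(abs(e_coef - sum(x^2)), 1e-8 * sum(x^2))
})

test_that("decomposition rejects invalid inputs", {
  expect_error(dwt_decompose(rnorm(100), wavelet_spec(levels = 9)), "too short")
  expect_error(wavelet_spec("haar"), "unknown wavelet")
})

test_that("detail sub-band edges halve with each level", {
  expect_equal(detail_band_edges(10, 1), c(2.5, 5.0))
  expect_equal(detail_band_edges(10, 3), c(0.625, 1.25))
  expect_equal(detail_band_edges(10, 9), c(0.009765625, 0.01953125))
  expect_error(detail_band_edges(10, 0), "positive integer")
})

test_that("containment rule reproduces the physiological band mapping", {
  mp <- assign_levels_to_bands(10, band_table(), 9)
  expect_identical(unname(mp), c(3L, 5L, 6L, 8L, 9L))
  expect_identical(names(mp), c("I", "II", "III", "IV", "V"))

  # at 8 levels the endothelial band has no covering sub-band
  expect_error(assign_levels_to_bands(10, band_table(), 8), "band V")

  # a band that equals one sub-band exactly maps to that level
  one <- data.frame(name = "X", f_low_hz = 0.625, f_high_hz = 1.25,
                    physiology = "synthetic")
  expect_identical(unname(assign_levels_to_bands(10, one, 9)), 3L)

  # Nyquist guard: fs must exceed twice the highest band edge
  expect_error(assign_levels_to_bands(3, band_table(), 9), "Nyquist")
})

test_that("band reconstruction is linear and localizes a cardiac tone in d3", {
  set.seed(23)
  x <- rnorm(3000)
  spec <- wavelet_spec(levels = 9)
  co <- dwt_decompose(x, spec)

  # all-zero coefficients reconstruct to zero
  z <- co
  z$approx <- numeric(length(z$approx))
  for (j in 1:9) z$details[[j]] <- numeric(length(z$details[[j]]))
  expect_equal(dwt_reconstruct(z), numeric(3000))

  # sum of all band reconstructions plus approximation equals the input
  parts <- Reduce(`+`, lapply(1:9, function(j) reconstruct_band(co, j)))
  approx_only <- co
  for (j in 1:9) approx_only$details[[j]] <- numeric(length(co$details[[j]]))
  expect_lt(max(abs(parts + dwt_reconstruct(approx_only) - x)), 1e-8)

  expect_error(reconstruct_band(co, 10), "level")

  # a 1 Hz tone at fs 10 lands in d3 (0.625-1.25 Hz) with most of its energy
  tone <- sin(2 * pi * 1.0 * (0:2999) / 10)
  cot <- dwt_decompose(tone, spec)
  energies <- vapply(cot$details, function(d) sum(d^2), 0)
  expect_identical(unname(which.max(energies)), 3L)
  band1 <- reconstruct_band(cot, 3)
  expect_gt(sum(band1^2) / sum(tone^2), 0.6)
})

test_that("decompose_bands returns full-length series under the printed mapping", {
  x <- rnorm(3000)
  dec <- decompose_bands(x, 10)
  expect_identical(unname(dec$mapping), c(3L, 5L, 6L, 8L, 9L))
  expect_true(all(vapply(dec$band_series, length, 0) == 3000))
})
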
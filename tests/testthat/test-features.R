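# Feature representations: spectra, band powers, freeze-index features,
# inertial MFCCs and contextual stacking.

test_that("FFT spectrum matches direct DFT summation and keeps 64 bins", {
  w <- sine_window(5)                     # bin 5*128/40 = 16
  sp <- fft_spectrum(w)
  expect_equal(dim(sp), c(64, 3))
  expect_equal(length(as.numeric(sp)), 192)
  expect_equal(unname(which.max(sp[, 1]) - 1), 16)
  for (axis in 1:3)
    expect_lt(max(abs(sp[, axis] - oracle_dft_mag(w[, axis]))), 1e-8)
  expect_true(all(fft_spectrum(matrix(0, 128, 3)) == 0))
  expect_error(fft_spectrum(matrix(0, 64, 3)), "128 x 3")

  fogkit:::with_seed(8, {
    wr <- matrix(rnorm(128 * 3), 128)
    spr <- fft_spectrum(wr)
    for (axis in 1:3)
      expect_lt(max(abs(spr[, axis] - oracle_dft_mag(wr[, axis]))), 1e-8)
  })
})

test_that("Parseval: time-domain energy equals scaled full-spectrum energy", {
  fogkit:::with_seed(9, {
    x <- rnorm(128)
    expect_equal(sum(x^2), sum(Mod(stats::fft(x))^2) / 128,
                 tolerance = 1e-6)
  })
})

test_that("band power is half-open, additive, and Parseval-consistent", {
  sp <- fft_spectrum(sine_window(6))[, 1]
  expect_equal(band_power(numeric(64), c(3, 8)), 0)
  expect_error(band_power(sp, c(8, 3)), "inverted")
  # a 6 Hz tone concentrates its power in the freeze band; via Parseval the
  # half-spectrum energy equals 64 * sum(x^2) for a tone away from DC/Nyquist
  total_power <- sum(sp^2)
  expect_equal(total_power, 64 * sum(sine_window(6)[, 1]^2), tolerance = 1e-3)
  expect_gt(band_power(sp, c(3, 8)) / total_power, 0.9)
  # additivity of adjacent half-open bands (3 Hz belongs to the freeze band)
  expect_equal(band_power(sp, c(0.5, 3)) + band_power(sp, c(3, 8)),
               band_power(sp, c(0.5, 8)))
})

test_that("freeze-index features: dimensions, conventions, discrimination", {
  v <- mazilu_features(sine_window(2))
  expect_length(v, 21)

  z <- mazilu_features(matrix(0, 128, 3))
  expect_true(all(z == 0))  # mean, sd, var, entropy, energy, FI, band power

  fi6 <- freeze_index(sine_window(6)[, 1])
  fi1 <- freeze_index(sine_window(1)[, 1])
  expect_gt(fi6, 10)
  expect_lt(fi1, 0.1)

  # scale invariance of the freeze index
  x <- sine_window(6)[, 1] + 0.3 * sine_window(1.5)[, 1]
  expect_equal(freeze_index(3.7 * x), freeze_index(x), tolerance = 1e-9)

  # the feature blocks carry mean / sd / var / energy as documented
  w <- sine_window(2) + 0.25
  v2 <- mazilu_features(w)
  expect_equal(v2[1], mean(w[, 1]))
  expect_equal(v2[2], stats::sd(w[, 1]))
  expect_equal(v2[3], stats::var(w[, 1]))
  expect_equal(v2[5], sum(w[, 1]^2))
})

test_that("inertial MFCCs match the brute-force filterbank/DCT loop", {
  fogkit:::with_seed(10, {
    w <- matrix(rnorm(128 * 3), 128)
    v <- inertial_mfcc(w)
    expect_length(v, 36)
    for (axis in 1:3)
      expect_lt(max(abs(v[(axis - 1) * 12 + 1:12] -
                          oracle_mfcc_axis(w[, axis]))), 1e-8)
  })
  # all-zero window: constant (floored) log energies -> only c0 survives
  vz <- inertial_mfcc(matrix(0, 128, 3))
  expect_true(all(abs(vz[2:12]) < 1e-10))
  expect_lt(vz[1], 0)  # log floor is deeply negative
  expect_error(inertial_mfcc(sine_window(2), n_coeff = 25), "exceeds")
})

test_that("contextual stacking pairs each window with its own recording's past", {
  ws <- tone_windows(rep(2, 10), integer(10))
  sp <- fogkit:::windows_spectra(ws)
  st <- stack_contextual(sp, ws$recording_id, 3)
  expect_equal(dim(st$values), c(7, 768))
  expect_equal(st$keep, 4:10)
  expect_equal(stack_contextual(sp, ws$recording_id, 0)$values, sp)
  expect_error(stack_contextual(sp, ws$recording_id, -1), ">= 0")

  # enumeration oracle across context depths
  for (k in 0:3)
    expect_equal(nrow(stack_contextual(sp, ws$recording_id, k)$values), 10 - k)

  # never mixes recordings: two recordings of 4 and 6 windows, k = 2
  rid <- rep(c("r1", "r2"), c(4, 6))
  st2 <- stack_contextual(sp, rid, 2)
  expect_equal(nrow(st2$values), (4 - 2) + (6 - 2))
  # the oldest step of the first surviving r2 stack is r2's first window
  r2_first <- which(st2$keep == 7)
  expect_equal(st2$values[r2_first, 1:192], sp[5, ])
})

test_that("representation dimensionalities are exactly as designed", {
  ws <- tone_windows(c(1, 2, 6, 7, 2, 3), c(0L, 0L, 1L, 1L, 0L, 0L))
  expect_equal(ncol(featurize(ws, "mazilu")$values), 21)
  expect_equal(ncol(featurize(ws, "mfcc")$values), 36)
  for (k in 0:3) {
    fm <- featurize(ws, "fft", k)
    expect_equal(ncol(fm$values), (k + 1) * 192)
    expect_equal(nrow(fm$values), 6 - k)
    expect_identical(fm$labels, ws$labels[(k + 1):6])
  }
  expect_error(featurize(ws, "mazilu", 2), "fft")
})
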
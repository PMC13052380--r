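test_that("brick-wall low-pass passes DC and in-band tones, removes out-of-band tones", {
  rate <- 60
  t <- (0:599) / rate
  dc <- scalar_trace(rep(9.81, 600), rate, "raw-norm")
  expect_equal(lowpass_fft(dc)$values, rep(9.81, 600), tolerance = 1e-12)

  # whole number of periods so the tones sit exactly on FFT bins
  hi <- scalar_trace(sin(2 * pi * 20 * t), rate, "raw-norm")
  expect_lt(max(abs(lowpass_fft(hi)$values)), 1e-9)

  lo <- sin(2 * pi * 2 * t)
  mix <- scalar_trace(lo + 0.7 * sin(2 * pi * 20 * t), rate, "raw-norm")
  expect_equal(lowpass_fft(mix)$values, lo, tolerance = 1e-9)
})

test_that("low-pass filtering is idempotent and validates its cutoff", {
  set.seed(4)
  s <- scalar_trace(rnorm(400), 60, "raw-norm")
  once <- lowpass_fft(s)
  twice <- lowpass_fft(once)
  expect_equal(twice$values, once$values, tolerance = 1e-9)
  expect_error(lowpass_fft(s, cutoff = 30), "Nyquist")
  expect_error(lowpass_fft(s, cutoff = 40), "Nyquist")
})

test_that("triaxial norm matches brute force and is rotation invariant", {
  expect_equal(triaxial_norm(accel_trace(c(3, 0), c(4, 0), c(0, 1)))$values,
               c(5, 1))
  set.seed(11)
  n <- 200
  tr <- accel_trace(rnorm(n), rnorm(n), rnorm(n), 60)
  brute <- sapply(seq_len(n), function(i)
    sqrt(tr$ax[i]^2 + tr$ay[i]^2 + tr$az[i]^2))
  expect_equal(triaxial_norm(tr)$values, brute)
  R <- random_rotation()
  rot <- t(R %*% rbind(tr$ax, tr$ay, tr$az))
  tr2 <- accel_trace(rot[, 1], rot[, 2], rot[, 3], 60)
  expect_equal(triaxial_norm(tr2)$values, triaxial_norm(tr)$values,
               tolerance = 1e-12)
})

test_that("dynamic component subtracts gravity only in the gravity-included dialect", {
  g <- 9.80665
  s <- scalar_trace(c(rep(g, 10), rep(g + 1.5, 10)), 60, "filtered")
  inc <- dynamic_component(s, "gravity-included")
  expect_equal(inc$values, c(rep(0, 10), rep(1.5, 10)))
  exc <- dynamic_component(s, "gravity-excluded")
  expect_equal(exc$values, s$values)
  expect_identical(inc$provenance, "dynamic")
  expect_error(dynamic_component(s, "no-such-dialect"), "dialect")
  raw <- scalar_trace(rep(g, 5), 60, "raw-norm")
  expect_error(dynamic_component(raw, "gravity-included"), "filtered")
})

test_that("linear resampling is exact on ramps and accurate on slow sinusoids", {
  rate <- 60
  ramp <- scalar_trace(seq(0, 5, length.out = 121), rate, "raw-norm")
  same <- resample_linear(ramp, rate)
  expect_equal(same$values, ramp$values)
  up <- resample_linear(ramp, 250)
  t_up <- (seq_along(up$values) - 1) / 250
  expect_equal(up$values, t_up * (5 / 2), tolerance = 1e-12)

  t <- (0:2000) / 1000
  sine <- scalar_trace(sin(2 * pi * 3 * t), 1000, "raw-norm")
  down <- resample_linear(sine, 60)
  t60 <- (seq_along(down$values) - 1) / 60
  # linear interpolation error bound ~ (2*pi*f)^2 * h^2 / 8 on the source grid
  expect_lt(max(abs(down$values - sin(2 * pi * 3 * t60))), 1e-4)
})

test_that("cross-correlation alignment recovers known shifts", {
  set.seed(21)
  base <- cumsum(rnorm(300))  # aperiodic
  a <- scalar_trace(base, 60, "dynamic")
  expect_identical(align_by_crosscorrelation(a, a)$lag_samples, 0L)

  for (k in c(-7L, 5L, 23L)) {
    shifted <- if (k > 0) c(rep(base[1], k), base[1:(300 - k)])
               else c(base[(-k + 1):300], rep(base[300], -k))
    b <- scalar_trace(shifted, 60, "dynamic")
    got <- align_by_crosscorrelation(a, b)
    # exhaustive oracle over the same window
    ks <- -120:120
    ors <- sapply(ks, function(kk) {
      if (kk >= 0) suppressWarnings(cor(base[1:(300 - kk)], shifted[(1 + kk):300]))
      else suppressWarnings(cor(base[(1 - kk):300], shifted[1:(300 + kk)]))
    })
    expect_identical(got$lag_samples, k)
    expect_equal(got$correlation, max(ors, na.rm = TRUE), tolerance = 1e-12)
  }

  b_off <- scalar_trace(base + 3.7, 60, "dynamic")
  expect_identical(align_by_crosscorrelation(a, b_off)$lag_samples, 0L)
  flat <- scalar_trace(rep(1, 300), 60, "dynamic")
  expect_error(align_by_crosscorrelation(a, flat), "zero-variance")
})

test_that("movement-phase extraction slices onset through stabilization inclusive", {
  s <- scalar_trace(seq_len(200), 60, "dynamic")
  f <- list(onset_index = 30, stabilization_index = 120)
  seg <- extract_movement_phase(s, f)
  expect_length(seg$values, 91)
  expect_equal(seg$values, 30:120)
  one <- extract_movement_phase(s, list(onset_index = 50, stabilization_index = 50))
  expect_length(one$values, 1)
  expect_error(extract_movement_phase(s, list(onset_index = 0,
                                              stabilization_index = 10)),
               "out of range")
})
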
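make_dyn <- function(values, rate = 60) scalar_trace(values, rate, "dynamic")

test_that("onset detection finds the pre-peak minimum with earliest-tie rule", {
  v <- rep(0, 200)
  v[30] <- -0.8          # dip
  v[60] <- 2.0           # peak
  expect_identical(detect_onset(make_dyn(v)), 30L)

  inc <- make_dyn(seq(0, 1, length.out = 50))
  expect_identical(detect_onset(inc), 1L)   # minimum at recording start

  tie <- rep(0, 100); tie[c(20, 40)] <- -0.5; tie[70] <- 1
  expect_identical(detect_onset(make_dyn(tie)), 20L)

  dec <- make_dyn(seq(1, 0, length.out = 50))
  expect_error(detect_onset(dec), "no rise")
})

test_that("peak detection takes the post-onset maximum with earliest-tie rule", {
  v <- c(rep(0, 30), seq(0, 1.5, length.out = 31), seq(1.5, 0, length.out = 30))
  pk <- detect_peak(make_dyn(v), 30L)
  expect_identical(pk$peak_index, 61L)
  expect_equal(pk$peak_accel, 1.5)

  tie <- rep(0, 100); tie[c(50, 60)] <- 2
  expect_identical(detect_peak(make_dyn(tie), 10L)$peak_index, 50L)
  expect_error(detect_peak(make_dyn(rep(0, 10)), 10L), "final sample")
})

test_that("stabilization uses the trailing-window range against 1% of g", {
  g <- 9.80665
  # constant after the peak: first index where the 12-sample window fits
  v <- c(rep(0, 10), 2, rep(0.1, 100))
  st <- detect_stabilization(make_dyn(v), 11L, window = 0.2)
  expect_identical(st$stabilization_index, 11L + 12L)
  expect_true(st$stabilized)

  # decaying oscillation: compare against a direct scan of the clean signal
  t <- (0:299) / 60
  osc <- 2 * exp(-t / 0.4) * cos(2 * pi * 3 * t)
  sig <- make_dyn(c(rep(0, 5), 2.2, osc))
  st2 <- detect_stabilization(sig, 6L, window = 0.2)
  w <- 12
  ranges <- sapply((6 + w):length(sig$values), function(i) {
    seg <- sig$values[(i - w + 1):i]; max(seg) - min(seg)
  })
  oracle <- (6 + w - 1) + which(ranges <= 0.01 * g)[1]
  expect_identical(st2$stabilization_index, as.integer(oracle))

  # sustained oscillation never stabilizes
  sus <- make_dyn(c(rep(0, 5), 2.2, 0.5 * cos(2 * pi * 3 * t)))
  st3 <- detect_stabilization(sus, 6L, window = 0.2)
  expect_false(st3$stabilized)
  expect_identical(st3$stabilization_index, length(sus$values))

  expect_error(detect_stabilization(make_dyn(rep(0, 20)), 15L, window = 0.2),
               "shorter than")
})

test_that("feature extraction composes the chain and satisfies the invariants", {
  g <- clean_trace(peak_force = 90, weight = 60, seed = 3)
  f <- extract_sts_features(g$trace, 60)
  expect_true(f$valid)
  expect_lte(f$onset_index, f$peak_index)
  expect_lte(f$peak_index, f$stabilization_index)
  expect_equal(f$T1, (f$peak_index - f$onset_index) / 60)
  expect_equal(f$T2, (f$stabilization_index - f$peak_index) / 60)
  expect_equal(f$peak_force, f$peak_accel * 60)

  # arithmetic of the definitions
  ff <- sts_features(31, 61, 151, 60, peak_accel = 1.5, weight_kg = 60)
  expect_equal(ff$T1, 0.5)
  expect_equal(ff$T2, 1.5)
  expect_equal(ff$peak_force, 90)
  expect_error(sts_features(61, 31, 151, 60, 1.5, 60), "ordering")
})

test_that("peak force scales linearly in body weight at fixed trace", {
  g <- clean_trace(peak_force = 100, weight = 50, seed = 9)
  f1 <- extract_sts_features(g$trace, 50)
  f2 <- extract_sts_features(g$trace, 100)
  expect_equal(f2$peak_force, 2 * f1$peak_force, tolerance = 1e-12)
  expect_identical(f1$peak_index, f2$peak_index)
  expect_error(extract_sts_features(g$trace, -1), "positive")
})

test_that("trial averaging means the measures and degrades gracefully", {
  a <- sts_features(30, 60, 150, 60, peak_accel = 80 / 60, weight_kg = 60)
  b <- sts_features(32, 68, 140, 60, peak_accel = 100 / 60, weight_kg = 60)
  avg <- average_trials(a, b)
  expect_equal(avg$peak_force, 90)
  expect_equal(avg$T1, mean(c(0.5, 0.6)))
  expect_false(avg$degraded)

  same <- average_trials(a, a)
  expect_equal(same$peak_force, a$peak_force)

  bad <- a; bad$valid <- FALSE
  one <- average_trials(bad, b)
  expect_true(one$degraded)
  expect_equal(one$peak_force, b$peak_force)
  none <- average_trials(bad, bad)
  expect_false(none$valid)
})
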
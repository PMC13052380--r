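test_that("generator configuration enforces its invariants", {
  expect_error(generator_config(sarcopenia_target_prevalence = 0), "strictly in")
  expect_error(generator_config(frailty_target_prevalence = 1.2), "strictly in")
  expect_error(generator_config(sampling_rate = 12), "15 Hz")
  expect_error(generator_config(trace_noise_sd = -0.1), ">= 0")
  expect_error(generator_config(n_subjects = 1), ">= 2")
  expect_error(generator_config(trace_noise_sd = NaN), "finite")
})

test_that("cohorts have the configured size, sex split and conditional moments", {
  cfg <- generator_config(n_subjects = 4000, calibration_n = 2000)
  co <- generate_cohort(cfg, seed = 91)
  expect_identical(nrow(co), 4000L)
  expect_lt(abs(mean(co$sex == "male") - 223 / 587), 0.03)

  # measures track the drawn-status conditional means (consistency
  # conditioning perturbs them mildly)
  tg <- cohort_targets()$sarcopenia$peak_force
  s <- co$sarcopenia_true
  expect_equal(mean(co$peak_force_true[s]), tg$case[1], tolerance = 0.06)
  expect_equal(mean(co$peak_force_true[!s]), tg$control[1], tolerance = 0.06)
  expect_equal(mean(co$age[s]) - mean(co$age[!s]), 4, tolerance = 0.4)
})

test_that("without consistency conditioning the drawn-status moments are exact", {
  cfg <- generator_config(n_subjects = 6000, enforce_consistency = FALSE,
                          calibration_n = 2000)
  co <- generate_cohort(cfg, seed = 95)
  # standardized mean difference of peak force between drawn status groups:
  # oracle is the closed form from the configured means/SDs
  tg <- cohort_targets()$sarcopenia$peak_force
  smd_oracle <- (tg$control[1] - tg$case[1]) /
    sqrt((tg$control[2]^2 + tg$case[2]^2) / 2)
  s <- co$sarcopenia_true
  nf <- !co$frail_true   # frail shift would bias the conditional means
  smd <- (mean(co$peak_force_true[!s & nf]) - mean(co$peak_force_true[s & nf])) /
    sqrt((var(co$peak_force_true[!s & nf]) + var(co$peak_force_true[s & nf])) / 2)
  expect_equal(smd, smd_oracle, tolerance = 0.08)
  expect_equal(mean(co$peak_force_true[s & nf]), tg$case[1], tolerance = 0.03)
  expect_equal(sd(co$peak_force_true[!s & nf]), tg$control[2], tolerance = 0.05)
})

test_that("classifier-emergent prevalence calibrates to the targets", {
  co <- generate_cohort(generator_config(n_subjects = 4000,
                                         calibration_n = 2000), seed = 92)
  # within two percentage points of the configured targets
  expect_lt(abs(mean(classify_sarcopenia(co)) - 95 / 569), 0.02)
  expect_lt(abs(mean(classify_frailty(co)$frail) - 51 / 569), 0.02)
})

test_that("without consistency enforcement a no-signal profile carries no signal", {
  prof <- default_effect_profile()
  for (v in unique(prof$variable)) {
    for (sx in unique(prof$sex[prof$variable == v])) {
      ctrl <- prof$mean[prof$variable == v & prof$sex == sx &
                          prof$status == "control"]
      prof[prof$variable == v & prof$sex == sx, "mean"] <- ctrl
      ctrl_sd <- prof$sd[prof$variable == v & prof$sex == sx &
                           prof$status == "control"]
      prof[prof$variable == v & prof$sex == sx, "sd"] <- ctrl_sd
    }
  }
  cfg <- generator_config(n_subjects = 3000, effect_profile = prof,
                          enforce_consistency = FALSE,
                          frail_shift = list(grip = 0, walking_speed = 0,
                                             peak_force = 0, age = 0),
                          calibration_n = 1500)
  co <- generate_cohort(cfg, seed = 93)
  s <- co$sarcopenia_true
  for (v in c("peak_force_true", "grip", "walking_speed", "age"))
    expect_equal(auc_mann_whitney(co[[v]], s), 0.5, tolerance = 0.04)
})

test_that("trace ground truth is ordered and matches the T1 definition", {
  cfg <- generator_config()
  for (seed in 1:10) {
    T1 <- runif(1, 0.35, 0.9)
    g <- generate_sts_trace(runif(1, 50, 120), runif(1, 45, 80), cfg,
                            T1 = T1, T2 = runif(1, 0.9, 1.8), seed = seed)
    tr <- g$truth
    expect_lte(tr$onset_index, tr$peak_index)
    expect_lte(tr$peak_index, tr$stabilization_index)
    expect_gte(tr$true_T1, 0)
    expect_gte(tr$true_T2, 0)
    # realized truth satisfies the definitional identity exactly and tracks
    # the nominal rising time within band-limiting slack
    expect_equal(tr$true_T1, (tr$peak_index - tr$onset_index) / 60)
    expect_lte(abs(tr$peak_index - tr$onset_index - round(T1 * 60)), 2)
  }
  expect_error(generate_sts_trace(-5, 60, cfg), "positive")
  expect_error(generate_sts_trace(90, 60, cfg, duration = 3), "3-s hold")
})

test_that("a rising time of 0.5 s at 60 Hz spans 30 samples", {
  g <- clean_trace(T1 = 0.5)
  # the definitional identity: T1 * rate sample periods between the events
  expect_identical(as.integer(round(g$truth$true_T1 * 60)),
                   g$truth$peak_index - g$truth$onset_index)
  expect_equal(g$truth$true_T1, 0.5, tolerance = 2 / 60 / 0.5)
})

test_that("within-subject noise drives the trial-pair ICC across its range", {
  cfg0 <- generator_config(n_subjects = 200, within_subject_sd = 0,
                           calibration_n = 1500)
  co <- generate_cohort(cfg0, seed = 94)
  pair_forces <- function(cfg, co, seed) {
    t(vapply(seq_len(nrow(co)), function(i) {
      p <- generate_trial_pair(co[i, ], cfg, seed = seed + i)
      c(p[[1]]$truth$true_peak_force, p[[2]]$truth$true_peak_force)
    }, numeric(2)))
  }
  m0 <- pair_forces(cfg0, co, 500)
  expect_gt(icc_2_1(m0)$icc, 0.999)   # no trial noise: perfect agreement

  # no between-subject variance: ICC near zero
  co_flat <- co
  co_flat$peak_force_true <- 90
  cfg_w <- generator_config(n_subjects = 200, within_subject_sd = 8,
                            calibration_n = 1500)
  m_flat <- pair_forces(cfg_w, co_flat, 900)
  expect_lt(abs(icc_2_1(m_flat)$icc), 0.15)
})

test_that("high-rate reference recordings align back to their imposed lag", {
  g <- clean_trace(seed = 42)
  ref <- generate_reference_pair(g$trace, ref_rate = 1000, lag = 0,
                                 noise_sd = 0, seed = 1)
  a <- resample_linear(triaxial_norm(g$trace), 1000)
  b <- triaxial_norm(ref)
  expect_identical(align_by_crosscorrelation(a, b)$lag_samples, 0L)

  ref2 <- generate_reference_pair(g$trace, ref_rate = 1000, lag = 0.1,
                                  noise_sd = 0, seed = 1)
  lag2 <- align_by_crosscorrelation(a, triaxial_norm(ref2))$lag
  expect_lt(abs(lag2 - 0.1), 1 / 60)
  expect_error(generate_reference_pair(g$trace, lag = 100), "duration")
  expect_error(generate_reference_pair(g$trace, ref_rate = 30), "exceed")
})

test_that("cohort generation is deterministic in the seed", {
  cfg <- test_config()
  c1 <- generate_cohort(cfg, seed = 5)
  c2 <- generate_cohort(cfg, seed = 5)
  c3 <- generate_cohort(cfg, seed = 6)
  expect_identical(c1, c2)
  expect_false(identical(c1$grip, c3$grip))
})
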
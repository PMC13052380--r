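#' Generator configuration
#'
#' Settings for the synthetic cohort and trace generator. Defaults emulate
#' the published study conditions: 569 completers, sarcopenia and frailty
#' prevalences of 95/569 and 51/569, a 223/364 male/female split, 60 Hz
#' smartphone sampling, the status-conditional effect profile of
#' \code{\link{default_effect_profile}}, and a trial-pair peak-force
#' reliability target of ICC(2,1) = 0.863.
#'
#' If \code{within_subject_sd} is \code{NULL} it is derived from
#' \code{target_reliability}: with between-subject peak-force variance
#' \eqn{\sigma_b^2} implied by the status mixture of the effect profile, the
#' population ICC of a trial pair is
#' \eqn{\sigma_b^2 / (\sigma_b^2 + \sigma_w^2)}, so
#' \eqn{\sigma_w = \sigma_b \sqrt{1/\mathrm{ICC} - 1}}.
#'
#' @param n_subjects number of participants (>= 2).
#' @param sarcopenia_target_prevalence,frailty_target_prevalence target
#'   emergent prevalences in (0,1) under the classification criteria.
#' @param sampling_rate trace sampling rate in Hz (> 15, i.e. Nyquist above
#'   the 7.5 Hz filter cutoff).
#' @param trace_noise_sd per-axis additive Gaussian noise SD on traces
#'   (m/s^2).
#' @param within_subject_sd trial-to-trial SD of peak force (N), or
#'   \code{NULL} to derive from \code{target_reliability}.
#' @param target_reliability population ICC(2,1) targeted for trial-pair peak
#'   force when \code{within_subject_sd} is \code{NULL}.
#' @param effect_profile status-conditional means/SDs and latent-factor
#'   loadings (see \code{\link{default_effect_profile}}).
#' @param prop_male probability a participant is male.
#' @param status_correlation correlation of the sarcopenia and frailty latent
#'   liabilities.
#' @param frail_shift additive shifts applied to measures of frail subjects.
#' @param component_probs probabilities of the three self-report frailty
#'   flags conditional on frailty status (derived from the published
#'   component counts).
#' @param dialect gravity dialect emitted for traces.
#' @param hf_noise_amp amplitude (m/s^2) of an above-cutoff (17 Hz)
#'   sinusoidal component added to traces to exercise the filter.
#' @param T1_mean,T1_sd,T2_mean,T2_sd between-subject distribution of the
#'   latent rising and stability times (s).
#' @param T1_within_sd,T2_within_sd trial-to-trial SDs of T1 and T2 (s);
#'   large relative to the between-subject SDs, reflecting the low observed
#'   reproducibility of the temporal measures.
#' @param calibration_n Monte-Carlo sample size of the prevalence
#'   calibration search.
#' @param enforce_consistency redraw a subject's measures until the
#'   classification criteria reproduce the drawn statuses (default TRUE).
#'   The published status-conditional moments are conditional on classified
#'   status, so consistency keeps the emulated conditional distributions
#'   faithful for variables outside the classifiers (age, peak force);
#'   turning it off yields the pure status-mixture model, in which the
#'   calibration search alone matches the target prevalence.
#' @return a list of class \code{generator_config}.
#' @export
generator_config <- function(n_subjects = 569,
                             sarcopenia_target_prevalence = 95 / 569,
                             frailty_target_prevalence = 51 / 569,
                             sampling_rate = 60,
                             trace_noise_sd = 0.05,
                             within_subject_sd = NULL,
                             target_reliability = 0.863,
                             effect_profile = default_effect_profile(),
                             prop_male = 223 / 587,
                             status_correlation = 0.3,
                             frail_shift = list(grip = -4, walking_speed = -0.25,
                                                peak_force = -10, age = 3),
                             component_probs = list(
                               frail = c(weight_loss = 33 / 51,
                                         exhaustion = 46 / 51,
                                         low_activity = 25 / 51),
                               nonfrail = c(weight_loss = 59 / 536,
                                            exhaustion = 127 / 536,
                                            low_activity = 77 / 536)),
                             dialect = "gravity-included",
                             hf_noise_amp = 0.05,
                             T1_mean = 0.55, T1_sd = 0.05,
                             T2_mean = 1.30, T2_sd = 0.15,
                             T1_within_sd = 0.08, T2_within_sd = 0.20,
                             calibration_n = 4000,
                             enforce_consistency = TRUE) {
  cfg <- list(n_subjects = as.integer(n_subjects),
              sarcopenia_target_prevalence = sarcopenia_target_prevalence,
              frailty_target_prevalence = frailty_target_prevalence,
              sampling_rate = sampling_rate,
              trace_noise_sd = trace_noise_sd,
              within_subject_sd = within_subject_sd,
              target_reliability = target_reliability,
              effect_profile = effect_profile,
              prop_male = prop_male,
              status_correlation = status_correlation,
              frail_shift = frail_shift,
              component_probs = component_probs,
              dialect = dialect,
              hf_noise_amp = hf_noise_amp,
              T1_mean = T1_mean, T1_sd = T1_sd,
              T2_mean = T2_mean, T2_sd = T2_sd,
              T1_within_sd = T1_within_sd, T2_within_sd = T2_within_sd,
              calibration_n = as.integer(calibration_n),
              enforce_consistency = isTRUE(enforce_consistency))
  validate_generator_config(cfg)
  if (is.null(cfg$within_subject_sd)) {
    if (cfg$target_reliability <= 0 || cfg$target_reliability > 1)
      stop_invalid("target_reliability must lie in (0, 1]")
    sb <- between_subject_force_sd(cfg)
    cfg$within_subject_sd <-
      if (cfg$target_reliability == 1) 0
      else sb * sqrt(1 / cfg$target_reliability - 1)
  }
  class(cfg) <- "generator_config"
  cfg
}

# Between-subject SD of latent peak force in the generated population. Under
# classifier-consistency the conditional draws are truncated, so the SD is
# measured empirically on a fixed-seed calibration cohort (global RNG state
# is preserved); without consistency the closed-form status mixture applies.
between_subject_force_sd <- function(cfg) {
  if (!isTRUE(cfg$enforce_consistency)) return(mixture_force_sd(cfg))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(201706L)
  cfg2 <- cfg
  cfg2$within_subject_sd <- 0
  class(cfg2) <- "generator_config"
  cal <- draw_cohort_core(cfg$calibration_n,
                          cfg$sarcopenia_target_prevalence,
                          cfg$frailty_target_prevalence, cfg2)
  stats::sd(cal$peak_force_true)
}

validate_generator_config <- function(cfg) {
  num_fields <- c("sarcopenia_target_prevalence", "frailty_target_prevalence",
                  "sampling_rate", "trace_noise_sd", "prop_male",
                  "status_correlation", "hf_noise_amp",
                  "T1_mean", "T1_sd", "T2_mean", "T2_sd",
                  "T1_within_sd", "T2_within_sd")
  for (f in num_fields)
    if (!is.numeric(cfg[[f]]) || !all(is.finite(cfg[[f]])))
      stop_invalid("config field '%s' must be finite numeric", f)
  for (p in c("sarcopenia_target_prevalence", "frailty_target_prevalence"))
    if (cfg[[p]] <= 0 || cfg[[p]] >= 1)
      stop_invalid("%s must lie strictly in (0, 1)", p)
  if (cfg$sampling_rate <= 15)
    stop_invalid("sampling_rate must exceed 15 Hz (Nyquist above the 7.5 Hz cutoff)")
  sds <- c(cfg$trace_noise_sd, cfg$T1_sd, cfg$T2_sd, cfg$T1_within_sd,
           cfg$T2_within_sd, cfg$effect_profile$sd)
  if (!is.null(cfg$within_subject_sd)) sds <- c(sds, cfg$within_subject_sd)
  if (any(!is.finite(sds)) || any(sds < 0))
    stop_invalid("all SDs must be finite and >= 0")
  if (cfg$n_subjects < 2L) stop_invalid("n_subjects must be >= 2")
  invisible(TRUE)
}

# Between-subject SD of latent peak force implied by the status mixture.
mixture_force_sd <- function(cfg) {
  p <- cfg$sarcopenia_target_prevalence
  ctrl <- profile_cell(cfg$effect_profile, "peak_force", "any", "control")
  case <- profile_cell(cfg$effect_profile, "peak_force", "any", "case")
  v <- (1 - p) * ctrl$sd^2 + p * case$sd^2 +
    p * (1 - p) * (ctrl$mean - case$mean)^2
  sqrt(v)
}

profile_cell <- function(profile, variable, sex, status) {
  i <- which(profile$variable == variable &
               (profile$sex == sex | profile$sex == "any") &
               profile$status == status)
  if (length(i) == 0)
    stop_invalid("effect profile has no cell for %s/%s/%s", variable, sex, status)
  list(mean = profile$mean[i[1]], sd = profile$sd[i[1]],
       loading = profile$loading[i[1]])
}

# Vectorized status-conditional draw of one variable for n subjects sharing a
# latent "function" factor ff.
draw_variable <- function(variable, sex, s_case, ff, profile) {
  n <- length(sex)
  mu <- sd <- lam <- numeric(n)
  for (sx in c("male", "female")) {
    for (st in c("control", "case")) {
      idx <- sex == sx & (s_case == (st == "case"))
      if (!any(idx)) next
      cell <- profile_cell(profile, variable, sx, st)
      mu[idx] <- cell$mean; sd[idx] <- cell$sd; lam[idx] <- cell$loading
    }
  }
  # low function factor should depress grip/speed/smi/force, so enter with +lam
  mu + sd * (lam * ff + sqrt(1 - lam^2) * stats::rnorm(n))
}

#' Generate a synthetic cohort
#'
#' Draws a status-first synthetic cohort: correlated sarcopenia and frailty
#' latent liabilities are thresholded to give generative statuses, continuous
#' measures are drawn from status-conditional normals of the effect profile
#' (co-moving through a shared latent function factor), self-report frailty
#' flags are drawn with status-conditional probabilities, and frail subjects'
#' measures receive the configured shifts. Because classification operates on
#' the drawn measures, the classifier-emergent prevalence differs from the
#' drawn-status rate; the draw rates are therefore calibrated beforehand by a
#' one-dimensional Monte-Carlo search (see Details).
#'
#' @details Calibration: the emergent prevalence is linear in the draw rate q
#' (\eqn{p(q) = q a + (1-q) b} with a, b the classification rates among drawn
#' cases and controls), so the search estimates a and b from a simulated
#' calibration sample and solves for q, iterating three times to absorb the
#' mild coupling between the two outcomes. When the profile carries
#' essentially no signal (a close to b) the draw rate falls back to the
#' target itself.
#'
#' @param config a \code{\link{generator_config}}.
#' @param seed integer seed; all randomness in the cohort derives from it.
#' @return data frame with one row per participant: demographics,
#'   anthropometrics, measures, self-report flags, latent trace parameters
#'   (\code{peak_force_true}, \code{T1_true}, \code{T2_true}) and generative
#'   statuses (\code{sarcopenia_true}, \code{frail_true}). Calibrated draw
#'   rates are attached as attribute \code{"draw_rates"}.
#' @export
generate_cohort <- function(config = generator_config(), seed = 1) {
  stopifnot(inherits(config, "generator_config"))
  rates <- calibrate_draw_rates(config, seed = child_seed(seed, 1))
  set.seed(child_seed(seed, 2))
  cohort <- draw_cohort_core(config$n_subjects, rates$q_s, rates$q_f, config)
  cohort$id <- sprintf("S%04d", seq_len(nrow(cohort)))
  cohort <- cohort[, c("id", setdiff(names(cohort), "id"))]
  attr(cohort, "draw_rates") <- rates
  cohort
}

# Status-conditional draw of all measures and flags for subjects with the
# given sex and statuses; assumes the RNG is already seeded.
draw_measures_block <- function(sex, s_case, f_case, config) {
  n <- length(sex)
  ff <- stats::rnorm(n)  # shared latent function factor (higher = fitter)
  prof <- config$effect_profile
  grip <- draw_variable("grip", sex, s_case, ff, prof)
  smi <- draw_variable("smi", sex, s_case, ff, prof)
  speed <- draw_variable("walking_speed", sex, s_case, ff, prof)
  force <- draw_variable("peak_force", sex, s_case, ff, prof)
  age <- draw_variable("age", sex, s_case, ff, prof)
  height <- draw_variable("height", sex, s_case, ff, prof)
  weight <- draw_variable("weight", sex, s_case, ff, prof)
  sh <- config$frail_shift
  grip[f_case] <- grip[f_case] + sh$grip
  speed[f_case] <- speed[f_case] + sh$walking_speed
  force[f_case] <- force[f_case] + sh$peak_force
  age[f_case] <- age[f_case] + sh$age
  # physiological floors
  grip <- pmax(grip, 2); smi <- pmax(smi, 2.5)
  speed <- pmax(speed, 0.2); force <- pmax(force, 20)
  age <- pmax(age, 65); height <- pmax(height, 130); weight <- pmax(weight, 30)
  pr <- config$component_probs
  flag <- function(comp) {
    p <- ifelse(f_case, pr$frail[[comp]], pr$nonfrail[[comp]])
    stats::runif(n) < p
  }
  t1 <- pmin(pmax(stats::rnorm(n, config$T1_mean + 0.04 * s_case, config$T1_sd),
                  0.30), 1.20)
  t2 <- pmin(pmax(stats::rnorm(n, config$T2_mean + 0.10 * s_case, config$T2_sd),
                  0.60), 2.50)
  data.frame(
    age = age, sex = sex, height = height, weight = weight,
    grip = grip, walking_speed = speed,
    smi = smi, asm = smi * (height / 100)^2,
    weight_loss = flag("weight_loss"), exhaustion = flag("exhaustion"),
    low_activity = flag("low_activity"),
    peak_force_true = force, T1_true = t1, T2_true = t2,
    sarcopenia_true = s_case, frail_true = f_case
  )
}

# Core cohort draw at given draw rates; assumes the RNG is already seeded.
# With enforce_consistency, measures of subjects whose classifier labels
# disagree with their drawn statuses are redrawn (rejection sampling), so the
# published status-conditional moments hold conditional on the CLASSIFIED
# groups, as they do in the source tables.
draw_cohort_core <- function(n, q_s, q_f, config) {
  sex <- ifelse(stats::runif(n) < config$prop_male, "male", "female")
  l_s <- stats::rnorm(n)
  rho <- config$status_correlation
  l_f <- rho * l_s + sqrt(1 - rho^2) * stats::rnorm(n)
  s_case <- l_s > stats::qnorm(1 - q_s)
  f_case <- l_f > stats::qnorm(1 - q_f)
  out <- draw_measures_block(sex, s_case, f_case, config)
  if (isTRUE(config$enforce_consistency)) {
    for (iter in 1:50) {
      cls <- classify_cohort_rates(out)
      bad <- which(cls$sar != out$sarcopenia_true | cls$fr != out$frail_true)
      if (length(bad) == 0) break
      out[bad, ] <- draw_measures_block(sex[bad], s_case[bad], f_case[bad],
                                        config)
    }
  }
  out
}

classify_cohort_rates <- function(cohort) {
  sar <- classify_sarcopenia(cohort)
  fr <- classify_frailty(cohort)$frail
  list(sar = sar, fr = fr)
}

# One-dimensional calibration of the status draw rates so the
# classifier-emergent prevalences hit the configured targets.
calibrate_draw_rates <- function(config, seed = 1) {
  t_s <- config$sarcopenia_target_prevalence
  t_f <- config$frailty_target_prevalence
  q_s <- t_s; q_f <- t_f
  n_cal <- config$calibration_n
  clip <- function(x) pmin(pmax(x, 1e-4), 1 - 1e-4)
  for (it in 1:3) {
    set.seed(child_seed(seed, it))
    cal <- draw_cohort_core(n_cal, q_s, q_f, config)
    cls <- classify_cohort_rates(cal)
    # conditional classification rates given drawn status
    solve_q <- function(cls_flag, drawn, target, q_old) {
      a <- mean(cls_flag[drawn]); b <- mean(cls_flag[!drawn])
      # below ~5 points of separation the linear solve is dominated by
      # Monte-Carlo noise; treat the profile as uninformative
      if (!is.finite(a) || !is.finite(b) || (a - b) < 0.05) return(q_old)
      clip((target - b) / (a - b))
    }
    q_s <- solve_q(cls$sar, cal$sarcopenia_true, t_s, q_s)
    q_f <- solve_q(cls$fr, cal$frail_true, t_f, q_f)
  }
  list(q_s = q_s, q_f = q_f)
}

# Smooth dynamic acceleration template d(t) of one sit-to-stand transition:
# quiet sit, half-cosine unweighting dip (minimum -A_neg at onset), cosine
# rise to A_peak over T1, then an exponentially decaying cosine oscillation.
sts_template <- function(t, onset_t, T1, A_peak, A_neg, dip_dur = 0.3,
                         osc_freq = 2.5, tau) {
  d <- numeric(length(t))
  peak_t <- onset_t + T1
  dip0 <- onset_t - dip_dur
  i <- t >= dip0 & t < onset_t
  d[i] <- -A_neg * (1 - cos(pi * (t[i] - dip0) / dip_dur)) / 2
  i <- t >= onset_t & t <= peak_t
  d[i] <- -A_neg + (A_peak + A_neg) * (1 - cos(pi * (t[i] - onset_t) / T1)) / 2
  i <- t > peak_t
  x <- (t[i] - peak_t) / tau
  # (1 + x) e^-x envelope: zero slope at the peak, so the rise joins the
  # decay C1-continuously
  d[i] <- A_peak * (1 + x) * exp(-x) * cos(2 * pi * osc_freq * (t[i] - peak_t))
  d
}

#' Generate one synthetic sit-to-stand trace
#'
#' Builds a phenomenological raw triaxial trace for a single transition:
#' quiet sitting, a negative unweighting lobe whose minimum defines the true
#' onset, a smooth rise peaking at \code{peak_force / weight_kg}, a decaying
#' oscillation whose amplitude crossing of the 1%-of-g criterion defines the
#' true stabilization, and quiet stance held beyond 3 s after the peak. The
#' movement axis is vertical in the world frame; the emitted device axes are
#' an arbitrary rigid rotation of the world frame, with gravity included or
#' excluded per the configured dialect, plus per-axis Gaussian noise and an
#' optional above-cutoff sinusoid.
#'
#' Ground-truth indices are computed by applying the definitional event rules
#' to the clean, unfiltered dynamic template of the trace's dialect, so they
#' are independent of the detection pipeline's filtering.
#'
#' @param peak_force true peak force in N (> 0).
#' @param weight_kg body mass in kg (> 0).
#' @param config a \code{\link{generator_config}} (supplies sampling rate,
#'   noise, dialect).
#' @param T1,T2 nominal rising and stability times in s.
#' @param rotation either \code{NULL} (random rotation), a numeric vector
#'   \code{c(yaw, pitch, roll)} in radians, or a 3x3 rotation matrix.
#' @param noise_sd,hf_amp,dialect overrides of the config values.
#' @param duration optional total duration in s; must leave at least 3 s
#'   after the peak. Defaults to an automatic value that does.
#' @param stab_window trailing window (s) used when computing the
#'   ground-truth stabilization index.
#' @param seed optional integer seed.
#' @return list with elements \code{trace} (an \code{\link{accel_trace}})
#'   and \code{truth} (onset/peak/stabilization indices, true peak
#'   acceleration and force, true T1 and T2).
#' @export
generate_sts_trace <- function(peak_force, weight_kg,
                               config = generator_config(),
                               T1 = config$T1_mean, T2 = config$T2_mean,
                               rotation = NULL,
                               noise_sd = config$trace_noise_sd,
                               hf_amp = config$hf_noise_amp,
                               dialect = config$dialect,
                               duration = NULL,
                               stab_window = 0.2,
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (!is.finite(weight_kg) || weight_kg <= 0) stop_invalid("weight_kg must be positive")
  A_peak <- peak_force / weight_kg
  if (!is.finite(A_peak) || A_peak <= 0)
    stop_invalid("true peak acceleration must be positive (peak_force %g N, weight %g kg)",
                 peak_force, weight_kg)
  rate <- config$sampling_rate
  onset_idx0 <- as.integer(round(1.3 * rate))
  onset_t <- onset_idx0 / rate
  peak_idx0 <- onset_idx0 + max(1L, as.integer(round(T1 * rate)))
  peak_t <- peak_idx0 / rate
  T1_snap <- peak_t - onset_t
  auto_dur <- peak_t + max(3.0, T2 + 1.5) + 0.3
  if (is.null(duration)) duration <- auto_dur
  if (duration < peak_t + 3.0)
    stop_invalid("trace duration %.2f s leaves less than the 3-s hold after the peak (%.2f s)",
                 duration, peak_t)
  n <- floor(duration * rate) + 1
  t <- (seq_len(n) - 1) / rate
  A_neg <- 0.3 * A_peak
  tau <- T2 / log(1.8 * A_peak / (0.01 * G_ACCEL))
  if (!is.finite(tau) || tau <= 0) tau <- T2 / 3
  d <- sts_template(t, onset_t, T1_snap, A_peak, A_neg, tau = tau)
  # Band-limit the clean template below the analysis cutoff so that the
  # emitted movement is free of above-band content by construction (the
  # phenomenological corners of the piecewise template are not physical).
  d <- lowpass_fft(scalar_trace(d, rate, "raw-norm"), cutoff = 7.0)$values
  # Ground truth: the definitional event rules applied to the clean dynamic
  # signal of the trace's dialect (the simulated motion itself). The nominal
  # T1/T2 arguments are template shape parameters; band-limiting can move
  # the realized extrema by a sample or two, and the realized values are
  # what the truth reports.
  clean <- if (dialect == "gravity-included") d else abs(d)
  tr_clean <- scalar_trace(clean, rate, "dynamic")
  onset <- detect_onset(tr_clean)
  pk <- detect_peak(tr_clean, onset)
  st <- detect_stabilization(tr_clean, pk$peak_index, window = stab_window)
  truth <- list(onset_index = onset,
                peak_index = pk$peak_index,
                stabilization_index = st$stabilization_index,
                stabilized = st$stabilized,
                true_peak_accel = pk$peak_accel,
                true_peak_force = pk$peak_accel * weight_kg,
                true_T1 = (pk$peak_index - onset) / rate,
                true_T2 = (st$stabilization_index - pk$peak_index) / rate)
  # emit device axes: world z carries the movement (+ gravity if included)
  d_emit <- d
  if (hf_amp > 0)
    d_emit <- d_emit + hf_amp * sin(2 * pi * 17 * t + stats::runif(1, 0, 2 * pi))
  wz <- if (dialect == "gravity-included") d_emit + G_ACCEL else d_emit
  R <- if (is.matrix(rotation)) rotation
       else if (is.numeric(rotation) && length(rotation) == 3)
         rotation_matrix(rotation[1], rotation[2], rotation[3])
       else rotation_matrix(stats::runif(1, -pi, pi),
                            stats::runif(1, -0.4, 0.4),
                            stats::runif(1, -0.4, 0.4))
  dev <- t(R) %*% rbind(0, 0, wz)
  if (noise_sd > 0) dev <- dev + matrix(stats::rnorm(3 * n, 0, noise_sd), 3)
  list(trace = accel_trace(dev[1, ], dev[2, ], dev[3, ], rate, dialect),
       truth = truth)
}

#' Generate a consecutive trial pair for one subject
#'
#' Two traces share the subject's latent peak force and latent T1/T2,
#' perturbed by trial-level (within-subject) noise:
#' \code{within_subject_sd} newtons for peak force and the configured
#' within-trial SDs for the temporal measures. The between/within variance
#' ratio thus sets the population trial-pair ICC.
#'
#' @param subject a list or one-row data frame with \code{peak_force_true},
#'   \code{weight}, \code{T1_true}, \code{T2_true}.
#' @param config a \code{\link{generator_config}}.
#' @param seed integer seed.
#' @return list of two \code{list(trace, truth)} elements.
#' @export
generate_trial_pair <- function(subject, config = generator_config(), seed = 1) {
  set.seed(seed)
  forces <- pmax(subject$peak_force_true +
                   stats::rnorm(2, 0, config$within_subject_sd), 15)
  t1s <- pmin(pmax(subject$T1_true + stats::rnorm(2, 0, config$T1_within_sd),
                   0.25), 1.4)
  t2s <- pmin(pmax(subject$T2_true + stats::rnorm(2, 0, config$T2_within_sd),
                   0.5), 2.8)
  lapply(1:2, function(i)
    generate_sts_trace(forces[i], subject$weight, config,
                       T1 = t1s[i], T2 = t2s[i],
                       seed = NULL))  # RNG continues from the pair seed
}

#' Generate a high-rate reference recording of a trace
#'
#' Produces the signal a research-grade reference accelerometer would record
#' of the same movement: the trace is linearly upsampled to \code{ref_rate},
#' time-shifted by \code{lag} (positive = reference delayed), and given
#' independent per-axis noise. Used to exercise cross-correlation alignment
#' and device-agreement waveform comparison.
#'
#' @param trace an \code{\link{accel_trace}} (e.g. a clean generated trace).
#' @param ref_rate reference sampling rate in Hz (> trace rate).
#' @param lag time shift in seconds; magnitude must be below the trace
#'   duration.
#' @param noise_sd per-axis Gaussian noise SD (m/s^2).
#' @param seed optional integer seed.
#' @return an \code{accel_trace} at \code{ref_rate}.
#' @export
generate_reference_pair <- function(trace, ref_rate = 1000, lag = 0,
                                    noise_sd = 0.02, seed = NULL) {
  stopifnot(inherits(trace, "accel_trace"))
  if (ref_rate <= trace$sampling_rate)
    stop_invalid("ref_rate must exceed the trace sampling rate")
  dur <- (length(trace$ax) - 1) / trace$sampling_rate
  if (abs(lag) >= dur)
    stop_invalid("lag (%.3f s) exceeds the trace duration (%.3f s)", lag, dur)
  if (!is.null(seed)) set.seed(seed)
  up <- function(v) {
    s <- scalar_trace(v, trace$sampling_rate, "raw-norm")
    resample_linear(s, ref_rate)$values
  }
  shift <- function(v) {
    k <- round(lag * ref_rate)
    n <- length(v)
    if (k > 0) c(rep(v[1], k), v[seq_len(n - k)])
    else if (k < 0) c(v[(-k + 1):n], rep(v[n], -k))
    else v
  }
  axes <- lapply(list(trace$ax, trace$ay, trace$az), function(v) {
    out <- shift(up(v))
    if (noise_sd > 0) out <- out + stats::rnorm(length(out), 0, noise_sd)
    out
  })
  accel_trace(axes[[1]], axes[[2]], axes[[3]], ref_rate, trace$dialect)
}
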
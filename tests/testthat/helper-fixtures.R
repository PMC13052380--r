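# Shared fixtures, built in code.

# Small, fast generator configuration for pipeline tests.
test_config <- function(...) {
  generator_config(n_subjects = 60, calibration_n = 1500, ...)
}

# Deterministic clean trace with known event structure.
clean_trace <- function(peak_force = 90, weight = 60, T1 = 0.5, T2 = 1.2,
                        dialect = "gravity-included", seed = 1, ...) {
  generate_sts_trace(peak_force, weight, generator_config(),
                     T1 = T1, T2 = T2, noise_sd = 0, hf_amp = 0,
                     dialect = dialect, seed = seed, ...)
}

# Random rotation matrix (QR of a Gaussian matrix, det +1).
random_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# Brute-force two-way mean squares via lm/anova: the independent ICC oracle.
icc_oracle <- function(m) {
  n <- nrow(m); k <- ncol(m)
  d <- data.frame(y = as.vector(m),
                  subj = factor(rep(seq_len(n), k)),
                  rater = factor(rep(seq_len(k), each = n)))
  a <- anova(lm(y ~ subj + rater, data = d))
  msr <- a["subj", "Mean Sq"]; msc <- a["rater", "Mean Sq"]
  mse <- a["Residuals", "Mean Sq"]
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}

# Exhaustive positive-negative pair count: the independent AUC oracle.
auc_oracle <- function(scores, labels) {
  y <- as.logical(labels)
  sp <- scores[y]; sn <- scores[!y]
  tot <- 0
  for (p in sp) tot <- tot + sum(p > sn) + 0.5 * sum(p == sn)
  tot / (length(sp) * length(sn))
}

# Small labelled cohort for model tests: one informative predictor plus
# noise, at a controllable separation.
model_test_data <- function(n = 300, delta = 1.5, seed = 1) {
  set.seed(seed)
  y <- rbinom(n, 1, 0.3)
  data.frame(
    y = y,
    signal = rnorm(n, mean = delta * y),
    noise1 = rnorm(n), noise2 = rnorm(n),
    sex = sample(c("male", "female"), n, replace = TRUE)
  )
}
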
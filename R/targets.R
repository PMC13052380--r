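#' Cohort summary counts and moments the generator emulates
#'
#' Published summary statistics of the community cohort of older adults that
#' the synthetic generator is calibrated to: assessment/completion counts,
#' classified sarcopenia and frailty counts, the sex split, frailty phenotype
#' component counts by frailty status, and status-conditional means/SDs of
#' the key continuous measures. These counts are also the inputs for the
#' exactly recomputable summary arithmetic (completion rate, prevalences,
#' component percentages).
#'
#' Note the two denominators in the source tables: 569 completers carry the
#' sarcopenia columns (474 + 95) while the frailty columns total 587
#' (536 + 51, the assessed sample). The completers (n = 569) are treated as
#' the analysis population; frailty prevalence is reported out of 569 and the
#' component percentages out of their published group sizes (536 / 51).
#'
#' @return a nested list of counts and moments.
#' @export
cohort_targets <- function() {
  list(
    n_assessed = 587L,
    n_completed = 569L,
    n_sarcopenia = 95L,
    n_frail = 51L,
    n_nonfrail = 536L,
    n_male = 223L,
    n_female = 364L,
    # component counts: frail (of 51) / non-frail (of 536)
    components = data.frame(
      component = c("slowness", "weight_loss", "exhaustion", "low_activity",
                    "weakness"),
      frail_n = c(16L, 33L, 46L, 25L, 44L),
      nonfrail_n = c(12L, 59L, 127L, 77L, 133L)
    ),
    # status-conditional moments (mean, sd) of the continuous measures
    sarcopenia = list(
      peak_force = list(case = c(70.87, 14.98), control = c(92.56, 25.20)),
      walking_speed = list(case = c(1.25, 0.22), control = c(1.40, 0.23)),
      grip = list(case = c(16, 5), control = c(26, 8)),
      smi = list(case = c(5.49, 0.74), control = c(6.66, 0.99)),
      age = list(case = c(77, 7), control = c(73, 6))
    ),
    frailty = list(
      peak_force = list(case = c(78.56, 20.49), control = c(89.93, 25.25)),
      walking_speed = list(case = c(1.13, 0.25), control = c(1.40, 0.23)),
      grip = list(case = c(19, 6), control = c(24, 8))
    )
  )
}

#' Default status-conditional effect profile of the generator
#'
#' Means and SDs of the continuous measures conditional on sarcopenia status,
#' by sex where the classification cutoffs are sex-specific. Grip strength
#' and SMI must be sex-stratified (the published pooled normals would place
#' most control men under the male SMI cutoff); the sex-by-status cells are
#' chosen so that their 38/62 male/female mixture reproduces the published
#' pooled means to within rounding. Peak force, walking speed and age are
#' sex-neutral, exactly matching the published status-conditional moments.
#' \code{loading} is each variable's loading on the shared latent "function"
#' factor that induces positive co-movement between strength, speed, muscle
#' mass and peak force within a subject.
#'
#' @return data frame with columns \code{variable}, \code{sex},
#'   \code{status} (case = sarcopenia), \code{mean}, \code{sd},
#'   \code{loading}.
#' @export
default_effect_profile <- function() {
  row <- function(variable, sex, status, mean, sd, loading) {
    data.frame(variable = variable, sex = sex, status = status,
               mean = mean, sd = sd, loading = loading)
  }
  rbind(
    row("grip", "male", "control", 30.0, 6.0, 0.5),
    row("grip", "male", "case", 20.0, 5.0, 0.5),
    row("grip", "female", "control", 23.1, 6.0, 0.5),
    row("grip", "female", "case", 14.6, 4.5, 0.5),
    row("smi", "male", "control", 7.60, 0.80, 0.4),
    row("smi", "male", "case", 6.30, 0.70, 0.4),
    row("smi", "female", "control", 6.08, 0.80, 0.4),
    row("smi", "female", "case", 5.20, 0.60, 0.4),
    row("walking_speed", "any", "control", 1.40, 0.23, 0.5),
    row("walking_speed", "any", "case", 1.25, 0.22, 0.5),
    row("peak_force", "any", "control", 92.56, 25.20, 0.5),
    row("peak_force", "any", "case", 70.87, 14.98, 0.5),
    row("age", "any", "control", 73, 6, 0.0),
    row("age", "any", "case", 77, 7, 0.0),
    row("height", "male", "control", 166.3, 6.5, 0.0),
    row("height", "male", "case", 161.5, 6.5, 0.0),
    row("height", "female", "control", 153.3, 5.8, 0.0),
    row("height", "female", "case", 149.5, 5.8, 0.0),
    row("weight", "male", "control", 66.0, 10.0, 0.2),
    row("weight", "male", "case", 56.0, 8.0, 0.2),
    row("weight", "female", "control", 53.0, 8.5, 0.2),
    row("weight", "female", "case", 45.5, 6.5, 0.2)
  )
}
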
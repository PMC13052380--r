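# AWGS2019 and J-CHS cutoffs. All comparisons are strict ("below" / "less
# than" / "slower than"); equality at a cutoff is a non-case.
AWGS_GRIP_CUT <- c(male = 28, female = 18)     # kgf
AWGS_SPEED_CUT <- 1.0                          # m/s
AWGS_SMI_CUT <- c(male = 7.0, female = 5.7)    # kg/m^2

#' Skeletal muscle index
#'
#' Appendicular skeletal muscle mass divided by height squared.
#'
#' @param asm appendicular skeletal mass in kg.
#' @param height_cm standing height in cm (> 0).
#' @return SMI in kg/m^2.
#' @export
compute_smi <- function(asm, height_cm) {
  if (any(!is.finite(height_cm)) || any(height_cm <= 0))
    stop_invalid("height must be positive")
  asm / (height_cm / 100)^2
}

check_fields <- function(data, fields, what) {
  missing_cols <- setdiff(fields, names(data))
  if (length(missing_cols) > 0)
    stop_invalid("%s requires column(s): %s", what,
                 paste(missing_cols, collapse = ", "))
  for (f in fields) {
    bad <- which(is.na(data[[f]]))
    if (length(bad) > 0)
      stop_invalid("%s: missing values in '%s' at row(s) %s (complete-case policy)",
                   what, f, paste(utils::head(bad, 5), collapse = ", "))
  }
  if (!all(data$sex %in% c("male", "female")))
    stop_invalid("%s: sex must be 'male' or 'female'", what)
  invisible(TRUE)
}

#' AWGS2019 sarcopenia classification
#'
#' Sarcopenia is low muscle mass combined with low strength or low physical
#' performance: SMI strictly below 7.0 kg/m^2 (men) / 5.7 kg/m^2 (women), AND
#' (grip strength strictly below 28 kgf (men) / 18 kgf (women) OR walking
#' speed strictly below 1.0 m/s). Severity is not graded.
#'
#' @param data data frame with columns \code{sex}, \code{grip},
#'   \code{walking_speed}, and \code{smi} (or \code{asm} + \code{height} from
#'   which SMI is derived).
#' @return logical vector, one element per row.
#' @export
classify_sarcopenia <- function(data) {
  if (!"smi" %in% names(data) && all(c("asm", "height") %in% names(data)))
    data$smi <- compute_smi(data$asm, data$height)
  check_fields(data, c("sex", "grip", "walking_speed", "smi"),
               "classify_sarcopenia")
  low_grip <- data$grip < AWGS_GRIP_CUT[data$sex]
  low_speed <- data$walking_speed < AWGS_SPEED_CUT
  low_smi <- data$smi < AWGS_SMI_CUT[data$sex]
  unname(low_smi & (low_grip | low_speed))
}

#' J-CHS frailty phenotype classification
#'
#' Scores the five phenotype components: unintentional weight loss (>= 2 kg in
#' 6 months, self-report flag), weakness (grip strictly below 28/18 kgf by
#' sex), exhaustion (self-report flag), slowness (walking speed strictly below
#' 1.0 m/s), and low physical activity (self-report flag). A participant is
#' frail when 3 or more components are present.
#'
#' @param data data frame with columns \code{sex}, \code{grip},
#'   \code{walking_speed} and logical \code{weight_loss}, \code{exhaustion},
#'   \code{low_activity}.
#' @return data frame of the five component flags (\code{weight_loss},
#'   \code{weakness}, \code{exhaustion}, \code{slowness},
#'   \code{low_activity}), the component count, and logical \code{frail}.
#' @export
classify_frailty <- function(data) {
  check_fields(data, c("sex", "grip", "walking_speed", "weight_loss",
                       "exhaustion", "low_activity"), "classify_frailty")
  flags <- data.frame(
    weight_loss = as.logical(data$weight_loss),
    weakness = unname(data$grip < AWGS_GRIP_CUT[data$sex]),
    exhaustion = as.logical(data$exhaustion),
    slowness = data$walking_speed < AWGS_SPEED_CUT,
    low_activity = as.logical(data$low_activity)
  )
  flags$n_components <- rowSums(flags)
  flags$frail <- flags$n_components >= 3L
  flags
}

#' Frailty phenotype component summary
#'
#' Count and percentage of each of the five phenotype components within the
#' frail and non-frail groups, with percentages rounded half-up to one
#' decimal as in cohort summary tables.
#'
#' @param data data frame containing logical columns \code{frail},
#'   \code{weight_loss}, \code{weakness}, \code{exhaustion}, \code{slowness},
#'   \code{low_activity} (e.g. the output of \code{\link{classify_frailty}}).
#' @return data frame with one row per component: counts and percentages in
#'   each group.
#' @export
frailty_component_summary <- function(data) {
  comps <- c("slowness", "weight_loss", "exhaustion", "low_activity", "weakness")
  check <- setdiff(c(comps, "frail"), names(data))
  if (length(check) > 0)
    stop_invalid("frailty_component_summary requires column(s): %s",
                 paste(check, collapse = ", "))
  frail <- as.logical(data$frail)
  n_f <- sum(frail); n_nf <- sum(!frail)
  if (n_f == 0 || n_nf == 0)
    stop_invalid("both frailty groups must be non-empty (frail %d, non-frail %d)",
                 n_f, n_nf)
  do.call(rbind, lapply(comps, function(cc) {
    x <- as.logical(data[[cc]])
    data.frame(component = cc,
               frail_n = sum(x[frail]), frail_pct = percent_of(sum(x[frail]), n_f),
               nonfrail_n = sum(x[!frail]),
               nonfrail_pct = percent_of(sum(x[!frail]), n_nf))
  }))
}
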
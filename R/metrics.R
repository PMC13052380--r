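#' Area under the ROC curve (Mann-Whitney form)
#'
#' The probability that a randomly chosen positive receives a higher score
#' than a randomly chosen negative, with ties counted one half (midrank
#' equivalence).
#'
#' @param scores numeric risk scores.
#' @param labels binary outcomes (0/1 or logical); both classes must be
#'   present.
#' @return AUC in [0, 1].
#' @export
auc_mann_whitney <- function(scores, labels) {
  y <- as.integer(as.logical(labels))
  if (length(scores) != length(y)) stop_invalid("scores and labels differ in length")
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L)
    stop_invalid("both outcome classes must be present (got %d positives, %d negatives)",
                 n1, n0)
  n1 <- as.numeric(n1); n0 <- as.numeric(n0)  # n1 * n0 can exceed .Machine$integer.max
  r <- rank(scores)  # midranks
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Closed-form binormal AUC
#'
#' AUC of a score distributed N(\code{mean_pos}, \code{sd_pos}^2) in positives
#' and N(\code{mean_neg}, \code{sd_neg}^2) in negatives:
#' \eqn{\Phi\left((\mu_+ - \mu_-)/\sqrt{\sigma_+^2 + \sigma_-^2}\right)}.
#' Serves as the analytic oracle for simulated single-predictor AUCs.
#'
#' @param mean_pos,sd_pos score distribution among positives.
#' @param mean_neg,sd_neg score distribution among negatives.
#' @return the AUC.
#' @export
binormal_auc <- function(mean_pos, sd_pos, mean_neg, sd_neg) {
  stats::pnorm((mean_pos - mean_neg) / sqrt(sd_pos^2 + sd_neg^2))
}

#' Calibration slope and intercept by logistic recalibration
#'
#' Fits the logistic recalibration model of the observed outcomes on the
#' model's linear predictor (the logit of the predicted probability). The
#' slope is the coefficient of the linear predictor; the intercept
#' (calibration-in-the-large) comes from a second fit with the linear
#' predictor as a fixed-slope offset. Slope 1 and intercept 0 indicate ideal
#' calibration; for a maximum-likelihood logistic model evaluated on its own
#' training data they hold identically by the score equations.
#'
#' @param probs predicted probabilities; values at 0/1 are clipped to
#'   \code{eps} with a warning.
#' @param y binary outcomes.
#' @param eps clipping bound for degenerate probabilities.
#' @return list with \code{slope} and \code{intercept}.
#' @export
calibration_slope_intercept <- function(probs, y, eps = 1e-10) {
  y <- as.integer(as.logical(y))
  if (any(probs <= 0 | probs >= 1)) {
    warning("probabilities at or beyond 0/1 clipped to [eps, 1 - eps]")
    probs <- pmin(pmax(probs, eps), 1 - eps)
  }
  lp <- stats::qlogis(probs)
  if (stats::sd(lp) == 0)
    stop_invalid("calibration slope undefined: linear predictor has zero variance")
  ctl <- stats::glm.control(epsilon = 1e-10, maxit = 200)
  # near-separated predictions routinely trip glm.fit's advisory warnings;
  # degenerate inputs are already handled by the clipping above
  quiet_glm <- function(expr) withCallingHandlers(expr,
    warning = function(w) {
      if (grepl("fitted probabilities numerically|algorithm did not converge",
                conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  slope <- unname(stats::coef(quiet_glm(
    stats::glm(y ~ lp, family = stats::binomial(), control = ctl)))[2])
  intercept <- unname(stats::coef(quiet_glm(
    stats::glm(y ~ 1 + offset(lp), family = stats::binomial(),
               control = ctl)))[1])
  list(slope = slope, intercept = intercept)
}

#' Youden-optimal operating point
#'
#' Chooses the score threshold maximizing Youden's J = sensitivity +
#' specificity - 1 over the observed score cutpoints (classifying scores at
#' or above the threshold as positive). Ties break toward the lowest
#' threshold.
#'
#' @param scores numeric risk scores.
#' @param labels binary outcomes; both classes required.
#' @return list with \code{threshold}, \code{sensitivity},
#'   \code{specificity}.
#' @export
youden_operating_point <- function(scores, labels) {
  y <- as.integer(as.logical(labels))
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L) stop_invalid("both outcome classes must be present")
  cuts <- sort(unique(scores))
  best <- list(j = -Inf, threshold = NA_real_, sensitivity = NA_real_,
               specificity = NA_real_)
  for (thr in cuts) {
    pos <- scores >= thr
    sens <- sum(pos & y == 1L) / n1
    spec <- sum(!pos & y == 0L) / n0
    j <- sens + spec - 1
    if (j > best$j + 1e-12) {
      best <- list(j = j, threshold = thr, sensitivity = sens,
                   specificity = spec)
    }
  }
  best[c("threshold", "sensitivity", "specificity")]
}
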
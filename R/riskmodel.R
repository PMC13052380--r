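#' Elastic-net penalized logistic regression on standardized predictors
#'
#' Fits the penalized logistic model minimizing the summed negative
#' log-likelihood plus
#' \eqn{\lambda [\alpha \sum_j |\beta_j| + (1-\alpha)/2 \sum_j \beta_j^2]}
#' over z-score standardized predictors, with an unpenalized intercept
#' (\eqn{\alpha} = \code{mixing}, \eqn{\lambda} = \code{strength}). The
#' default \code{strength = 1} is the unit inverse-regularization convention
#' on the summed log-likelihood. Columns with at most two distinct values
#' (binary indicators such as sex) are left unstandardized; zero-variance
#' columns are dropped with a warning. Fitting is delegated to
#' \code{\link[glmnet]{glmnet}} with \code{lambda = strength / n} (glmnet's
#' mean-log-likelihood scaling) along a short warm-start path, and is
#' deterministic given data and settings.
#'
#' @param x numeric predictor matrix (no missing values).
#' @param y binary outcome vector with both classes present.
#' @param mixing elastic-net mixing fraction in [0, 1] (1 = lasso).
#' @param strength penalty strength on the summed-likelihood scale (>= 0).
#' @param standardize standardize non-binary columns (default TRUE).
#' @return object of class \code{penlogit}: standardized-scale
#'   \code{coefficients}, \code{intercept}, standardization \code{centers}
#'   and \code{scales}, and the fit settings.
#' @export
fit_penalized_logistic <- function(x, y, mixing = 0.5, strength = 1,
                                   standardize = TRUE) {
  x <- as.matrix(x)
  y <- as.integer(as.logical(y))
  if (anyNA(x) || anyNA(y)) stop_invalid("missing values are not supported")
  if (length(unique(y)) < 2L) stop_invalid("outcome has a single class")
  if (mixing < 0 || mixing > 1) stop_invalid("mixing must lie in [0, 1]")
  if (strength < 0) stop_invalid("strength must be >= 0")
  n <- nrow(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  sds <- apply(x, 2, stats::sd)
  dropped <- colnames(x)[sds == 0]
  if (length(dropped) > 0) {
    warning(sprintf("dropping zero-variance predictor(s): %s",
                    paste(dropped, collapse = ", ")))
    x <- x[, sds > 0, drop = FALSE]
    sds <- sds[sds > 0]
  }
  if (ncol(x) == 0L) stop_invalid("no usable predictors remain")
  is_binary <- apply(x, 2, function(v) length(unique(v)) <= 2L)
  centers <- ifelse(is_binary | !standardize, 0, colMeans(x))
  scales <- ifelse(is_binary | !standardize, 1, sds)
  names(centers) <- names(scales) <- colnames(x)
  z <- sweep(sweep(x, 2, centers), 2, scales, "/")
  padded <- ncol(z) == 1L  # glmnet requires >= 2 columns
  if (padded) z <- cbind(z, `..pad..` = 0)
  lam <- strength / n
  lam_path <- sort(unique(c(lam, lam + c(0.64, 0.16, 0.04, 0.01))),
                   decreasing = TRUE)
  fit <- withCallingHandlers(
    glmnet::glmnet(z, y, family = "binomial", alpha = mixing,
                   lambda = lam_path, standardize = FALSE,
                   thresh = 1e-12, maxit = 1e6),
    warning = function(w) {
      # glmnet's small-class advisory; degenerate classes are guarded upstream
      if (grepl("fewer than 8\\s+observations", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  j <- which(abs(fit$lambda - lam) < 1e-12)[1]
  beta <- as.numeric(fit$beta[, j])
  names(beta) <- rownames(fit$beta)
  if (padded) beta <- beta[names(beta) != "..pad.."]
  structure(list(coefficients = beta,
                 intercept = as.numeric(fit$a0[j]),
                 centers = centers, scales = scales,
                 columns = names(centers), dropped = dropped,
                 mixing = mixing, strength = strength, n = n),
            class = "penlogit")
}

# Linear predictor of a penlogit fit on new raw predictors.
penlogit_link <- function(object, x) {
  x <- as.matrix(x)[, object$columns, drop = FALSE]
  z <- sweep(sweep(x, 2, object$centers), 2, object$scales, "/")
  drop(object$intercept + z %*% object$coefficients)
}

#' @export
predict.penlogit <- function(object, newdata,
                             type = c("response", "link"), ...) {
  type <- match.arg(type)
  eta <- penlogit_link(object, newdata)
  if (type == "link") eta else stats::plogis(eta)
}

#' @export
coef.penlogit <- function(object, ...) {
  c("(Intercept)" = object$intercept, object$coefficients)
}

#' Sit-to-stand risk model
#'
#' The package's central model: an elastic-net penalized logistic regression
#' of a binary status (sarcopenia or frailty) on clinical and
#' smartphone-derived predictors, fitted on z-score standardized continuous
#' predictors via \code{\link{fit_penalized_logistic}}. Returns a classed
#' object supporting \code{print}, \code{summary}, \code{coef},
#' \code{predict}, \code{plot} (ROC curve), \code{residuals},
#' \code{simulate}, and internal validation via \code{\link{validate}}.
#'
#' @param formula model formula, e.g.
#'   \code{sarcopenia ~ age + sex + peak_force}.
#' @param data data frame holding the outcome and predictors.
#' @param mixing elastic-net mixing fraction (default 0.5).
#' @param strength penalty strength on the summed-likelihood scale
#'   (default 1).
#' @param ... reserved.
#' @return object of class \code{sts_riskmodel}.
#' @export
sts_riskmodel <- function(formula, data, mixing = 0.5, strength = 1, ...) {
  mf <- stats::model.frame(formula, data, na.action = stats::na.fail)
  tt <- attr(mf, "terms")
  y <- stats::model.response(mf)
  if (is.factor(y)) y <- as.integer(y) - 1L
  y <- as.integer(as.logical(y))
  x <- stats::model.matrix(tt, mf)
  x <- x[, colnames(x) != "(Intercept)", drop = FALSE]
  fit <- fit_penalized_logistic(x, y, mixing = mixing, strength = strength)
  eta <- penlogit_link(fit, x)
  structure(list(fit = fit, formula = formula, terms = tt,
                 xlevels = stats::.getXlevels(tt, mf),
                 y = y, x = x, data = data,
                 fitted_link = eta, fitted = stats::plogis(eta),
                 mixing = mixing, strength = strength,
                 call = match.call()),
            class = "sts_riskmodel")
}

riskmodel_design <- function(object, newdata) {
  tt <- stats::delete.response(object$terms)
  mf <- stats::model.frame(tt, newdata, na.action = stats::na.fail,
                           xlev = object$xlevels)
  x <- stats::model.matrix(tt, mf)
  x[, colnames(x) != "(Intercept)", drop = FALSE]
}

#' @export
predict.sts_riskmodel <- function(object, newdata = NULL,
                                  type = c("response", "link"), ...) {
  type <- match.arg(type)
  eta <- if (is.null(newdata)) object$fitted_link
         else penlogit_link(object$fit, riskmodel_design(object, newdata))
  if (type == "link") eta else stats::plogis(eta)
}

#' @export
coef.sts_riskmodel <- function(object, scale = c("standardized", "original"),
                               ...) {
  scale <- match.arg(scale)
  b <- object$fit$coefficients
  a <- object$fit$intercept
  if (scale == "original") {
    b0 <- b / object$fit$scales
    a <- a - sum(b0 * object$fit$centers)
    b <- b0
  }
  c("(Intercept)" = a, b)
}

#' @export
fitted.sts_riskmodel <- function(object, ...) object$fitted

#' @export
residuals.sts_riskmodel <- function(object,
                                    type = c("deviance", "pearson",
                                             "response"), ...) {
  type <- match.arg(type)
  y <- object$y; p <- object$fitted
  switch(type,
         response = y - p,
         pearson = (y - p) / sqrt(p * (1 - p)),
         deviance = sign(y - p) *
           sqrt(-2 * (y * log(p) + (1 - y) * log1p(-p))))
}

#' @export
simulate.sts_riskmodel <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  p <- object$fitted
  out <- as.data.frame(replicate(nsim, stats::rbinom(length(p), 1L, p)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' @export
print.sts_riskmodel <- function(x, ...) {
  cat("Penalized logistic sit-to-stand risk model\n")
  cat("  formula:", deparse(x$formula), "\n")
  cat(sprintf("  n = %d, events = %d (%.1f%%), mixing = %g, strength = %g\n",
              length(x$y), sum(x$y), 100 * mean(x$y), x$mixing, x$strength))
  cat("  coefficients (standardized scale):\n")
  print(round(coef(x), 4))
  invisible(x)
}

#' @export
summary.sts_riskmodel <- function(object, ...) {
  auc <- auc_mann_whitney(object$fitted_link, object$y)
  cal <- tryCatch(calibration_slope_intercept(object$fitted, object$y),
                  error = function(e) list(slope = NA_real_,
                                           intercept = NA_real_))
  out <- list(model = object, apparent_auc = auc,
              calibration = cal,
              operating_point = youden_operating_point(object$fitted,
                                                       object$y))
  class(out) <- "summary.sts_riskmodel"
  out
}

#' @export
print.summary.sts_riskmodel <- function(x, ...) {
  print(x$model)
  cat(sprintf("  apparent AUC: %.3f\n", x$apparent_auc))
  cat(sprintf("  apparent calibration: slope %.3f, intercept %.3f\n",
              x$calibration$slope, x$calibration$intercept))
  cat(sprintf("  Youden operating point: threshold %.3f, sens %.3f, spec %.3f\n",
              x$operating_point$threshold, x$operating_point$sensitivity,
              x$operating_point$specificity))
  invisible(x)
}

#' ROC curve of a fitted risk model
#'
#' @param x an \code{\link{sts_riskmodel}}.
#' @param ... passed to \code{plot.default}.
#' @return invisibly, the data frame of ROC points.
#' @export
plot.sts_riskmodel <- function(x, ...) {
  sc <- x$fitted_link; y <- x$y
  cuts <- c(Inf, sort(unique(sc), decreasing = TRUE))
  n1 <- sum(y); n0 <- sum(1 - y)
  pts <- t(vapply(cuts, function(thr) {
    pos <- sc >= thr
    c(fpr = sum(pos & y == 0L) / n0, tpr = sum(pos & y == 1L) / n1)
  }, numeric(2)))
  graphics::plot(pts[, "fpr"], pts[, "tpr"], type = "l",
                 xlab = "1 - specificity", ylab = "Sensitivity",
                 xlim = c(0, 1), ylim = c(0, 1), ...)
  graphics::abline(0, 1, lty = 3, col = "grey50")
  invisible(as.data.frame(pts))
}
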
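test_that("penalized fit at vanishing strength matches the unpenalized oracle", {
  d <- model_test_data(n = 400, delta = 1.2, seed = 71)
  x <- as.matrix(d[c("signal", "noise1", "noise2")])
  fit <- fit_penalized_logistic(x, d$y, mixing = 0.5, strength = 1e-8)
  zx <- scale(x)
  oracle <- glm(d$y ~ zx, family = binomial(),
                control = glm.control(epsilon = 1e-12))
  expect_equal(unname(fit$coefficients), unname(coef(oracle)[-1]),
               tolerance = 1e-4)
  expect_equal(fit$intercept, unname(coef(oracle)[1]), tolerance = 1e-4)
})

test_that("full shrinkage leaves only the prevalence intercept", {
  d <- model_test_data(n = 500, seed = 72)
  x <- as.matrix(d[c("signal", "noise1")])
  fit <- fit_penalized_logistic(x, d$y, strength = 1e7)
  expect_true(all(abs(fit$coefficients) < 1e-6))
  expect_equal(fit$intercept, qlogis(mean(d$y)), tolerance = 1e-3)
})

test_that("pure ridge splits a duplicated predictor evenly", {
  d <- model_test_data(n = 300, seed = 73)
  x <- cbind(a = d$signal, b = d$signal, c = d$noise1)
  fit <- fit_penalized_logistic(x, d$y, mixing = 0, strength = 5)
  expect_equal(fit$coefficients[["a"]], fit$coefficients[["b"]],
               tolerance = 1e-4)
})

test_that("degenerate inputs are rejected or dropped", {
  d <- model_test_data(n = 100, seed = 74)
  x <- as.matrix(d[c("signal", "noise1")])
  expect_error(fit_penalized_logistic(x, rep(1, 100)), "single class")
  x2 <- cbind(x, flat = 1)
  expect_warning(fit2 <- fit_penalized_logistic(x2, d$y), "zero-variance")
  expect_false("flat" %in% names(fit2$coefficients))
  expect_error(fit_penalized_logistic(cbind(x, NA), d$y), "missing")
})

test_that("single-predictor models fit and predict", {
  d <- model_test_data(n = 300, delta = 1.5, seed = 75)
  m <- sts_riskmodel(y ~ signal, d)
  expect_length(coef(m), 2)
  p <- predict(m, d)
  expect_true(all(p > 0 & p < 1))
  expect_gt(auc_mann_whitney(p, d$y), 0.7)
})

test_that("the risk model's S3 surface behaves", {
  d <- model_test_data(n = 300, delta = 1.5, seed = 76)
  m <- sts_riskmodel(y ~ signal + noise1 + sex, d)

  expect_output(print(m), "Penalized logistic")
  expect_output(print(summary(m)), "apparent AUC")

  # standardized and original-scale coefficients give the same predictions
  co <- coef(m, scale = "original")
  x <- cbind(1, as.matrix(riskmodel_design <- model.matrix(
    ~ signal + noise1 + sex, d)[, -1]))
  eta_manual <- drop(x %*% co)
  expect_equal(predict(m, d, type = "link"), eta_manual, tolerance = 1e-10)

  # response + link consistency
  expect_equal(predict(m, d), plogis(predict(m, d, type = "link")))

  r <- residuals(m)
  expect_equal(sum(r^2), sum(residuals(m, "deviance")^2))
  expect_equal(residuals(m, "response"), d$y - fitted(m))

  sim <- simulate(m, nsim = 3, seed = 9)
  expect_identical(dim(sim), c(300L, 3L))
  expect_true(all(unlist(sim) %in% 0:1))
  sim2 <- simulate(m, nsim = 3, seed = 9)
  expect_identical(sim, sim2)

  pdf(NULL)
  roc <- plot(m)
  dev.off()
  expect_true(all(diff(roc$tpr) >= 0))

  # deterministic refit
  m2 <- sts_riskmodel(y ~ signal + noise1 + sex, d)
  expect_identical(coef(m), coef(m2))
})
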
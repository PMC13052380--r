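test_that("SMI is mass over height squared", {
  expect_equal(compute_smi(20, 170), 20 / 1.7^2)
  expect_equal(compute_smi(0, 160), 0)
  set.seed(2)
  asm <- runif(50, 10, 30); h <- runif(50, 140, 190)
  expect_equal(compute_smi(asm, h), asm / (h / 100)^2)
  expect_error(compute_smi(20, 0), "positive")
})

test_that("sarcopenia rule is low mass AND (low grip OR low speed), strict, sex-specific", {
  rec <- function(sex, smi, grip, speed)
    data.frame(sex = sex, smi = smi, grip = grip, walking_speed = speed)
  expect_true(classify_sarcopenia(rec("male", 6.5, 25, 1.2)))
  # boundary: equality at a cutoff never qualifies
  expect_false(classify_sarcopenia(rec("female", 5.7, 10, 0.5)))
  expect_false(classify_sarcopenia(rec("male", 6.9, 28, 1.0)))
  # low mass alone is not sarcopenia
  expect_false(classify_sarcopenia(rec("female", 5.0, 25, 1.3)))
  # sex-specific cutoffs: same numbers, different outcome
  expect_true(classify_sarcopenia(rec("male", 6.9, 27.9, 1.2)))
  expect_false(classify_sarcopenia(rec("female", 6.9, 27.9, 1.2)))
  expect_error(classify_sarcopenia(rec("male", NA, 20, 1.0)), "missing")
})

test_that("sarcopenia classification is monotone in its inputs", {
  set.seed(31)
  for (i in 1:50) {
    d <- data.frame(sex = sample(c("male", "female"), 1),
                    smi = runif(1, 4, 9), grip = runif(1, 10, 40),
                    walking_speed = runif(1, 0.5, 2))
    if (classify_sarcopenia(d)) {
      worse <- d
      worse$smi <- d$smi - runif(1, 0, 2)
      worse$grip <- d$grip - runif(1, 0, 5)
      worse$walking_speed <- max(d$walking_speed - runif(1, 0, 0.5), 0)
      expect_true(classify_sarcopenia(worse))
    }
  }
})

test_that("frailty is 3 or more of the 5 phenotype components", {
  base <- data.frame(sex = "male", grip = 30, walking_speed = 1.4,
                     weight_loss = FALSE, exhaustion = FALSE,
                     low_activity = FALSE)
  expect_false(classify_frailty(base)$frail)

  two <- base; two$weight_loss <- TRUE; two$exhaustion <- TRUE
  expect_false(classify_frailty(two)$frail)

  three <- two; three$low_activity <- TRUE
  expect_true(classify_frailty(three)$frail)

  # weakness and slowness computed from the measures
  meas <- base; meas$grip <- 27.9; meas$walking_speed <- 0.99
  meas$weight_loss <- TRUE
  out <- classify_frailty(meas)
  expect_true(out$weakness && out$slowness && out$frail)

  all5 <- data.frame(sex = "female", grip = 10, walking_speed = 0.6,
                     weight_loss = TRUE, exhaustion = TRUE,
                     low_activity = TRUE)
  expect_identical(classify_frailty(all5)$n_components, 5)
})

test_that("frail flag equals the brute-force component count on random records", {
  set.seed(77)
  n <- 200
  d <- data.frame(sex = sample(c("male", "female"), n, TRUE),
                  grip = runif(n, 5, 45), walking_speed = runif(n, 0.4, 2),
                  weight_loss = runif(n) < 0.3, exhaustion = runif(n) < 0.3,
                  low_activity = runif(n) < 0.3)
  out <- classify_frailty(d)
  brute <- (d$weight_loss + d$exhaustion + d$low_activity +
              (d$grip < ifelse(d$sex == "male", 28, 18)) +
              (d$walking_speed < 1.0)) >= 3
  expect_identical(out$frail, brute)
})

test_that("component summary reports table-style rounded percentages", {
  n_f <- 51; n_nf <- 536
  d <- data.frame(
    frail = rep(c(TRUE, FALSE), c(n_f, n_nf)),
    slowness = rep(c(TRUE, FALSE, TRUE, FALSE), c(16, 35, 12, 524)),
    weight_loss = rep(c(TRUE, FALSE, TRUE, FALSE), c(33, 18, 59, 477)),
    exhaustion = rep(c(TRUE, FALSE, TRUE, FALSE), c(46, 5, 127, 409)),
    low_activity = rep(c(TRUE, FALSE, TRUE, FALSE), c(25, 26, 77, 459)),
    weakness = rep(c(TRUE, FALSE, TRUE, FALSE), c(44, 7, 133, 403)))
  s <- frailty_component_summary(d)
  expect_equal(s$frail_pct[s$component == "slowness"], 31.4)
  expect_equal(s$nonfrail_pct[s$component == "slowness"], 2.2)
  expect_equal(s$frail_pct[s$component == "exhaustion"], 90.2)
  expect_equal(s$nonfrail_pct[s$component == "weight_loss"], 11.0)

  # degenerate proportions
  d0 <- data.frame(frail = rep(c(TRUE, FALSE), c(51, 10)),
                   slowness = rep(c(TRUE, FALSE), c(51, 10)),
                   weight_loss = FALSE, exhaustion = FALSE,
                   low_activity = FALSE, weakness = FALSE)
  s0 <- frailty_component_summary(d0)
  expect_equal(s0$frail_pct[s0$component == "slowness"], 100.0)
  expect_equal(s0$frail_pct[s0$component == "weakness"], 0.0)
  expect_error(frailty_component_summary(d[d$frail, ]), "non-empty")
})

test_that("percent rounding is half-up at one decimal", {
  expect_equal(round_half_up(0.25, 1), 0.3)
  expect_equal(percent_of(1, 800), 0.1)   # 0.125% -> 0.1
  expect_equal(percent_of(95, 569), 16.7)
})
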
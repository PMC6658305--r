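# Deterministic demographic frame with a programmed weight effect on the
# high-fever outcome (used across the logistic tests).
sim_highfever_frame <- function(n, beta_weight = 0.2, beta_age = 0,
                                intercept = -2.85) {
  age <- stats::rgamma(n, shape = (15 / 9)^2, rate = 15 / 9^2)
  weight <- 0.4 * age + 4 + stats::rnorm(n)
  sex <- ifelse(stats::runif(n) < 0.6, "male", "female")
  lp <- intercept + beta_weight * weight + beta_age * age
  y <- stats::runif(n) < stats::plogis(lp)
  data.frame(tmax_c = ifelse(y, 39.3, 38.4), age_months = age,
             weight_kg = weight, sex = sex, stringsAsFactors = FALSE)
}

test_that("a null coefficient maps to an odds ratio of one with a
           log-symmetric interval", {
  o <- or_from_coef(0, 0.2)
  expect_equal(unname(o["or"]), 1)
  expect_equal(unname(o["lo"] * o["hi"]), 1, tolerance = 1e-12)
  # the multiplier is the 97.5% normal quantile
  o2 <- or_from_coef(1, 1)
  expect_equal(unname(log(o2["hi"]) - 1), stats::qnorm(0.975),
               tolerance = 1e-9)
})

test_that("the fitted model satisfies its score equations and invariants", {
  set.seed(42)
  d <- sim_highfever_frame(2000)
  fit <- fit_high_fever_logistic(d)
  X <- stats::model.matrix(fit$fit)
  grad <- crossprod(X, (d$tmax_c >= 39) - stats::fitted(fit$fit))
  expect_lt(max(abs(grad)), 1e-6)
  co <- fit$coefficients
  expect_equal(co$or, exp(co$B), tolerance = 1e-12)
  expect_true(all(co$or_lo < co$or & co$or < co$or_hi))
  expect_equal(co$or_lo, exp(co$B - stats::qnorm(0.975) * co$SE),
               tolerance = 1e-12)
})

test_that("the weight effect is recovered near its programmed value", {
  set.seed(43)
  d <- sim_highfever_frame(8000, beta_weight = 0.2)
  fit <- fit_high_fever_logistic(d)
  b <- fit$coefficients
  expect_equal(b$B[b$predictor == "weight_kg"], 0.2, tolerance = 0.2)
  expect_gt(b$p[b$predictor == "sex_male"], 0.001)  # null predictor
})

test_that("perfect separation is reported with the offending predictor", {
  d <- data.frame(tmax_c = c(rep(39.5, 20), rep(38.2, 20)),
                  age_months = rnorm(40, 15),
                  weight_kg = c(rnorm(20, 20, 0.5), rnorm(20, 8, 0.5)),
                  sex = rep(c("male", "female"), 20))
  expect_error(fit_high_fever_logistic(d), "weight_kg")
  d2 <- data.frame(tmax_c = rep(38, 20), age_months = rnorm(20, 15),
                   weight_kg = rnorm(20, 10), sex = "male")
  expect_error(fit_high_fever_logistic(d2), "no events")
})

test_that("variance inflation follows its closed form and symmetries", {
  x1 <- c(1, 1, -1, -1); x2 <- c(1, -1, 1, -1)
  v <- compute_vif(cbind(a = x1, b = x2))
  expect_equal(v$vif, c(1, 1))  # orthogonal design

  # exact correlation 0.6 gives VIF 1/(1 - 0.36) = 1.5625
  t <- 1:40
  z1 <- as.numeric(scale(t))
  e <- stats::resid(stats::lm((-1)^t ~ z1))
  e <- e / stats::sd(e)
  z2 <- 0.6 * z1 + sqrt(1 - 0.36) * e
  v2 <- compute_vif(cbind(p = z1, q = z2))
  expect_equal(v2$vif, c(1.5625, 1.5625), tolerance = 1e-9)

  # two-predictor designs share one auxiliary R-squared
  set.seed(9)
  age <- rgamma(300, 4, 0.3); weight <- 0.4 * age + 4 + rnorm(300)
  v3 <- compute_vif(cbind(age = age, weight = weight))
  expect_equal(v3$vif[1], v3$vif[2], tolerance = 1e-10)
})

test_that("auxiliary-regression VIFs agree with the car implementation", {
  set.seed(10)
  x1 <- rnorm(200); x2 <- 0.7 * x1 + rnorm(200); x3 <- rnorm(200)
  y <- rnorm(200)
  ours <- compute_vif(cbind(x1 = x1, x2 = x2, x3 = x3))$vif
  theirs <- unname(car::vif(stats::lm(y ~ x1 + x2 + x3)))
  expect_equal(ours, theirs, tolerance = 1e-8)
})

test_that("exactly collinear predictors are flagged, not fatal", {
  x <- rnorm(50)
  v <- compute_vif(cbind(a = x, b = 2 * x))
  expect_true(all(!is.finite(v$vif)))
  expect_true(all(v$flagged))
  expect_error(compute_vif(cbind(a = x, b = rep(1, 50))), "constant")
})
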
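test_that("linear fit recovers an exact line and the 3-point toy set", {
  d <- tibble::tibble(x = 0:10, y = 2 * (0:10) + 1)
  fit <- fit_linear(d, x, y)
  expect_equal(fit$slope, 2)
  expect_equal(fit$intercept, 1)
  expect_equal(fit$residual_sd, 0)
  # residual_sd = 0 collapses the PI onto the estimate
  pb <- predict_with_pi(fit, 4)
  expect_equal(pb$pi_low, pb$estimate)
  expect_equal(pb$pi_high, pb$estimate)

  toy <- tibble::tibble(x = c(0, 12, 24), y = c(130, 135, 140))
  fit3 <- fit_linear(toy, x, y)
  expect_equal(fit3$slope, 5 / 12)
  expect_equal(fit3$intercept, 130)

  expect_error(fit_linear(toy[1:2, ], x, y), "at least 3")
  expect_error(fit_linear(tibble::tibble(x = c(1, 1, 1), y = 1:3), x, y),
               "constant predictor")
})

test_that("prediction intervals match the t-based formula and predict.lm", {
  # noisy 3-point set: hand OLS gives slope 5/12, intercept 130.333,
  # residual SD sqrt(2/3); PI at x = 12 uses t(0.975, 1 df) = 12.706
  toy <- tibble::tibble(x = c(0, 12, 24), y = c(130, 136, 140))
  fit <- fit_linear(toy, x, y)
  expect_equal(fit$slope, 5 / 12)
  expect_equal(fit$intercept, 130 + 1 / 3)
  expect_equal(fit$residual_sd, sqrt(2 / 3))
  pb <- predict_with_pi(fit, 12)
  half_hand <- qt(0.975, 1) * sqrt(2 / 3) * sqrt(1 + 1 / 3)
  expect_equal(pb$estimate, 135 + 1 / 3)
  expect_equal(pb$pi_high - pb$estimate, half_hand)

  # dual route: agree with predict.lm(interval = "prediction") on random data
  withr::with_seed(23, {
    for (rep in 1:10) {
      n <- sample(10:60, 1)
      d <- tibble::tibble(x = runif(n, 0, 24),
                          y = 120 + 0.7 * x + rnorm(n, 0, 4))
      fit <- fit_linear(d, x, y)
      at <- runif(3, -5, 30)
      mine <- predict_with_pi(fit, at)
      ref <- predict(lm(y ~ x, data = d), newdata = data.frame(x = at),
                     interval = "prediction", level = 0.95)
      expect_equal(mine$estimate, unname(ref[, "fit"]), tolerance = 1e-10)
      expect_equal(mine$pi_low, unname(ref[, "lwr"]), tolerance = 1e-10)
      expect_equal(mine$pi_high, unname(ref[, "upr"]), tolerance = 1e-10)
    }
  })
})

test_that("PI width is minimal at the predictor mean and grows outward", {
  withr::with_seed(29, {
    d <- tibble::tibble(x = runif(40, 0, 1), y = 130 + 10 * x + rnorm(40))
  })
  fit <- fit_linear(d, x, y)
  at <- seq(0, 1, by = 0.05)
  pb <- predict_with_pi(fit, at)
  width <- pb$pi_high - pb$pi_low
  expect_equal(at[which.min(width)], at[which.min(abs(at - fit$predictor_mean))])
  expect_true(all(diff(width[at > fit$predictor_mean]) > 0))
})

test_that("prediction intervals attain nominal coverage on fresh data", {
  withr::with_seed(31, {
    hits <- replicate(2000, {
      x <- runif(30, 0, 1)
      y <- 130 + 8 * x + rnorm(30, 0, 3)
      fit <- fit_linear(tibble::tibble(x = x, y = y), x, y)
      x_new <- runif(1)
      y_new <- 130 + 8 * x_new + rnorm(1, 0, 3)
      pb <- predict_with_pi(fit, x_new)
      y_new >= pb$pi_low && y_new <= pb$pi_high
    })
  })
  expect_equal(mean(hits), 0.95, tolerance = 0.015 / 0.95)
})

test_that("logit fit recovers exact parameters and excludes boundary ratios", {
  x <- seq(0.05, 0.95, by = 0.05)
  d <- tibble::tibble(ct = c(0, x, 1),
                      y = c(100, 135 + 6 * qlogis(x), 170))
  fit <- fit_logit(d, ct, y)
  expect_equal(fit$excluded_boundary_points, 2L)
  expect_equal(fit$n, length(x))
  expect_equal(fit$slope, 6, tolerance = 1e-10)
  expect_equal(fit$intercept, 135, tolerance = 1e-10)
  expect_error(predict_with_pi(fit, 0), "0 < x < 1")
  expect_error(fit_logit(tibble::tibble(ct = c(0, 1, 0.5), y = 1:3), ct, y),
               "at least 3")

  # closed-form least-squares oracle on random noisy instances
  withr::with_seed(37, {
    for (rep in 1:10) {
      ct <- runif(30, 0.02, 0.98)
      y <- 134 + 5 * qlogis(ct) + rnorm(30, 0, 2)
      fit <- fit_logit(tibble::tibble(ct = ct, y = y), ct, y)
      g <- qlogis(ct)
      slope_ref <- sum((g - mean(g)) * (y - mean(y))) / sum((g - mean(g))^2)
      expect_equal(fit$slope, slope_ref, tolerance = 1e-8)
      expect_equal(fit$intercept, mean(y) - slope_ref * mean(g), tolerance = 1e-8)
    }
  })
})

test_that("confidence thresholds scan integer counts and ratio grids", {
  # exact integer line: PI collapses, thresholds bracket the target
  d <- tibble::tibble(x = 0:24, y = 125 + 0:24)
  fit <- fit_linear(d, x, y)
  thr <- confidence_thresholds(fit, 136.5, domain = 0:24)
  expect_equal(thr$rule_in, 12)  # estimate 137 at count 12, PI width ~0
  expect_equal(thr$rule_out, 11) # estimate 136 at count 11

  expect_lt(thr$rule_out, thr$rule_in)

  # degenerate band entirely above target: no rule-out, smallest value rules in
  hi <- tibble::tibble(x = 0:24, y = 150 + (0:24) * 0.5)
  thr_hi <- confidence_thresholds(fit_linear(hi, x, y), 135, domain = 0:24)
  expect_true(is.na(thr_hi$rule_out))
  expect_equal(thr_hi$rule_in, 0)

  expect_error(
    confidence_thresholds(fit_linear(tibble::tibble(x = 0:9, y = 9:0), x, y), 135),
    "non-increasing"
  )

  # ratio domain reports 2-decimal thresholds inside (0, 1)
  withr::with_seed(41, {
    ct <- runif(200, 0.01, 0.99)
    y <- 127 + 16 * ct + rnorm(200, 0, 3)
  })
  fitr <- fit_linear(tibble::tibble(ct = ct, y = y), ct, y)
  thr_r <- confidence_thresholds(fitr, 135, domain = "ratio")
  expect_true(thr_r$rule_out > 0 && thr_r$rule_in < 1)
  expect_lt(thr_r$rule_out, thr_r$rule_in)
  expect_equal(thr_r$rule_out, round(thr_r$rule_out, 2))
})

test_that("indeterminate zone widens as residual noise grows", {
  thr_at_noise <- function(sd) {
    withr::with_seed(43, {
      x <- rep(0:24, 8)
      y <- 125 + x * 10 / 12 + rnorm(length(x), 0, sd)
    })
    confidence_thresholds(fit_linear(tibble::tibble(x = x, y = y), x, y),
                          135, domain = 0:24)
  }
  lo <- thr_at_noise(1)
  hi <- thr_at_noise(5)
  expect_lte(hi$rule_out, lo$rule_out)
  expect_gte(hi$rule_in, lo$rule_in)
})

test_that("calibration table is monotone and combines both model forms", {
  withr::with_seed(47, {
    ct <- runif(150, 0.02, 0.98)
    y <- 135 + 14 * (ct - 0.5) + rnorm(150, 0, 2)
  })
  d <- tibble::tibble(ct = ct, y = y)
  lin <- fit_linear(d, ct, y, channel = "sbp")
  lgt <- fit_logit(d, ct, y, channel = "sbp")
  tab <- calibration_table(lin, lgt)
  expect_equal(nrow(tab), 14) # 7 ratios x 2 models
  expect_setequal(unique(tab$model), c("linear", "logit"))
  expect_true(all(tab$pi_low <= tab$estimate & tab$estimate <= tab$pi_high))
  for (m in c("linear", "logit")) {
    expect_true(all(diff(tab$estimate[tab$model == m]) > 0))
  }
  # linear and logit agree near the centre of the ratio scale
  expect_lt(abs(tab$estimate[tab$ratio == 0.5 & tab$model == "linear"] -
                  tab$estimate[tab$ratio == 0.5 & tab$model == "logit"]), 1)

  # glance/tidy carry the fit metadata
  expect_equal(glance(lgt)$form, "logit")
  expect_equal(nrow(tidy(lin)), 2)
  expect_s3_class(autoplot(lin, target = 135), "ggplot")
})

test_that("response-range restriction subsets before fitting", {
  d <- tibble::tibble(ct = seq(0.02, 0.98, length.out = 100))
  d$y <- 135 + 30 * (d$ct - 0.5)
  fit <- fit_linear(d, ct, y, fit_range = c(125, 145))
  expect_true(all(fit$data$y >= 125 & fit$data$y <= 145))
  expect_lt(fit$n, 100)
  expect_equal(glance(fit)$fit_range_low, 125)
})
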
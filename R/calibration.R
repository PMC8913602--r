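# Calibration: mapping a count statistic (high count or C/T ratio) to an
# estimated mean BP by ordinary least squares, either directly (linear)
# or on the logit-transformed ratio, with t-based 95% prediction
# intervals and the rule-in / rule-out thresholds those intervals imply.

new_calibration_fit <- function(form, predictor_name, response_name,
                                coef, residual_sd, n, predictor_mean,
                                predictor_ssq, fit_range, excluded, data,
                                channel = NULL) {
  structure(
    list(
      form = form,
      predictor = predictor_name,
      response = response_name,
      intercept = unname(coef[1]),
      slope = unname(coef[2]),
      residual_sd = residual_sd,
      n = n,
      predictor_mean = predictor_mean,
      predictor_ssq = predictor_ssq,
      fit_range = fit_range,
      excluded_boundary_points = excluded,
      data = data,
      channel = channel
    ),
    class = "calibration_fit"
  )
}

# shared OLS core on (g(x), y); g is identity or qlogis
fit_calibration_ols <- function(x, gx, y, form, predictor_name, response_name,
                                fit_range, excluded, channel) {
  n <- length(gx)
  if (n < 3) {
    rlang::abort("calibration needs at least 3 points after subsetting/exclusion.")
  }
  if (stats::var(gx) == 0) {
    rlang::abort("constant predictor: calibration is unidentifiable.")
  }
  fit <- stats::lm(y ~ gx)
  new_calibration_fit(
    form = form,
    predictor_name = predictor_name, response_name = response_name,
    coef = stats::coef(fit),
    residual_sd = sqrt(sum(stats::residuals(fit)^2) / (n - 2)),
    n = n,
    predictor_mean = mean(gx),
    predictor_ssq = sum((gx - mean(gx))^2),
    fit_range = fit_range,
    excluded = excluded,
    data = tibble::tibble(x = x, gx = gx, y = y),
    channel = channel
  )
}

#' Linear count-to-mean-BP calibration
#'
#' Ordinary least squares of a mean BP on a count statistic. An optional
#' `fit_range` restricts the fit to responses inside a closed interval
#' (e.g. mean SBP in \[125, 145\] mmHg, the near-target band where the
#' relation is locally linear) before fitting. Sufficient statistics are
#' stored so [predict_with_pi()] can rebuild exact t-based prediction
#' intervals.
#'
#' @param data Data frame holding the fitted variables.
#' @param predictor,response Columns (tidy-eval): the count statistic and
#'   the mean BP (mmHg).
#' @param fit_range Optional length-2 closed interval on the response.
#' @param channel Optional label (`"sbp"`/`"dbp"`) carried into reports.
#' @return An object of class `calibration_fit`; see [predict_with_pi()],
#'   [confidence_thresholds()], `tidy()`, `glance()`, `autoplot()`.
#' @examples
#' d <- tibble::tibble(count = 0:24, mbp = 125 + 0.8 * (0:24))
#' fit_linear(d, count, mbp)
#' @export
fit_linear <- function(data, predictor, response, fit_range = NULL,
                       channel = NULL) {
  x <- rlang::eval_tidy(rlang::enquo(predictor), data)
  y <- rlang::eval_tidy(rlang::enquo(response), data)
  pname <- rlang::as_name(rlang::enquo(predictor))
  rname <- rlang::as_name(rlang::enquo(response))
  if (!is.null(fit_range)) {
    stopifnot(length(fit_range) == 2, fit_range[1] < fit_range[2])
    keep <- y >= fit_range[1] & y <= fit_range[2]
    x <- x[keep]
    y <- y[keep]
  }
  fit_calibration_ols(x, x, y, "linear", pname, rname,
                      fit_range = fit_range, excluded = 0L, channel = channel)
}

#' Logit-curve calibration for C/T ratios
#'
#' Fits mean BP = C + beta * log(x / (1 - x)) by ordinary least squares on
#' the logit-transformed C/T ratio. The transform is only defined on
#' 0 < x < 1, so boundary ratios (0 or 1 — series with no or only high
#' readings) are excluded, not clamped; the exclusion count is recorded on
#' the fit.
#'
#' @inheritParams fit_linear
#' @return A `calibration_fit` with `form = "logit"` and
#'   `excluded_boundary_points` set.
#' @export
fit_logit <- function(data, predictor, response, channel = NULL) {
  x <- rlang::eval_tidy(rlang::enquo(predictor), data)
  y <- rlang::eval_tidy(rlang::enquo(response), data)
  pname <- rlang::as_name(rlang::enquo(predictor))
  rname <- rlang::as_name(rlang::enquo(response))
  interior <- x > 0 & x < 1
  excluded <- sum(!interior)
  x <- x[interior]
  y <- y[interior]
  fit_calibration_ols(x, stats::qlogis(x), y, "logit", pname, rname,
                      fit_range = NULL, excluded = excluded, channel = channel)
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat("<calibration_fit>", x$form, ":", x$response, "~",
      if (x$form == "logit") paste0("logit(", x$predictor, ")") else x$predictor,
      if (!is.null(x$channel)) paste0("[", x$channel, "]"), "\n")
  cat("  intercept =", format(x$intercept, digits = 6),
      " slope =", format(x$slope, digits = 6),
      " residual SD =", format(x$residual_sd, digits = 4),
      " n =", x$n, "\n")
  if (!is.null(x$fit_range)) {
    cat("  response restricted to [", x$fit_range[1], ",", x$fit_range[2], "] mmHg\n")
  }
  if (x$excluded_boundary_points > 0) {
    cat("  boundary ratios excluded:", x$excluded_boundary_points, "\n")
  }
  invisible(x)
}

transform_predictor <- function(fit, at) {
  if (fit$form == "logit") {
    if (any(at <= 0 | at >= 1)) {
      rlang::abort("logit calibration is defined only on 0 < x < 1.")
    }
    stats::qlogis(at)
  } else {
    at
  }
}

#' Predict mean BP with a prediction interval
#'
#' Point estimate and t-based prediction interval for a new series at the
#' given predictor value(s): estimate = C + beta * g(at), and
#' PI = estimate +/- t(1 - alpha/2, n - 2) * s * sqrt(1 + 1/n +
#' (g(at) - mean(g))^2 / SSQ(g)), where g is the identity (linear) or the
#' logit transform and s the residual SD. The PI covers a new observation
#' (a new series' mean BP), so it is strictly wider than the confidence
#' band of the fitted mean whenever s > 0.
#'
#' @param fit A `calibration_fit`.
#' @param at Predictor value(s); for logit fits must lie in (0, 1).
#' @param level Coverage level; default 0.95.
#' @return Tibble `at`, `estimate`, `pi_low`, `pi_high`, `level`.
#' @export
predict_with_pi <- function(fit, at, level = 0.95) {
  stopifnot(inherits(fit, "calibration_fit"), level > 0, level < 1)
  g <- transform_predictor(fit, at)
  est <- fit$intercept + fit$slope * g
  tq <- stats::qt(1 - (1 - level) / 2, df = fit$n - 2)
  half <- tq * fit$residual_sd *
    sqrt(1 + 1 / fit$n + (g - fit$predictor_mean)^2 / fit$predictor_ssq)
  tibble::tibble(at = at, estimate = est,
                 pi_low = est - half, pi_high = est + half, level = level)
}

#' Rule-in / rule-out thresholds from a calibration fit
#'
#' The rule-out threshold is the largest predictor value whose whole
#' prediction interval lies below the BP target (controlled with at least
#' `level` confidence); the rule-in threshold is the smallest whose PI
#' lower limit reaches the target (uncontrolled with at least `level`
#' confidence). Between them lies the indeterminate zone.
#'
#' `domain` is either an integer/numeric vector of candidate predictor
#' values (e.g. `0:24` for counts out of 24 readings — scanned exactly) or
#' `"ratio"` for a continuous C/T-ratio search on (0, 1) at 1e-4
#' resolution, reported rounded to 2 decimals.
#'
#' @param fit A `calibration_fit` with positive slope.
#' @param target BP target in mmHg (e.g. 135 systolic, 85 diastolic).
#' @param level Confidence level; default 0.95.
#' @param domain Numeric vector of counts, or `"ratio"`.
#' @return One-row tibble `rule_out`, `rule_in`, `target`, `level` (`NA`
#'   when no domain value qualifies).
#' @export
confidence_thresholds <- function(fit, target, level = 0.95, domain = "ratio") {
  stopifnot(inherits(fit, "calibration_fit"))
  if (fit$slope <= 0) {
    rlang::abort("non-increasing calibration: slope must be positive.")
  }
  if (identical(domain, "ratio")) {
    grid <- seq(1e-4, 1 - 1e-4, by = 1e-4)
    round_to <- 2L
  } else {
    stopifnot(is.numeric(domain), length(domain) >= 1)
    grid <- sort(domain)
    round_to <- NULL
  }
  pb <- predict_with_pi(fit, grid, level = level)
  out_idx <- which(pb$pi_high < target)
  in_idx <- which(pb$pi_low >= target)
  rule_out <- if (length(out_idx)) grid[max(out_idx)] else NA_real_
  rule_in <- if (length(in_idx)) grid[min(in_idx)] else NA_real_
  if (!is.null(round_to)) {
    rule_out <- round(rule_out, round_to)
    rule_in <- round(rule_in, round_to)
  }
  tibble::tibble(rule_out = rule_out, rule_in = rule_in,
                 target = target, level = level)
}

#' Calibration report over a ratio grid
#'
#' Tabulates the linear and logit calibration estimates with prediction
#' intervals over a grid of C/T ratios — the look-up table a clinician
#' would use to turn a counted ratio into an approximate mean BP.
#'
#' @param linear_fit,logit_fit `calibration_fit` objects for the same
#'   channel (either may be NULL to omit).
#' @param at Ratio grid; default `seq(0.2, 0.8, by = 0.1)`.
#' @param level Coverage level; default 0.95.
#' @return Tibble `model`, `ratio`, `estimate`, `pi_low`, `pi_high` (and
#'   `channel` when the fits carry one).
#' @export
calibration_table <- function(linear_fit = NULL, logit_fit = NULL,
                              at = seq(0.2, 0.8, by = 0.1), level = 0.95) {
  if (is.null(linear_fit) && is.null(logit_fit)) {
    rlang::abort("supply at least one fit.")
  }
  one <- function(fit, label) {
    if (is.null(fit)) return(NULL)
    pb <- predict_with_pi(fit, at, level = level)
    out <- tibble::tibble(model = label, ratio = at, estimate = pb$estimate,
                          pi_low = pb$pi_low, pi_high = pb$pi_high)
    if (!is.null(fit$channel)) out$channel <- fit$channel
    out
  }
  dplyr::bind_rows(one(logit_fit, "logit"), one(linear_fit, "linear"))
}
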
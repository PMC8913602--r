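# broom-style tidiers for the package's fitted objects

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an ROC curve
#'
#' @param x An `hbp_roc` from [roc_curve()].
#' @param ... Unused.
#' @return The threshold sweep: tibble `threshold`, `sens`, `spec`.
#' @method tidy hbp_roc
#' @export
tidy.hbp_roc <- function(x, ...) {
  x$curve
}

#' @rdname tidy.hbp_roc
#' @return `glance()`: one row `auc`, `auc_lo`, `auc_hi`, `ci_method`,
#'   `n`, `n_positive`.
#' @method glance hbp_roc
#' @export
glance.hbp_roc <- function(x, ...) {
  tibble::tibble(
    auc = x$auc,
    auc_lo = if (is.null(x$auc_ci)) NA_real_ else x$auc_ci[["low"]],
    auc_hi = if (is.null(x$auc_ci)) NA_real_ else x$auc_ci[["high"]],
    ci_method = x$ci_method,
    n = x$n,
    n_positive = x$n_positive
  )
}

#' Tidy a bootstrap set
#'
#' @param x A `bootstrap_set` from [bootstrap_statistic()].
#' @param ... Unused.
#' @return Tibble `replicate`, `value`.
#' @method tidy bootstrap_set
#' @export
tidy.bootstrap_set <- function(x, ...) {
  tibble::tibble(replicate = seq_along(x$replicates), value = x$replicates)
}

#' @rdname tidy.bootstrap_set
#' @return `glance()`: one row `statistic`, `R`, `n`, `median`, `iqr_lo`,
#'   `iqr_hi`, `redraws`.
#' @method glance bootstrap_set
#' @export
glance.bootstrap_set <- function(x, ...) {
  q <- stats::quantile(x$replicates, c(0.25, 0.5, 0.75), names = FALSE)
  tibble::tibble(statistic = x$statistic, R = x$R, n = x$n,
                 median = q[2], iqr_lo = q[1], iqr_hi = q[3],
                 redraws = x$redraws)
}

#' Tidy a mixed-model design comparison
#'
#' @param x An `effect_comparison` from [compare_across_design()].
#' @param ... Unused.
#' @return The fixed-effect table: tibble `term`, `estimate`, `se`,
#'   `statistic`, `p_value`.
#' @method tidy effect_comparison
#' @export
tidy.effect_comparison <- function(x, ...) {
  x$fixed
}

#' @rdname tidy.effect_comparison
#' @return `glance()`: one row `n_obs`, `random_intercept_sd`,
#'   `residual_sd`, `degenerate`.
#' @method glance effect_comparison
#' @export
glance.effect_comparison <- function(x, ...) {
  tibble::tibble(n_obs = x$n_obs,
                 random_intercept_sd = x$random_intercept_sd,
                 residual_sd = x$residual_sd,
                 degenerate = x$degenerate)
}

#' Tidy a calibration fit
#'
#' @param x A `calibration_fit` from [fit_linear()] or [fit_logit()].
#' @param ... Unused.
#' @return Tibble `term` (`"(Intercept)"`, the predictor), `estimate`.
#' @method tidy calibration_fit
#' @export
tidy.calibration_fit <- function(x, ...) {
  tibble::tibble(
    term = c("(Intercept)",
             if (x$form == "logit") paste0("logit(", x$predictor, ")") else x$predictor),
    estimate = c(x$intercept, x$slope)
  )
}

#' @rdname tidy.calibration_fit
#' @return `glance()`: one row `form`, `n`, `residual_sd`,
#'   `excluded_boundary_points`, `fit_range_low`, `fit_range_high`.
#' @method glance calibration_fit
#' @export
glance.calibration_fit <- function(x, ...) {
  tibble::tibble(
    form = x$form, n = x$n, residual_sd = x$residual_sd,
    excluded_boundary_points = x$excluded_boundary_points,
    fit_range_low = if (is.null(x$fit_range)) NA_real_ else x$fit_range[1],
    fit_range_high = if (is.null(x$fit_range)) NA_real_ else x$fit_range[2]
  )
}
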
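# ggplot2 graphics for the result types

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an ROC curve
#'
#' @param object An `hbp_roc` from [roc_curve()].
#' @param ... Unused.
#' @return A ggplot: 1 - specificity vs sensitivity with the chance
#'   diagonal and the AUC in the subtitle.
#' @method autoplot hbp_roc
#' @export
autoplot.hbp_roc <- function(object, ...) {
  cur <- object$curve
  lab <- paste0("AUC = ", format(object$auc, digits = 3))
  if (!is.null(object$auc_ci)) {
    lab <- paste0(lab, " (", format(object$auc_ci[["low"]], digits = 3), "-",
                  format(object$auc_ci[["high"]], digits = 3), ", ",
                  object$ci_method, ")")
  }
  ggplot2::ggplot(cur, ggplot2::aes(x = 1 - .data$spec, y = .data$sens)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_path() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "1 - specificity", y = "Sensitivity", subtitle = lab) +
    ggplot2::theme_minimal()
}

#' Plot a calibration fit with its prediction band
#'
#' Scatter of the fitted points, the regression line, the prediction-
#' interval ribbon and, when `target` is given, the target line with the
#' rule-in / rule-out thresholds as dotted verticals.
#'
#' @param object A `calibration_fit`.
#' @param target Optional BP target (mmHg) to annotate thresholds for.
#' @param level PI level; default 0.95.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot calibration_fit
#' @export
autoplot.calibration_fit <- function(object, target = NULL, level = 0.95, ...) {
  dat <- object$data
  grid <- if (object$form == "logit") {
    seq(max(min(dat$x), 0.01), min(max(dat$x), 0.99), length.out = 200)
  } else {
    seq(min(dat$x), max(dat$x), length.out = 200)
  }
  band <- predict_with_pi(object, grid, level = level)
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_ribbon(
      data = band,
      ggplot2::aes(x = .data$at, ymin = .data$pi_low, ymax = .data$pi_high),
      inherit.aes = FALSE, fill = "red", alpha = 0.15
    ) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_line(
      data = band, ggplot2::aes(x = .data$at, y = .data$estimate),
      inherit.aes = FALSE, colour = "blue"
    ) +
    ggplot2::labs(
      x = if (object$form == "logit") paste0(object$predictor, " (logit scale fit)")
          else object$predictor,
      y = paste0(object$response, " (mmHg)")
    ) +
    ggplot2::theme_minimal()
  if (!is.null(target)) {
    thr <- confidence_thresholds(
      object, target, level = level,
      domain = if (object$form == "linear" &&
                   all(dat$x == round(dat$x))) sort(unique(dat$x)) else "ratio"
    )
    p <- p + ggplot2::geom_hline(yintercept = target, colour = "grey40")
    for (v in c(thr$rule_out, thr$rule_in)) {
      if (!is.na(v)) {
        p <- p + ggplot2::geom_vline(xintercept = v, linetype = "dotted",
                                     colour = "grey40")
      }
    }
  }
  p
}

#' Plot performance distributions across the design
#'
#' Boxplots of per-cell bootstrap replicates of a performance statistic
#' by SD level, one panel per series length K — the at-a-glance view of
#' how accuracy degrades with reading variability and (not) with series
#' length.
#'
#' @param replicates Tibble from [bootstrap_design()] (columns `k`,
#'   `sd_level`, `value`, optionally `channel`/`statistic` used for
#'   labels).
#' @return A ggplot.
#' @export
plot_performance_by_design <- function(replicates) {
  stopifnot(all(c("k", "sd_level", "value") %in% names(replicates)))
  ylab <- if ("statistic" %in% names(replicates)) {
    paste(unique(toupper(replicates$statistic)), collapse = "/")
  } else {
    "value"
  }
  ggplot2::ggplot(
    replicates,
    ggplot2::aes(x = factor(.data$sd_level), y = .data$value)
  ) +
    ggplot2::geom_boxplot(outlier.alpha = 0.2) +
    ggplot2::facet_wrap(~k, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "Reading SD (mmHg)", y = ylab) +
    ggplot2::theme_minimal()
}
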
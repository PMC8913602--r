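# Bootstrap distributions of diagnostic performance per design cell, and
# a mixed-model comparison of those distributions across the factorial
# design (series length K x reading SD).

# fast midrank AUC without input re-validation (hot loop)
auc_fast <- function(scores, pos) {
  n_pos <- sum(pos)
  n_neg <- length(pos) - n_pos
  r <- rank(scores)
  (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Bootstrap a diagnostic performance statistic
#'
#' Case bootstrap: resamples (score, label) pairs with replacement and
#' recomputes the statistic per replicate. `"auc"` is the C-statistic;
#' `"ccr"` is the correct classification rate at the fixed cut supplied in
#' `cut` (fixed before resampling, never re-optimised per replicate).
#' Resamples containing a single outcome class are rejected and redrawn;
#' the number of redraws is reported.
#'
#' @inheritParams auc
#' @param statistic `"auc"` or `"ccr"`.
#' @param R Number of bootstrap replicates; default 2000.
#' @param cut Decision cut for `"ccr"` (e.g. half of K); ignored for
#'   `"auc"`.
#' @param seed Optional seed.
#' @return An object of class `bootstrap_set`: list with `statistic`,
#'   `replicates` (length `R`, values in \[0, 1\]), `R`, `n`, `redraws`,
#'   `cut`, `seed`, and free-form `meta`. `tidy()` gives a tibble of
#'   replicates.
#' @export
bootstrap_statistic <- function(scores, labels,
                                statistic = c("auc", "ccr"),
                                R = 2000, cut = NULL, seed = NULL) {
  statistic <- match.arg(statistic)
  labels <- check_scores_labels(scores, labels)
  if (statistic == "ccr" && is.null(cut)) {
    rlang::abort("`cut` is required for the ccr statistic (fixed before resampling).")
  }
  n <- length(scores)
  stat_fun <- if (statistic == "auc") {
    function(s, l) auc_fast(s, l)
  } else {
    function(s, l) mean((s >= cut) == l)
  }
  redraws <- 0L
  replicates <- with_seed_if(seed, {
    vapply(seq_len(R), function(r) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        l <- labels[idx]
        if (any(l) && !all(l)) break
        redraws <<- redraws + 1L
      }
      stat_fun(scores[idx], l)
    }, numeric(1))
  })
  structure(
    list(statistic = statistic, replicates = replicates, R = as.integer(R),
         n = n, redraws = redraws, cut = cut, seed = seed, meta = list()),
    class = "bootstrap_set"
  )
}

#' @export
print.bootstrap_set <- function(x, ...) {
  cat("<bootstrap_set>", x$statistic, "| R =", x$R, "| n =", x$n, "\n")
  cat("  median =", format(stats::median(x$replicates), digits = 4),
      " IQR = [", format(stats::quantile(x$replicates, 0.25), digits = 4), ",",
      format(stats::quantile(x$replicates, 0.75), digits = 4), "]\n")
  if (x$redraws > 0) cat("  one-class resamples redrawn:", x$redraws, "\n")
  invisible(x)
}

#' Bootstrap every cell of a simulated design
#'
#' Runs [bootstrap_statistic()] in each (K, SD) cell of a
#' [run_simulation()] table, per channel. Scores are the high counts of
#' the channel; labels are its uncontrolledness; the `"ccr"` cut is half
#' of K. Each cell gets its own derived substream so cells reproduce
#' independently of one another.
#'
#' @param sim Tibble from [run_simulation()].
#' @param channel `"sbp"` or `"dbp"`.
#' @param statistic `"auc"` or `"ccr"`.
#' @param R Replicates per cell; default 2000.
#' @param seed Master seed (required).
#' @return Tibble `channel`, `statistic`, `k`, `sd_level`, `replicate`,
#'   `value` with `R` rows per cell — the tidy collection consumed by
#'   [compare_across_design()] and [plot_performance_by_design()].
#' @export
bootstrap_design <- function(sim, channel = c("sbp", "dbp"),
                             statistic = c("auc", "ccr"),
                             R = 2000, seed) {
  channel <- match.arg(channel)
  statistic <- match.arg(statistic)
  score_col <- paste0("high_", channel, "_count")
  label_col <- paste0("uncontrolled_", channel)
  stopifnot(all(c(score_col, label_col, "k", "sd_level") %in% names(sim)))
  cells <- dplyr::distinct(sim, .data$k, .data$sd_level) |>
    dplyr::arrange(.data$k, .data$sd_level)
  purrr::pmap(cells, function(k, sd_level) {
    cell <- sim[sim$k == k & sim$sd_level == sd_level, ]
    bs <- bootstrap_statistic(
      cell[[score_col]], cell[[label_col]],
      statistic = statistic, R = R,
      cut = if (statistic == "ccr") k / 2 else NULL,
      seed = derive_seed(seed, cell_stream_index(k, sd_level, offset = 5e5))
    )
    tibble::tibble(
      channel = channel, statistic = statistic,
      k = k, sd_level = sd_level,
      replicate = seq_len(R), value = bs$replicates
    )
  }) |>
    dplyr::bind_rows()
}

#' Compare performance across the design with a mixed model
#'
#' Fits a linear mixed-effects model to per-cell bootstrap replicates of a
#' performance statistic: fixed effects for K and SD (as numeric
#' covariates, optionally their interaction, or as factors via
#' `factor_coding`), and a random intercept per (K, SD) cell so replicate
#' values within a cell share their cell's deviation. P-values are
#' Wald-normal on the fixed-effect t-statistics.
#'
#' A table whose replicate values are all identical is degenerate: no
#' model is fit and a flagged zero-effect result is returned. A singular
#' mixed-model fit raises an error carrying the variance-component
#' diagnostics.
#'
#' @param replicates Tibble with columns `k`, `sd_level`, `value` (e.g.
#'   from [bootstrap_design()]).
#' @param include_interaction Include the K x SD interaction (default
#'   TRUE).
#' @param factor_coding Treat K and SD as unordered factors instead of
#'   numeric covariates (default FALSE).
#' @return An object of class `effect_comparison`: list with `fixed`
#'   (tibble `term`, `estimate`, `se`, `statistic`, `p_value`),
#'   `random_intercept_sd`, `residual_sd`, `n_obs`, `degenerate`,
#'   `model` (the `lmerMod`, or NULL when degenerate). `tidy()` returns
#'   `fixed`; `glance()` the model-level row.
#' @export
compare_across_design <- function(replicates, include_interaction = TRUE,
                                  factor_coding = FALSE) {
  stopifnot(all(c("k", "sd_level", "value") %in% names(replicates)))
  if (dplyr::n_distinct(replicates$k) < 2 ||
      dplyr::n_distinct(replicates$sd_level) < 2) {
    rlang::abort("need at least 2 distinct K and 2 distinct SD levels.")
  }
  dat <- tibble::tibble(
    value = replicates$value,
    k = if (factor_coding) factor(replicates$k) else as.numeric(replicates$k),
    sd_level = if (factor_coding) factor(replicates$sd_level) else as.numeric(replicates$sd_level),
    cell = interaction(replicates$k, replicates$sd_level, drop = TRUE)
  )
  if (stats::var(dat$value) == 0) {
    terms <- if (include_interaction) {
      c("(Intercept)", "k", "sd_level", "k:sd_level")
    } else {
      c("(Intercept)", "k", "sd_level")
    }
    fixed <- tibble::tibble(
      term = terms,
      estimate = c(dat$value[1], rep(0, length(terms) - 1)),
      se = 0, statistic = NA_real_, p_value = NA_real_
    )
    return(structure(
      list(fixed = fixed, random_intercept_sd = 0, residual_sd = 0,
           n_obs = nrow(dat), degenerate = TRUE, model = NULL,
           include_interaction = include_interaction),
      class = "effect_comparison"
    ))
  }
  form <- if (include_interaction) {
    value ~ k * sd_level + (1 | cell)
  } else {
    value ~ k + sd_level + (1 | cell)
  }
  fit <- lme4::lmer(form, data = dat, REML = TRUE)
  vc <- as.data.frame(lme4::VarCorr(fit))
  if (lme4::isSingular(fit)) {
    rlang::abort(
      c("singular mixed-model fit",
        paste0(vc$grp, " variance = ", signif(vc$vcov, 4), collapse = "; ")),
      class = "hbpcount_singular_fit"
    )
  }
  cf <- summary(fit)$coefficients
  fixed <- tibble::tibble(
    term = rownames(cf),
    estimate = cf[, "Estimate"],
    se = cf[, "Std. Error"],
    statistic = cf[, "t value"],
    p_value = 2 * stats::pnorm(-abs(cf[, "t value"]))
  )
  structure(
    list(
      fixed = fixed,
      random_intercept_sd = vc$sdcor[vc$grp == "cell"],
      residual_sd = vc$sdcor[vc$grp == "Residual"],
      n_obs = nrow(dat),
      degenerate = FALSE,
      model = fit,
      include_interaction = include_interaction
    ),
    class = "effect_comparison"
  )
}

#' @export
print.effect_comparison <- function(x, ...) {
  cat("<effect_comparison> n_obs =", x$n_obs,
      if (x$degenerate) "(degenerate: constant response)" else "", "\n")
  print(as.data.frame(x$fixed), row.names = FALSE, digits = 4)
  cat("random intercept SD (cell):", format(x$random_intercept_sd, digits = 4),
      "| residual SD:", format(x$residual_sd, digits = 4), "\n")
  invisible(x)
}

#' Compare two sets of replicate values
#'
#' Convenience wrapper around [stats::wilcox.test()] for comparing pooled
#' bootstrap distributions between channels (e.g. systolic vs diastolic
#' C-statistics), reporting medians, IQRs and the Mann-Whitney p-value.
#'
#' @param x,y Numeric replicate vectors.
#' @return One-row tibble: `median_x`, `iqr_lo_x`, `iqr_hi_x`, `median_y`,
#'   `iqr_lo_y`, `iqr_hi_y`, `p_value`.
#' @export
compare_replicate_sets <- function(x, y) {
  qx <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
  qy <- stats::quantile(y, c(0.25, 0.5, 0.75), names = FALSE)
  tibble::tibble(
    median_x = qx[2], iqr_lo_x = qx[1], iqr_hi_x = qx[3],
    median_y = qy[2], iqr_lo_y = qy[1], iqr_hi_y = qy[3],
    p_value = stats::wilcox.test(x, y)$p.value
  )
}
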
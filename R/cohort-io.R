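# Reading real HBPM cohort files, the standard exclusions (drop the first
# monitoring day, drop short series), Table-4-style stratification and the
# full validation evaluation of the C/T decision rule.

#' Read a long-format HBPM cohort CSV
#'
#' Expects one row per reading with patient id, ISO-8601 date, SBP and
#' DBP columns (names configurable). Malformed rows — unparseable date,
#' non-numeric or missing BP — are not silently dropped: they are
#' collected into a rejects report attached as the `"rejects"` attribute
#' (see [hbpm_rejects()]).
#'
#' @param path CSV file path.
#' @param col_patient,col_date,col_sbp,col_dbp Column names in the file.
#' @return Readings tibble `series_id`, `day` (Date), `sbp`, `dbp`,
#'   ordered by patient then date, ready for [apply_exclusions()] and
#'   [summarize_series()].
#' @export
read_hbpm_csv <- function(path, col_patient = "patient_id", col_date = "date",
                          col_sbp = "sbp", col_dbp = "dbp") {
  if (!file.exists(path)) {
    rlang::abort(paste0("file not found: ", path))
  }
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         comment = "#", progress = FALSE)
  needed <- c(col_patient, col_date, col_sbp, col_dbp)
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols) > 0) {
    rlang::abort(paste0("missing required column(s): ",
                        paste(missing_cols, collapse = ", ")))
  }
  day <- as.Date(raw[[col_date]], format = "%Y-%m-%d")
  sbp <- suppressWarnings(as.numeric(raw[[col_sbp]]))
  dbp <- suppressWarnings(as.numeric(raw[[col_dbp]]))
  bad_date <- is.na(day)
  bad_bp <- !is.finite(sbp) | !is.finite(dbp)
  bad_id <- is.na(raw[[col_patient]]) | raw[[col_patient]] == ""
  bad <- bad_date | bad_bp | bad_id
  rejects <- tibble::tibble(
    row = which(bad),
    reason = dplyr::case_when(
      bad_id[bad] ~ "missing patient id",
      bad_date[bad] ~ "unparseable date",
      TRUE ~ "non-numeric BP"
    ),
    raw = apply(raw[bad, , drop = FALSE], 1, paste, collapse = ",")
  )
  out <- tibble::tibble(
    series_id = raw[[col_patient]][!bad],
    day = day[!bad],
    sbp = sbp[!bad],
    dbp = dbp[!bad]
  ) |>
    dplyr::arrange(.data$series_id, .data$day)
  attr(out, "rejects") <- rejects
  out
}

#' Rejected rows of a cohort read
#'
#' @param readings Tibble returned by [read_hbpm_csv()].
#' @return Tibble of rejected rows (`row`, `reason`, `raw`).
#' @export
hbpm_rejects <- function(readings) {
  attr(readings, "rejects") %||% tibble::tibble(
    row = integer(), reason = character(), raw = character()
  )
}

#' Apply standard HBPM exclusions
#'
#' Two exclusions, in this order: (1) drop every reading taken on each
#' patient's first monitoring day (the earliest calendar day present in
#' their records) — first-day readings are conventionally discarded for
#' reproducibility; (2) drop patients left with fewer than `min_readings`
#' readings. The accounting is attached as attribute `"exclusion_log"`
#' (see [exclusion_log()]); excluded-patient count plus retained count
#' always equals the input count.
#'
#' @param readings Readings tibble with `series_id`, `sbp`, `dbp` and —
#'   when `drop_first_day` — a `day` column.
#' @param min_readings Minimum retained readings per patient; default 8.
#' @param drop_first_day Drop first-day readings first; default TRUE.
#'   Requesting it without day labels is an error, never a silent skip.
#' @return Filtered readings tibble with the exclusion log attached.
#' @export
apply_exclusions <- function(readings, min_readings = 8, drop_first_day = TRUE) {
  if (nrow(readings) == 0) {
    rlang::abort("empty cohort")
  }
  if (drop_first_day && !"day" %in% names(readings)) {
    rlang::abort("`drop_first_day = TRUE` but `readings` has no `day` column.")
  }
  n_in <- dplyr::n_distinct(readings$series_id)
  kept <- tibble::as_tibble(readings)
  n_first_day <- 0L
  if (drop_first_day) {
    kept <- kept |>
      dplyr::group_by(.data$series_id) |>
      dplyr::filter(.data$day != min(.data$day)) |>
      dplyr::ungroup()
    n_first_day <- nrow(readings) - nrow(kept)
  }
  counts <- dplyr::count(kept, .data$series_id)
  short <- counts$series_id[counts$n < min_readings]
  # patients whose every reading fell on day one vanish from `kept`;
  # they are short series too
  gone <- setdiff(unique(readings$series_id), counts$series_id)
  excluded <- sort(unique(c(short, gone)))
  out <- kept[!kept$series_id %in% excluded, , drop = FALSE]
  attr(out, "exclusion_log") <- tibble::tibble(
    n_patients_in = n_in,
    n_first_day_readings_removed = n_first_day,
    n_patients_excluded = length(excluded),
    n_patients_retained = n_in - length(excluded),
    min_readings = min_readings,
    drop_first_day = drop_first_day,
    excluded_patients = list(excluded)
  )
  out
}

#' Exclusion accounting of a filtered cohort
#'
#' @param readings Tibble returned by [apply_exclusions()].
#' @return One-row tibble of counts (see [apply_exclusions()]).
#' @export
exclusion_log <- function(readings) {
  log <- attr(readings, "exclusion_log")
  if (is.null(log)) {
    rlang::abort("no exclusion log attached; run apply_exclusions() first.")
  }
  log
}

#' Define a stratification variable
#'
#' Bins a per-series summary variable at ordered cutpoints. Bins are
#' half-open `[low, high)`: below the first cut, between consecutive
#' cuts, and at-or-above the last cut — so printed bounds like
#' "10-14.9 mmHg" become `[10, 15)` and values such as 14.95 are not
#' orphaned.
#'
#' @param variable Summary column to bin (`k`, `sd_sbp`, `sd_dbp`,
#'   `range_sbp`, `range_dbp`, `mean_sbp`, `mean_dbp`).
#' @param bounds Strictly increasing interior cutpoints.
#' @param labels One label per bin (`length(bounds) + 1`).
#' @return An object of class `stratum_definition`.
#' @export
stratum_definition <- function(variable, bounds, labels) {
  if (is.unsorted(bounds, strictly = TRUE)) {
    rlang::abort("`bounds` must be strictly increasing (overlapping bins are not allowed).")
  }
  if (length(labels) != length(bounds) + 1) {
    rlang::abort("need exactly length(bounds) + 1 labels.")
  }
  structure(list(variable = variable, bounds = bounds, labels = labels),
            class = "stratum_definition")
}

#' Default validation strata
#'
#' The stratification grid of the validation analysis: series length K
#' (8-15, 16-23, >= 24 readings), within-series SDs (systolic cuts 10 and
#' 15 mmHg; diastolic 7 and 10 mmHg), reading ranges (max - min; systolic
#' cuts 40 and 60, diastolic 30 and 45 mmHg) and near-target mean-BP bands
#' (\[130, 140) systolic, \[80, 90) diastolic).
#'
#' @return Named list of [stratum_definition()]s.
#' @export
default_strata <- function() {
  list(
    k = stratum_definition("k", c(16, 24), c("8-15", "16-23", ">=24")),
    sd_sbp = stratum_definition("sd_sbp", c(10, 15), c("<10", "10-14.9", ">=15")),
    sd_dbp = stratum_definition("sd_dbp", c(7, 10), c("<7", "7-9.9", ">=10")),
    range_sbp = stratum_definition("range_sbp", c(40, 60), c("<40", "40-59", ">=60")),
    range_dbp = stratum_definition("range_dbp", c(30, 45), c("<30", "30-44", ">=45")),
    mean_sbp = stratum_definition("mean_sbp", c(130, 140), c("<130", "130-139", ">=140")),
    mean_dbp = stratum_definition("mean_dbp", c(80, 90), c("<80", "80-89", ">=90"))
  )
}

#' Assign strata to series summaries
#'
#' Adds one `<variable>_stratum` factor column per definition.
#'
#' @param summaries Tibble from [summarize_series()].
#' @param definitions List of [stratum_definition()]s; default
#'   [default_strata()].
#' @return `summaries` with stratum columns appended.
#' @export
stratify <- function(summaries, definitions = default_strata()) {
  for (def in definitions) {
    if (!def$variable %in% names(summaries)) {
      rlang::abort(paste0("summary column not found: ", def$variable))
    }
    breaks <- c(-Inf, def$bounds, Inf)
    summaries[[paste0(def$variable, "_stratum")]] <-
      cut(summaries[[def$variable]], breaks = breaks, labels = def$labels,
          right = FALSE)
  }
  summaries
}

# one evaluation row: C/T ratio vs uncontrolledness in a subset
evaluate_subset <- function(summaries, channel, ratio_cut) {
  ct <- summaries[[paste0("ct_", channel)]]
  lab <- summaries[[paste0("uncontrolled_", channel)]]
  n <- length(lab)
  n_pos <- sum(lab)
  one_class <- n_pos == 0 || n_pos == n
  # confusion matrix computed directly so one-class strata keep the
  # indices that remain defined (C-statistic alone becomes unavailable)
  pred <- ct >= ratio_cut
  tp <- sum(pred & lab); fp <- sum(pred & !lab)
  tn <- sum(!pred & !lab); fn <- sum(!pred & lab)
  safe_div <- function(a, b) if (b > 0) a / b else NA_real_
  idx <- tibble::tibble(
    sensitivity = safe_div(tp, tp + fn),
    specificity = safe_div(tn, tn + fp),
    ppv = safe_div(tp, tp + fp),
    npv = safe_div(tn, tn + fn),
    ccr = (tp + tn) / n
  )
  if (one_class || n_pos < 2 || (n - n_pos) < 2 ||
      stats::var(ct) == 0) {
    aucs <- tibble::tibble(auc = NA_real_, auc_lo = NA_real_,
                           auc_hi = NA_real_, auc_available = FALSE)
  } else {
    ci <- suppressWarnings(delong_ci(ct, lab))
    aucs <- tibble::tibble(auc = attr(ci, "auc"), auc_lo = ci[["low"]],
                           auc_hi = ci[["high"]], auc_available = TRUE)
  }
  dplyr::bind_cols(tibble::tibble(n = n, n_uncontrolled = n_pos), idx, aucs)
}

#' Evaluate the C/T decision rule on a cohort
#'
#' Runs the full validation analysis on a (post-exclusion) readings
#' table: per channel, the C-statistic of the C/T ratio for
#' uncontrolledness with its DeLong CI and the diagnostic indices of the
#' rule C/T >= `ratio_cut`, overall and within every stratum of
#' `strata`. Strata with a single outcome class keep their counts but
#' have the C-statistic marked unavailable.
#'
#' @param readings Readings tibble (after [apply_exclusions()]).
#' @param target A [bp_target()].
#' @param strata List of [stratum_definition()]s; default
#'   [default_strata()].
#' @param ratio_cut C/T decision cut; default 0.5.
#' @return An object of class `validation_report`: a tibble with columns
#'   `channel`, `variable` (`"overall"` or the stratification variable),
#'   `stratum`, `n`, `n_uncontrolled`, the five indices, `auc`,
#'   `auc_lo`, `auc_hi`, `auc_available`; the per-series summaries are
#'   attached as attribute `"summaries"`.
#' @export
evaluate_validation <- function(readings, target = bp_target(),
                                strata = default_strata(), ratio_cut = 0.5) {
  summaries <- summarize_series(readings, target = target)
  summaries <- stratify(summaries, strata)
  channels <- c("sbp", "dbp")
  rows <- purrr::map(channels, function(ch) {
    overall <- dplyr::bind_cols(
      tibble::tibble(channel = ch, variable = "overall", stratum = "overall"),
      evaluate_subset(summaries, ch, ratio_cut)
    )
    per_stratum <- purrr::imap(strata, function(def, name) {
      col <- paste0(def$variable, "_stratum")
      split(summaries, summaries[[col]]) |>
        purrr::imap(function(sub, lvl) {
          if (nrow(sub) == 0) return(NULL)
          dplyr::bind_cols(
            tibble::tibble(channel = ch, variable = def$variable, stratum = lvl),
            evaluate_subset(sub, ch, ratio_cut)
          )
        }) |>
        dplyr::bind_rows()
    }) |>
      dplyr::bind_rows()
    dplyr::bind_rows(overall, per_stratum)
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "summaries") <- summaries
  attr(out, "ratio_cut") <- ratio_cut
  class(out) <- c("validation_report", class(out))
  out
}

#' Per-series summaries behind a validation report
#'
#' @param report A `validation_report` from [evaluate_validation()].
#' @return The stratified [summarize_series()] tibble the report was
#'   computed from.
#' @export
validation_summaries <- function(report) {
  attr(report, "summaries")
}
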
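#' Blood pressure control target
#'
#' Defines the home blood pressure target against which individual readings
#' and series means are judged. The conventional home target is
#' 135/85 mmHg; a reading (or a series mean) at or above either cut is
#' "high" (or "uncontrolled") in the corresponding channel. Comparisons are
#' inclusive (`>=`) throughout the package.
#'
#' @param sbp_cut Systolic cut in mmHg (default 135).
#' @param dbp_cut Diastolic cut in mmHg (default 85).
#'
#' @return An object of class `bp_target`: a named list with elements
#'   `sbp_cut` and `dbp_cut`.
#' @examples
#' bp_target()
#' bp_target(140, 90) # office-style target
#' @export
bp_target <- function(sbp_cut = 135, dbp_cut = 85) {
  if (!is.numeric(sbp_cut) || !is.numeric(dbp_cut) ||
      length(sbp_cut) != 1L || length(dbp_cut) != 1L) {
    rlang::abort("`sbp_cut` and `dbp_cut` must be single numbers.")
  }
  if (!is.finite(sbp_cut) || !is.finite(dbp_cut) || sbp_cut <= 0 || dbp_cut <= 0) {
    rlang::abort("BP cuts must be finite and positive.")
  }
  if (sbp_cut <= dbp_cut) {
    rlang::abort("`sbp_cut` must exceed `dbp_cut` (systolic > diastolic).")
  }
  structure(list(sbp_cut = sbp_cut, dbp_cut = dbp_cut), class = "bp_target")
}

#' @export
print.bp_target <- function(x, ...) {
  cat("<bp_target> SBP >=", x$sbp_cut, "mmHg, DBP >=", x$dbp_cut, "mmHg\n")
  invisible(x)
}

# Validate a long readings table: series_id, sbp, dbp, optional day.
# Readings must be finite and inside the plausibility window; day labels,
# when present, must be non-decreasing within each series.
validate_readings <- function(readings, plausible = c(30, 300)) {
  if (!is.data.frame(readings)) {
    rlang::abort("`readings` must be a data frame.")
  }
  missing_cols <- setdiff(c("sbp", "dbp"), names(readings))
  if (length(missing_cols) > 0) {
    rlang::abort(paste0(
      "`readings` lacks required column(s): ",
      paste(missing_cols, collapse = ", ")
    ))
  }
  if (nrow(readings) == 0L) {
    rlang::abort("empty series")
  }
  readings <- tibble::as_tibble(readings)
  if (!"series_id" %in% names(readings)) {
    readings$series_id <- "series1"
  }
  for (ch in c("sbp", "dbp")) {
    v <- readings[[ch]]
    if (!is.numeric(v)) {
      rlang::abort(paste0("`", ch, "` must be numeric."))
    }
    bad <- which(!is.finite(v))
    if (length(bad) > 0) {
      rlang::abort(paste0(
        "non-finite ", ch, " reading at index ", bad[1],
        " (series ", readings$series_id[bad[1]], ")"
      ))
    }
    out_of_window <- which(v < plausible[1] | v > plausible[2])
    if (length(out_of_window) > 0) {
      rlang::abort(paste0(
        ch, " reading at index ", out_of_window[1], " (",
        v[out_of_window[1]], " mmHg) is outside the plausibility window [",
        plausible[1], ", ", plausible[2], "] mmHg"
      ))
    }
  }
  if ("day" %in% names(readings)) {
    ok <- vapply(
      split(readings$day, readings$series_id),
      function(d) !is.unsorted(d),
      logical(1)
    )
    if (!all(ok)) {
      rlang::abort(paste0(
        "day labels must be non-decreasing within a series (series ",
        names(ok)[!ok][1], ")"
      ))
    }
  }
  readings
}

#' Summarise blood pressure series
#'
#' Reduces a long table of readings (one row per reading) to one row per
#' series carrying the count-based decision statistics: the number of
#' readings `k` (the total T), per-channel means, sample standard
#' deviations and ranges, the high-reading counts C (readings at or above
#' the target cut, channel by channel), the C/T ratios, and the reference
#' controlledness labels (series mean at or above the cut).
#'
#' @param readings Data frame with columns `sbp` and `dbp` (mmHg), an
#'   optional `series_id` (a single series is assumed when absent) and an
#'   optional `day` label (dates or day indices, non-decreasing within a
#'   series).
#' @param target A [bp_target()].
#' @param include_any Also compute a non-canonical any-channel high count
#'   (`high_any_count`, `ct_any`): readings high in either channel. The
#'   canonical statistics are per-channel; this variant exists because
#'   "high reading" is sometimes read as a single combined definition.
#' @param sd_type `"sample"` (n-1 denominator, default) or `"population"`.
#' @param plausible Plausibility window for readings in mmHg.
#'
#' @return A tibble with one row per series: `series_id`, `k`, `mean_sbp`,
#'   `mean_dbp`, `sd_sbp`, `sd_dbp`, `range_sbp`, `range_dbp`,
#'   `high_sbp_count`, `high_dbp_count`, `ct_sbp`, `ct_dbp`,
#'   `uncontrolled_sbp`, `uncontrolled_dbp`, `uncontrolled_any`.
#' @examples
#' readings <- tibble::tibble(
#'   series_id = "pt1",
#'   sbp = c(130, 140, 136, 128, 135, 120, 150, 129),
#'   dbp = c(80, 85, 82, 78, 84, 75, 90, 79)
#' )
#' summarize_series(readings)
#' @export
summarize_series <- function(readings, target = bp_target(),
                             include_any = FALSE,
                             sd_type = c("sample", "population"),
                             plausible = c(30, 300)) {
  sd_type <- match.arg(sd_type)
  stopifnot(inherits(target, "bp_target"))
  readings <- validate_readings(readings, plausible = plausible)

  sd_fun <- if (sd_type == "sample") {
    stats::sd
  } else {
    function(x) sqrt(mean((x - mean(x))^2))
  }

  out <- readings |>
    dplyr::group_by(.data$series_id) |>
    dplyr::summarise(
      k = dplyr::n(),
      mean_sbp = mean(.data$sbp),
      mean_dbp = mean(.data$dbp),
      sd_sbp = sd_fun(.data$sbp),
      sd_dbp = sd_fun(.data$dbp),
      range_sbp = max(.data$sbp) - min(.data$sbp),
      range_dbp = max(.data$dbp) - min(.data$dbp),
      high_sbp_count = sum(.data$sbp >= target$sbp_cut),
      high_dbp_count = sum(.data$dbp >= target$dbp_cut),
      high_any_count = sum(.data$sbp >= target$sbp_cut |
                             .data$dbp >= target$dbp_cut),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      ct_sbp = .data$high_sbp_count / .data$k,
      ct_dbp = .data$high_dbp_count / .data$k,
      ct_any = .data$high_any_count / .data$k,
      uncontrolled_sbp = .data$mean_sbp >= target$sbp_cut,
      uncontrolled_dbp = .data$mean_dbp >= target$dbp_cut,
      uncontrolled_any = .data$uncontrolled_sbp | .data$uncontrolled_dbp
    )
  if (!include_any) {
    out <- dplyr::select(out, -"high_any_count", -"ct_any")
  }
  out
}

#' Half-of-K count decision
#'
#' Applies the count-based decision rule to series summaries: a channel is
#' flagged uncontrolled when its C/T ratio is at least `ratio_cut`
#' (default 0.5, the half-of-K rule: count >= ceiling(k/2); at the even
#' series lengths 16/20/24 this is a count of at least 8/10/12).
#'
#' @param summaries A tibble from [summarize_series()] (or any table with
#'   `ct_sbp` and `ct_dbp` columns).
#' @param ratio_cut Decision cut on the C/T ratio (default 0.5).
#'
#' @return The input with logical columns `sbp_flag`, `dbp_flag`,
#'   `any_flag` appended.
#' @examples
#' readings <- tibble::tibble(sbp = rep(c(140, 130), 8), dbp = rep(80, 16))
#' readings |> summarize_series() |> count_rule_decision()
#' @export
count_rule_decision <- function(summaries, ratio_cut = 0.5) {
  if (!all(c("ct_sbp", "ct_dbp") %in% names(summaries))) {
    rlang::abort("`summaries` needs `ct_sbp` and `ct_dbp` columns; see summarize_series().")
  }
  if (!is.numeric(ratio_cut) || length(ratio_cut) != 1L ||
      ratio_cut <= 0 || ratio_cut > 1) {
    rlang::abort("`ratio_cut` must be a single value in (0, 1].")
  }
  dplyr::mutate(
    tibble::as_tibble(summaries),
    sbp_flag = .data$ct_sbp >= ratio_cut,
    dbp_flag = .data$ct_dbp >= ratio_cut,
    any_flag = .data$sbp_flag | .data$dbp_flag
  )
}

#' Read or write readings as JSON records
#'
#' Serialises a long readings table to an array of JSON records (one per
#' reading, field names as in the data model) and back. Intended for
#' machine interchange with non-R front ends.
#'
#' @param readings A readings data frame (see [summarize_series()]).
#' @param path File path.
#' @return `write_series_json()` returns `path` invisibly;
#'   `read_series_json()` returns a tibble of readings.
#' @export
write_series_json <- function(readings, path) {
  readings <- validate_readings(readings)
  jsonlite::write_json(readings, path, dataframe = "rows",
                       auto_unbox = TRUE, digits = NA, Date = "ISO8601")
  invisible(path)
}

#' @rdname write_series_json
#' @export
read_series_json <- function(path) {
  out <- tibble::as_tibble(jsonlite::read_json(path, simplifyVector = TRUE))
  if ("day" %in% names(out) && is.character(out$day)) {
    parsed <- as.Date(out$day, format = "%Y-%m-%d")
    if (!anyNA(parsed)) out$day <- parsed
  }
  validate_readings(out)
}
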
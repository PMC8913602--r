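# Factorial simulation of home BP series. The design emulates the
# clinically hard region: true mean SBP uniform on [130, 140) mmHg and
# mean DBP uniform on [80, 90) mmHg, i.e. straddling the 135/85 target;
# readings are independent Gaussians around the case mean at four SD
# levels, with DBP spread fixed at 70% of the systolic SD; series lengths
# K = 16/20/24 mirror 2 readings/day over 8-12 days.

#' Factorial simulation design
#'
#' Parameters of the simulated-series study: number of cases per design
#' cell, series lengths (K), systolic reading SD levels, the
#' diastolic-to-systolic SD ratio, and the uniform ranges the true case
#' means are drawn from. The same case means are reused in every (K, SD)
#' cell, so cells differ only in series length and noise.
#'
#' @param n_cases Cases (series) per cell; default 100.
#' @param k_values Series lengths; default `c(16, 20, 24)`.
#' @param sd_levels_sbp Within-series SBP reading SDs in mmHg; default
#'   `c(5, 10, 15, 20)`. The DBP SDs are these times `dbp_sd_ratio`
#'   (3.5, 7, 10.5, 14 at the defaults).
#' @param dbp_sd_ratio DBP SD as a fraction of the SBP SD; default 0.7.
#' @param mean_sbp_range,mean_dbp_range Uniform ranges (mmHg) for the true
#'   case means; defaults `c(130, 140)` and `c(80, 90)`.
#' @param seed Optional integer seed recorded with the design.
#' @return An object of class `simulation_design` (named list).
#' @export
simulation_design <- function(n_cases = 100,
                              k_values = c(16, 20, 24),
                              sd_levels_sbp = c(5, 10, 15, 20),
                              dbp_sd_ratio = 0.7,
                              mean_sbp_range = c(130, 140),
                              mean_dbp_range = c(80, 90),
                              seed = NULL) {
  stopifnot(
    n_cases >= 2,
    length(k_values) >= 1, all(k_values >= 1),
    length(sd_levels_sbp) >= 1, all(sd_levels_sbp > 0),
    dbp_sd_ratio > 0, dbp_sd_ratio <= 1,
    length(mean_sbp_range) == 2, diff(mean_sbp_range) >= 0,
    length(mean_dbp_range) == 2, diff(mean_dbp_range) >= 0
  )
  structure(
    list(
      n_cases = as.integer(n_cases),
      k_values = as.integer(k_values),
      sd_levels_sbp = as.numeric(sd_levels_sbp),
      dbp_sd_ratio = dbp_sd_ratio,
      mean_sbp_range = as.numeric(mean_sbp_range),
      mean_dbp_range = as.numeric(mean_dbp_range),
      seed = seed
    ),
    class = "simulation_design"
  )
}

# Deterministic substream seed: spreads a master seed over indexed
# substreams while staying inside 32-bit integer range.
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 1103 + as.numeric(index) * 7919) %% 2147483647)
}

# substream index from a cell's identity (not its position), so a cell
# reproduces even when other cells are absent from the run
cell_stream_index <- function(k, sd_level, offset = 0) {
  offset + k * 1000 + round(sd_level * 10)
}

with_seed_if <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(seed, code)
}

#' Draw true case means
#'
#' Samples `n_cases` (mean SBP, mean DBP) pairs uniformly on the design
#' ranges. These are the latent series means around which readings are
#' generated; the identical set of pairs is reused across all (K, SD)
#' cells of the factorial design.
#'
#' @param design A [simulation_design()].
#' @param seed Seed (defaults to the design's).
#' @return Tibble `case_id`, `mean_sbp`, `mean_dbp` with `n_cases` rows.
#' @export
sample_mean_bps <- function(design, seed = design$seed) {
  stopifnot(inherits(design, "simulation_design"))
  with_seed_if(seed, {
    tibble::tibble(
      case_id = seq_len(design$n_cases),
      mean_sbp = stats::runif(design$n_cases,
                              design$mean_sbp_range[1], design$mean_sbp_range[2]),
      mean_dbp = stats::runif(design$n_cases,
                              design$mean_dbp_range[1], design$mean_dbp_range[2])
    )
  })
}

#' Generate one simulated series
#'
#' Draws `k` paired readings around a case mean: SBP ~ Normal(mean_sbp,
#' sd_sbp), DBP ~ Normal(mean_dbp, sd_sbp * dbp_sd_ratio), independent
#' across readings and channels. Readings are left unrounded.
#'
#' @param mean_sbp,mean_dbp True series means in mmHg.
#' @param k Number of readings.
#' @param sd_sbp Systolic reading SD in mmHg.
#' @param dbp_sd_ratio DBP SD as a fraction of `sd_sbp` (default 0.7).
#' @param series_id Series identifier for the output table.
#' @return Tibble `series_id`, `reading_index`, `sbp`, `dbp`.
#' @export
generate_series <- function(mean_sbp, mean_dbp, k, sd_sbp,
                            dbp_sd_ratio = 0.7, series_id = "series1") {
  stopifnot(k >= 1, sd_sbp > 0)
  tibble::tibble(
    series_id = series_id,
    reading_index = seq_len(k),
    sbp = stats::rnorm(k, mean = mean_sbp, sd = sd_sbp),
    dbp = stats::rnorm(k, mean = mean_dbp, sd = sd_sbp * dbp_sd_ratio)
  )
}

#' Run the factorial simulation
#'
#' Draws the case means once, then for every (K, SD) cell generates one
#' series per case and summarises it against `target`. With the default
#' design this yields 100 cases x 3 K values x 4 SD levels = 1200 series.
#'
#' Each cell runs on its own substream derived from the master seed and
#' the cell's identity (K, SD), so a cell's content does not depend on
#' which other cells are generated.
#'
#' @param design A [simulation_design()].
#' @param target A [bp_target()].
#' @param keep_readings Attach the raw readings as attribute `"readings"`.
#' @param seed Master seed (defaults to the design's).
#' @return Tibble with one row per case x K x SD: `case_id`, `k`,
#'   `sd_level` (systolic SD; the diastolic SD is `sd_level *
#'   dbp_sd_ratio`), the true means `true_mean_sbp`, `true_mean_dbp`, and
#'   all [summarize_series()] columns.
#' @examples
#' sim <- run_simulation(simulation_design(n_cases = 10), seed = 1)
#' nrow(sim) # 10 * 3 * 4
#' @export
run_simulation <- function(design = simulation_design(),
                           target = bp_target(),
                           keep_readings = FALSE,
                           seed = design$seed) {
  stopifnot(inherits(design, "simulation_design"))
  if (is.null(seed)) {
    rlang::abort("`seed` is required (set it here or in the design) for a reproducible run.")
  }
  means <- sample_mean_bps(design, seed = derive_seed(seed, 0))

  cells <- tidyr::expand_grid(k = design$k_values, sd_level = design$sd_levels_sbp)

  per_cell <- purrr::pmap(cells, function(k, sd_level) {
    withr::with_seed(derive_seed(seed, cell_stream_index(k, sd_level)), {
      n <- design$n_cases
      # k readings per case, cases in contiguous blocks
      sbp_v <- stats::rnorm(n * k, mean = rep(means$mean_sbp, each = k), sd = sd_level)
      dbp_v <- stats::rnorm(n * k, mean = rep(means$mean_dbp, each = k),
                            sd = sd_level * design$dbp_sd_ratio)
      ids <- sprintf("case%04d_k%02d_sd%g", rep(means$case_id, each = k), k, sd_level)
      idx <- rep(seq_len(k), times = n)
      tibble::tibble(
        series_id = ids,
        case_id = rep(means$case_id, each = k),
        k = k,
        sd_level = sd_level,
        reading_index = idx,
        sbp = sbp_v,
        dbp = dbp_v
      )
    })
  })
  readings <- dplyr::bind_rows(per_cell)

  summaries <- readings |>
    summarize_series(target = target, plausible = c(-Inf, Inf)) |>
    dplyr::left_join(
      dplyr::distinct(readings, .data$series_id, .data$case_id, .data$k, .data$sd_level),
      by = "series_id"
    ) |>
    dplyr::left_join(
      dplyr::rename(means, true_mean_sbp = "mean_sbp", true_mean_dbp = "mean_dbp"),
      by = "case_id"
    ) |>
    dplyr::select(
      "series_id", "case_id", k = "k.y", "sd_level",
      "true_mean_sbp", "true_mean_dbp",
      dplyr::everything(), -"k.x"
    ) |>
    dplyr::arrange(.data$k, .data$sd_level, .data$case_id)

  if (keep_readings) {
    attr(summaries, "readings") <- readings
  }
  summaries
}
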
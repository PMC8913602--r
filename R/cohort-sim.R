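# Synthetic HBPM cohort generator. Emulates the hierarchical structure of
# a real monitored cohort of treated hypertensives: patient-level true
# means drawn from a correlated bivariate normal, patient-specific
# within-series reading SDs drawn log-normally (positivity), series
# lengths varying patient by patient, and readings grouped into calendar
# days so a first-day exclusion is exercisable.

#' Synthetic cohort design
#'
#' Parameters of the synthetic home-monitoring cohort. Defaults emulate a
#' treated-hypertensive clinic cohort: 424 enrolled patients of whom a
#' small low-adherence tail records fewer than 8 readings after the first
#' day (and is dropped by the standard exclusions, leaving about 412);
#' patient mean SBP ~ Normal(128.2, 14.8) mmHg and mean DBP ~
#' Normal(79.9, 9.7) mmHg with correlation 0.6 across channels; mean
#' within-patient reading SDs of 11.8 (systolic) and 8.0 (diastolic) mmHg;
#' 8-70 readings per patient at 2 per day.
#'
#' @param n_patients Patients enrolled (before exclusions); default 424.
#' @param mean_sbp,mean_dbp Length-2 `c(mean, sd)` of the patient-level
#'   true mean distributions (mmHg).
#' @param mean_correlation Correlation between a patient's SBP and DBP
#'   means; default 0.6.
#' @param within_sd_sbp,within_sd_dbp Mean of the log-normal within-patient
#'   reading SD distributions (mmHg); defaults 11.8 and 8.0.
#' @param within_sd_cv Coefficient of variation of the within-patient SD
#'   distributions; default 0.3.
#' @param k_log_mean,k_log_sd Log-scale location/spread of the series
#'   length distribution (readings kept after the first day), truncated to
#'   `k_range`; defaults give a median near 20 with most mass in 10-40.
#' @param k_range Range of post-first-day series lengths; default
#'   `c(8, 70)`.
#' @param low_k_prob Probability a patient is a low-adherence recorder with
#'   only 6-7 post-first-day readings (excluded downstream); default
#'   12/424.
#' @param readings_per_day Readings per calendar day; default 2
#'   (morning/evening style duplication).
#' @param start_date First monitoring date; default `"2018-01-01"`.
#' @param round_readings Round readings to integer mmHg as consumer
#'   devices display them; default FALSE (raw Gaussian values).
#' @param seed Optional integer seed recorded with the design.
#' @return An object of class `cohort_design` (named list).
#' @export
cohort_design <- function(n_patients = 424,
                          mean_sbp = c(128.2, 14.8),
                          mean_dbp = c(79.9, 9.7),
                          mean_correlation = 0.6,
                          within_sd_sbp = 11.8,
                          within_sd_dbp = 8.0,
                          within_sd_cv = 0.3,
                          k_log_mean = log(20),
                          k_log_sd = 0.35,
                          k_range = c(8, 70),
                          low_k_prob = 12 / 424,
                          readings_per_day = 2,
                          start_date = as.Date("2018-01-01"),
                          round_readings = FALSE,
                          seed = NULL) {
  stopifnot(
    n_patients >= 1,
    length(mean_sbp) == 2, mean_sbp[2] > 0,
    length(mean_dbp) == 2, mean_dbp[2] > 0,
    abs(mean_correlation) < 1,
    within_sd_sbp > 0, within_sd_dbp > 0, within_sd_cv > 0,
    k_range[1] >= 1, k_range[2] >= k_range[1],
    low_k_prob >= 0, low_k_prob < 1,
    readings_per_day >= 1
  )
  structure(
    list(
      n_patients = as.integer(n_patients),
      mean_sbp = mean_sbp, mean_dbp = mean_dbp,
      mean_correlation = mean_correlation,
      within_sd_sbp = within_sd_sbp, within_sd_dbp = within_sd_dbp,
      within_sd_cv = within_sd_cv,
      k_log_mean = k_log_mean, k_log_sd = k_log_sd,
      k_range = as.integer(k_range),
      low_k_prob = low_k_prob,
      readings_per_day = as.integer(readings_per_day),
      start_date = as.Date(start_date),
      round_readings = round_readings,
      seed = seed
    ),
    class = "cohort_design"
  )
}

# log-normal with a given arithmetic mean and coefficient of variation
rlnorm_mean_cv <- function(n, mean, cv) {
  sdlog <- sqrt(log(1 + cv^2))
  meanlog <- log(mean) - sdlog^2 / 2
  stats::rlnorm(n, meanlog = meanlog, sdlog = sdlog)
}

#' Generate a synthetic HBPM cohort
#'
#' Per patient: draw the series length, the correlated pair of true mean
#' BPs, the within-patient reading SDs, then Gaussian readings assigned to
#' consecutive calendar days (`readings_per_day` per day, after a full
#' first day that the standard exclusions will drop).
#'
#' @param design A [cohort_design()].
#' @param seed Seed (defaults to the design's).
#' @return Tibble of readings: `patient_id`, `date`, `sbp`, `dbp`, one row
#'   per reading, ordered by patient and date. Feed to
#'   [apply_exclusions()] / [evaluate_validation()] or write with
#'   [readr::write_csv()] for the `read_hbpm_csv()` dialect.
#' @examples
#' cohort <- generate_synthetic_cohort(cohort_design(n_patients = 5), seed = 1)
#' dplyr::count(cohort, patient_id)
#' @export
generate_synthetic_cohort <- function(design = cohort_design(),
                                      seed = design$seed) {
  stopifnot(inherits(design, "cohort_design"))
  if (is.null(seed)) {
    rlang::abort("`seed` is required (set it here or in the design) for a reproducible cohort.")
  }
  withr::with_seed(seed, {
    n <- design$n_patients
    # series length after the first day
    low <- stats::runif(n) < design$low_k_prob
    k_after <- integer(n)
    k_after[low] <- sample(c(6L, 7L), sum(low), replace = TRUE)
    k_main <- round(stats::rlnorm(sum(!low), design$k_log_mean, design$k_log_sd))
    k_after[!low] <- pmin(pmax(k_main, design$k_range[1]), design$k_range[2])

    # correlated patient-level true means
    z1 <- stats::rnorm(n)
    z2 <- stats::rnorm(n)
    rho <- design$mean_correlation
    mu_sbp <- design$mean_sbp[1] + design$mean_sbp[2] * z1
    mu_dbp <- design$mean_dbp[1] + design$mean_dbp[2] * (rho * z1 + sqrt(1 - rho^2) * z2)

    sd_sbp <- rlnorm_mean_cv(n, design$within_sd_sbp, design$within_sd_cv)
    sd_dbp <- rlnorm_mean_cv(n, design$within_sd_dbp, design$within_sd_cv)

    rpd <- design$readings_per_day
    per_patient <- purrr::map(seq_len(n), function(i) {
      k_total <- rpd + k_after[i] # full first day + retained readings
      day_idx <- c(rep(0L, rpd), (seq_len(k_after[i]) - 1L) %/% rpd + 1L)
      tibble::tibble(
        patient_id = sprintf("pt%04d", i),
        date = design$start_date + day_idx,
        sbp = stats::rnorm(k_total, mu_sbp[i], sd_sbp[i]),
        dbp = stats::rnorm(k_total, mu_dbp[i], sd_dbp[i])
      )
    })
    out <- dplyr::bind_rows(per_patient)
    # monitors cannot record outside the plausibility window; clamp the
    # rare (<1e-4) Gaussian tail draws so every reading is device-valid
    out$sbp <- pmin(pmax(out$sbp, 30), 300)
    out$dbp <- pmin(pmax(out$dbp, 30), 300)
    if (design$round_readings) {
      out$sbp <- round(out$sbp)
      out$dbp <- round(out$dbp)
    }
    out
  })
}
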
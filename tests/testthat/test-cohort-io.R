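test_that("cohort CSV reader groups readings and reports rejects", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "patient_id,date,sbp,dbp",
    "p1,2020-01-01,132,81",
    "p1,2020-01-01,128,79",
    "p1,2020-01-02,140,88",
    "p2,2020-01-01,abc,80",
    "p2,not-a-date,120,70",
    ",2020-01-03,120,70"
  ), path)
  coh <- read_hbpm_csv(path)
  expect_equal(nrow(coh), 3)
  expect_equal(unique(coh$series_id), "p1")
  expect_s3_class(coh$day, "Date")
  rej <- hbpm_rejects(coh)
  expect_equal(nrow(rej), 3)
  expect_setequal(rej$reason,
                  c("non-numeric BP", "unparseable date", "missing patient id"))

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,when,s,d", "p1,2020-01-01,120,70"), bad)
  expect_error(read_hbpm_csv(bad), "missing required column")
  expect_equal(nrow(read_hbpm_csv(bad, "id", "when", "s", "d")), 1)
  expect_error(read_hbpm_csv("/nonexistent.csv"), "not found")
})

test_that("exclusions drop the first day, then short series, with full accounting", {
  mk <- function(id, days_counts) {
    purrr::imap(days_counts, function(nn, d) {
      tibble::tibble(series_id = id,
                     day = as.Date("2020-01-01") + as.integer(d),
                     sbp = rep(130, nn), dbp = rep(80, nn))
    }) |> dplyr::bind_rows()
  }
  # p1: 2 readings on day one + 8 later -> retained with 8
  # p2: 2 + 5 -> dropped (5 < 8); p3: all 10 on day one -> dropped
  coh <- dplyr::bind_rows(
    mk("p1", c("0" = 2, "1" = 4, "2" = 4)),
    mk("p2", c("0" = 2, "1" = 5)),
    mk("p3", c("0" = 10))
  )
  out <- apply_exclusions(coh)
  log <- exclusion_log(out)
  expect_equal(sort(unique(out$series_id)), "p1")
  expect_equal(nrow(out), 8)
  expect_equal(log$n_patients_in, 3)
  expect_equal(log$n_patients_excluded, 2)
  expect_equal(log$n_patients_retained + log$n_patients_excluded,
               log$n_patients_in)
  expect_setequal(log$excluded_patients[[1]], c("p2", "p3"))

  # identity transform when nothing is requested
  ident <- apply_exclusions(coh, min_readings = 1, drop_first_day = FALSE)
  expect_equal(nrow(ident), nrow(coh))
  expect_equal(exclusion_log(ident)$n_patients_excluded, 0)

  expect_error(apply_exclusions(dplyr::select(coh, -day)), "no `day` column")
  expect_error(exclusion_log(coh), "no exclusion log")
})

test_that("stratification uses half-open bins matching printed bounds", {
  s <- tibble::tibble(k = c(8, 15, 16, 23, 24, 40),
                      sd_sbp = c(9.99, 10, 14.95, 15, 5, 20),
                      mean_sbp = c(129, 130, 135, 139.9, 140, 150))
  defs <- default_strata()[c("k", "sd_sbp", "mean_sbp")]
  out <- stratify(s, defs)
  expect_equal(as.character(out$k_stratum),
               c("8-15", "8-15", "16-23", "16-23", ">=24", ">=24"))
  expect_equal(as.character(out$sd_sbp_stratum),
               c("<10", "10-14.9", "10-14.9", ">=15", "<10", ">=15"))
  expect_equal(as.character(out$mean_sbp_stratum),
               c("<130", "130-139", "130-139", "130-139", ">=140", ">=140"))

  # hand-binned oracle on random values
  withr::with_seed(53, {
    v <- runif(200, 5, 30)
    got <- stratify(tibble::tibble(sd_sbp = v), default_strata()["sd_sbp"])
    oracle <- cut(v, c(-Inf, 10, 15, Inf), labels = c("<10", "10-14.9", ">=15"),
                  right = FALSE)
    expect_equal(got$sd_sbp_stratum, oracle)
  })

  expect_error(stratum_definition("k", c(10, 10), c("a", "b", "c")),
               "strictly increasing")
  expect_error(stratum_definition("k", c(10, 20), c("a", "b")), "labels")
  expect_error(stratify(tibble::tibble(x = 1), default_strata()["k"]),
               "not found")
})

test_that("validation report evaluates overall and per-stratum performance", {
  coh <- generate_synthetic_cohort(cohort_design(n_patients = 150), seed = 21) |>
    dplyr::rename(series_id = patient_id, day = date) |>
    apply_exclusions()
  rep <- evaluate_validation(coh)
  overall <- rep[rep$variable == "overall", ]
  expect_equal(nrow(overall), 2) # sbp + dbp
  # stratum sizes add up to the overall n for every variable
  sums <- rep |>
    dplyr::filter(variable != "overall") |>
    dplyr::group_by(channel, variable) |>
    dplyr::summarise(n = sum(n), .groups = "drop")
  expect_true(all(sums$n == overall$n[1]))
  expect_true(all(rep$auc[rep$auc_available] >= 0 &
                    rep$auc[rep$auc_available] <= 1))
  # C/T ratio separates controlled from uncontrolled strongly
  expect_gt(overall$auc[overall$channel == "sbp"], 0.9)

  s <- validation_summaries(rep)
  expect_equal(nrow(s), dplyr::n_distinct(coh$series_id))

  # invariant to patient order and reading order within a day
  shuffled <- dplyr::arrange(coh, dplyr::desc(series_id), day, dplyr::desc(sbp))
  rep2 <- evaluate_validation(shuffled)
  expect_equal(tibble::as_tibble(rep), tibble::as_tibble(rep2))

  # serialise -> reload -> identical report
  path <- withr::local_tempfile(fileext = ".csv")
  coh |>
    dplyr::transmute(patient_id = series_id,
                     date = format(day, "%Y-%m-%d"), sbp, dbp) |>
    readr::write_csv(path)
  back <- read_hbpm_csv(path)
  rep3 <- evaluate_validation(back)
  expect_equal(tibble::as_tibble(rep), tibble::as_tibble(rep3))
})

test_that("one-class strata keep their counts with the C-statistic unavailable", {
  # all-controlled cohort: low means, tiny noise
  coh <- generate_synthetic_cohort(
    cohort_design(n_patients = 30, mean_sbp = c(110, 2), mean_dbp = c(65, 2),
                  within_sd_sbp = 2, within_sd_dbp = 2, low_k_prob = 0),
    seed = 23
  ) |>
    dplyr::rename(series_id = patient_id, day = date) |>
    apply_exclusions()
  rep <- evaluate_validation(coh)
  overall <- rep[rep$variable == "overall" & rep$channel == "sbp", ]
  expect_equal(overall$n_uncontrolled, 0)
  expect_false(overall$auc_available)
  expect_true(is.na(overall$auc))
  expect_true(is.na(overall$sensitivity)) # no positives: undefined
  expect_equal(overall$specificity, 1)    # still defined and reported
  expect_equal(overall$ccr, 1)
  expect_equal(overall$n, dplyr::n_distinct(coh$series_id))
})
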
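# shared in-code fixtures

# one-series readings table from vectors
readings_tbl <- function(sbp, dbp = rep(70, length(sbp)), id = "s1", day = NULL) {
  out <- tibble::tibble(series_id = id, sbp = sbp, dbp = dbp)
  if (!is.null(day)) out$day <- day
  out
}

# random score/label instance with ties (count-like scores), both classes
random_instance <- function(n, max_score = 10) {
  repeat {
    scores <- sample(0:max_score, n, replace = TRUE)
    labels <- stats::runif(n) < 0.5
    if (any(labels) && !all(labels)) return(list(scores = scores, labels = labels))
  }
}

# exhaustive Mann-Whitney pair oracle for the AUC
auc_pair_oracle <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# brute-force Youden argmax over the midpoint + sentinel threshold grid,
# same tie-break (higher specificity, then higher threshold)
youden_oracle <- function(scores, labels) {
  labels <- as.logical(labels)
  u <- sort(unique(scores))
  thr <- if (length(u) > 1) c(-Inf, (u[-1] + u[-length(u)]) / 2, Inf) else c(-Inf, Inf)
  thr <- thr[is.finite(thr)]
  if (length(thr) == 0) thr <- c(-Inf, Inf)
  best_j <- -Inf; best_spec <- -Inf; best_t <- -Inf
  for (t in thr) {
    sens <- mean(scores[labels] >= t)
    spec <- mean(scores[!labels] < t)
    j <- sens + spec - 1
    better <- (j > best_j + 1e-12) ||
      (abs(j - best_j) <= 1e-12 && (spec > best_spec + 1e-12 ||
        (abs(spec - best_spec) <= 1e-12 && t > best_t)))
    if (better) { best_j <- j; best_spec <- spec; best_t <- t }
  }
  best_t
}

# write a small cohort CSV (patient_id, date, sbp, dbp) and return its path
write_cohort_csv <- function(df, path = tempfile(fileext = ".csv")) {
  readr::write_csv(df, path)
  path
}
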
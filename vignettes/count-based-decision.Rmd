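---
title: "Count-based decisions on home blood pressure control: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Count-based decisions on home blood pressure control: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hbpcount)
```

## The problem

Home blood pressure monitoring (HBPM) produces a series of paired
systolic/diastolic readings, and the clinical reference standard for
*uncontrolled* home BP is a series **mean** of at least 135/85 mmHg.
Computing that mean at the point of care is a real barrier: a month of
records is a page of numbers, and many monitors offer no usable summary.
The statistic this package is built around replaces the mean with a
count. With $T$ readings of which $C$ are *high* (at or above the
channel's cut, 135 mmHg systolic or 85 mmHg diastolic), the decision
statistic is the ratio $C/T$, and the working rule flags a channel as
uncontrolled when $C/T \ge 0.5$ — for the common even series lengths
$K = 16, 20, 24$, a count of at least 8, 10 or 12. A clinician can apply
it by tallying, not averaging.

The package provides (i) the data model and decision statistics, (ii) a
factorial simulation study quantifying how well counts discriminate
uncontrolled series, (iii) bootstrap and mixed-model machinery to compare
that performance across the design, (iv) calibration models that turn a
count into an approximate mean BP with a prediction interval, and (v) a
validation pipeline for real cohort files plus a synthetic-cohort
generator emulating their structure.

## Data model and decision statistics

A series is a long table of readings (`series_id`, `sbp`, `dbp`,
optional `day`). `summarize_series()` reduces it to the per-series
sufficient statistics: $K$ (= $T$), channel means, sample SDs
($n-1$ denominator — stratification bounds downstream are phrased in
terms of observed cohort SDs, and a `sd_type` switch exists), ranges,
high counts, $C/T$ ratios, and the reference labels
(`uncontrolled_* = mean >= cut`). Comparisons at the cuts are inclusive
throughout: a reading of exactly 135/85 is high, a mean of exactly
135/85 is uncontrolled.

Two conventions deserve a note:

* **High readings are counted per channel** (SBP against 135, DBP
  against 85, separately). A combined any-channel count is available
  behind `include_any = TRUE` but is explicitly non-canonical; reported
  single "combined" discrimination figures are ambiguous between the
  per-channel and any-channel readings of the definition, so the package
  exposes both and leaves the choice to the analyst.
* **Odd series lengths** are resolved through the ratio form of the rule:
  $C/T \ge 0.5$ is equivalent to $C \ge \lceil K/2 \rceil$, which is the
  natural extension of the half-of-$K$ cutoffs defined at even $K$.

## The factorial simulation

`simulation_design()` encodes the study conditions: 100 cases per design
cell, with true case means drawn uniformly on [130, 140) mmHg systolic
and [80, 90) mmHg diastolic — deliberately straddling the target, where
the decision is hardest — and readings drawn independently as
$\mathcal N(\mu, \sigma^2)$ at systolic SD levels 5, 10, 15, 20 mmHg,
diastolic SD fixed at 70% of the systolic value (3.5, 7, 10.5, 14). With
series lengths 16, 20, 24 this is a 3 × 4 factorial, 1200 series per
run. Readings are kept unrounded; the generator draws raw Gaussian
values. The same 100 mean pairs are reused in every cell, so cells
differ only in length and noise, and each cell runs on a random
substream derived from the master seed and the cell's identity
$(K, \sigma)$ — a cell reproduces bit-for-bit even when simulated alone.

Values measured on this design are Monte-Carlo quantities: a cell's
C-statistic at $n = 100$ carries a standard error of roughly 0.01–0.04
(larger at higher SD), dominated by the particular draw of the 100 case
means. Where the package's own tests pin cell-level values they therefore
average over 30 replicate runs of the full design (about 20 s of
compute), which brings the standard error of the average near 0.005;
single-run quantities are only asserted with tolerances matching their
single-run spread.

## Diagnostic accuracy machinery

The C-statistic (`auc()`) is computed in its Mann–Whitney form through
midranks: the probability that a random uncontrolled series out-scores a
random controlled one, ties counted one half. This is exactly the
trapezoidal area under the empirical ROC curve, and the test suite holds
it equal to an exhaustive pair-enumeration oracle on every random
instance it generates. `roc_curve()` sweeps thresholds at midpoints
between consecutive distinct scores plus $\pm\infty$ sentinels, with
*predicted positive* always meaning score ≥ threshold (so integer count
cutoffs read naturally as "count at least $c$").

Confidence intervals for the C-statistic are Wald intervals on the
DeLong structural-component variance, clipped to [0, 1]; with perfect
separation the variance is zero and the interval collapses to the point
estimate with a warning and a `degenerate` flag rather than a silent
(1, 1). `best_threshold_youden()` maximises $J = \text{sens} +
\text{spec} - 1$ over the threshold grid; ties are broken toward higher
specificity and then toward the higher threshold, a choice recorded in
the result's metadata because other conventions exist. Confusion-matrix
indices at empty cells (no predicted positives) return `NA` with an
explicit `ppv_defined`/`npv_defined` flag, never a silent zero.

## Bootstrap and design-wide comparison

`bootstrap_statistic()` case-resamples (score, label) pairs and
recomputes the statistic per replicate, 2000 replicates per cell by
default. Two defined behaviours matter:

* a resample containing a single outcome class cannot score; it is
  rejected and redrawn, with the redraw count reported (at the default
  50/50 prevalence and $n = 100$ this is essentially never exercised);
* the correct-classification-rate statistic uses the half-of-$K$ cut
  fixed **before** resampling — the rule is being evaluated, not
  re-optimised per replicate.

`compare_across_design()` fits a linear mixed model to the per-cell
replicate values: fixed effects for $K$ and SD with their interaction,
and a random intercept per cell. $K$ and SD enter as numeric covariates
by default — the scientific question is a trend per mmHg of noise and
per added reading, not an unordered 2- or 3-df contrast — with factor
coding behind a flag. P-values are Wald-normal on the fixed-effect
t-statistics (with 24,000 replicate rows the normal approximation is
immaterial); a constant replicate table short-circuits to a flagged
degenerate result, and a singular mixed fit raises an error carrying the
variance components rather than returning estimates of doubtful meaning.

## Calibration: counts to mean BP

Because the count is (noisily) monotone in the underlying mean, an
ordinary least-squares fit of series mean BP on the count statistic
turns the tally into an estimated mean with a t-based 95% prediction
interval:

$$\hat y(x) \pm t_{0.975,\,n-2}\; s \sqrt{1 + \tfrac1n +
\frac{(g(x)-\bar g)^2}{\sum_i (g_i - \bar g)^2}}$$

with $g$ the identity (`fit_linear()`) or the logit transform
$g(x) = \log\frac{x}{1-x}$ of the $C/T$ ratio (`fit_logit()`). The fit
object stores the sufficient statistics, so intervals are exact
reconstructions, verified against `predict.lm(interval = "prediction")`.
Choices made where the design was open:

* **Boundary ratios are excluded, not clamped.** The logit transform is
  undefined at $C/T \in \{0, 1\}$; such series (all-low or all-high) are
  dropped from logit fitting and their count is reported on the fit.
  Clamping would manufacture leverage points at arbitrary positions.
* **Prediction intervals for the logit model are computed on the
  transformed predictor scale** — standard OLS theory applies there; the
  interval is then read at the ratio of interest.
* **Range-restricted linear fits** subset on the *response* (closed
  intervals, e.g. mean SBP in [125, 145] mmHg) before fitting: within a
  near-target band the logit curve is locally linear, and restricting
  the response keeps the linear model honest about the only region where
  it is used. Bounds are inclusive.
* `confidence_thresholds()` reports the **rule-out** value (largest
  predictor whose whole PI lies below the target — controlled with ≥95%
  confidence) and the **rule-in** value (smallest whose PI lower limit
  reaches the target). Integer count domains are scanned exactly;
  continuous ratio domains are scanned on a $10^{-4}$ grid and reported
  at 2 decimals, the granularity at which such thresholds are usable in
  clinic.

## The synthetic cohort

`generate_synthetic_cohort()` emulates the hierarchical structure of a
real treated-hypertensive HBPM cohort, for exercising the validation
pipeline end to end when real records cannot be redistributed:

* 424 patients enrolled; patient-level true means bivariate normal with
  SBP $\sim \mathcal N(128.2, 14.8^2)$, DBP
  $\sim \mathcal N(79.9, 9.7^2)$ and cross-channel correlation 0.6 (a
  configurable default: systolic and diastolic pressures co-vary
  strongly across patients, and 0.6 yields a combined uncontrolled-BP
  prevalence near 40%);
* within-patient reading SDs log-normal (positivity) with means
  11.8/8.0 mmHg and CV 0.3;
* series lengths varying patient by patient over 8–70 retained readings
  (log-normal bulk centred near 20), plus a small low-adherence tail
  (probability 12/424) recording fewer than 8 readings after the first
  day, which the standard exclusions then drop — the default pipeline
  lands near 412 analysed patients;
* readings grouped 2 per calendar day after a full first day, so the
  first-day exclusion is exercisable. Two readings per day mirrors
  guideline-style morning/evening duplication, but it is a structural
  guess, exposed as `readings_per_day`;
* Gaussian tail draws outside the 30–300 mmHg plausibility window
  (probability ~$10^{-5}$ per reading) are clamped to it, since monitors
  cannot record such values and the downstream readers reject them.

What the generator does **not** emulate: diurnal and weekly BP rhythms,
autocorrelation between consecutive readings, and the skewness/kurtosis
of real reading distributions. Tests passing on synthetic cohorts
therefore demonstrate that the pipeline's plumbing, exclusion
accounting, stratification and calibration behave correctly under the
modelled hierarchy — they do not certify the decision rule's accuracy on
real populations, where those unmodelled features can only blunt it.

## Validation pipeline

`read_hbpm_csv()` reads long-format records (patient, ISO date, SBP,
DBP), collecting malformed rows into a rejects report instead of
dropping them silently. `apply_exclusions()` removes each patient's
first calendar day ("first day" = earliest date present, since real
series are irregular) *before* applying the minimum-readings filter
(default 8), and attaches a full accounting: excluded plus retained
always equals input. `stratify()` bins summaries into the standard
reporting strata — series length (8–15, 16–23, ≥24), systolic SD (<10,
10–14.9, ≥15 mmHg), diastolic SD (<7, 7–9.9, ≥10), reading ranges and
near-target mean bands — all as half-open `[low, high)` intervals so a
printed bound like "10–14.9" cannot orphan a value of 14.95; the
near-target systolic band is [130, 140). `evaluate_validation()` then
reports, per channel, overall and per stratum: the C-statistic of the
$C/T$ ratio with its DeLong CI and the indices of the $C/T \ge 0.5$
rule. One-class strata keep every index that remains defined and mark
only the C-statistic unavailable.

## Reproducibility and numerical choices

* Every stochastic entry point takes a seed; design cells and bootstrap
  cells run on substreams derived from the master seed and the cell
  identity, so partial reruns reproduce exactly.
* The AUC uses midranks ($O(n \log n)$); the DeLong components are the
  $O(mn)$ placement averages, fine at cohort scale.
* PI threshold searches on the ratio scale use a fixed $10^{-4}$ grid
  rather than root-finding, since PI limits need not be monotone far
  from the data.
* Degenerate inputs fail loudly and specifically: empty series,
  non-finite readings (with the offending index), one-class labels,
  constant predictors, non-increasing calibrations, missing day labels
  when a first-day drop is requested.

## Known limitations

The simulation draws independent Gaussian readings — by design, since
the study targets the near-threshold regime, but real series are
autocorrelated and rhythmic. The mixed-model p-values are asymptotic.
The calibration table is only as transportable as the cohort it was fit
on; rule-in/rule-out ratio thresholds derived from one population's
noise profile should not be reused on another without refitting.
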
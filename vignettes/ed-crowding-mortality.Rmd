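---
title: "Measuring ED crowding and its association with short-term mortality"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring ED crowding and its association with short-term mortality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question

Emergency department (ED) crowding arises when demand for emergency care
exceeds the resources available, and it is widely suspected of harming
patients. `edcrowd` implements an observational analysis pipeline that asks a
specific version of that question: *do patients who arrive at an unusually
crowded hour — for their ED and for that time of day — die more often in the
following 1, 7 or 30 days?* The pipeline runs from raw timestamped visit logs
to adjusted Cox proportional-hazards ratios, and ships with a synthetic
multi-ED visit generator so every stage can be validated end to end without
access to patient data.

## Crowding measurements

All measurements are made per ED on a 1-hour clock grid. Windows are
half-open `[start, end)`: a patient is present from arrival (inclusive) to
departure (exclusive), so nobody is double-counted at an hour boundary.
Timestamps are naive wall-clock time at minute resolution; duplicated
daylight-saving hours are taken at face value, because that is what source
systems log.

For the completed hour `[H-1h, H)`:

* **census** — the number of distinct patients present at any moment of the
  hour;
* **patient-hours** — the summed presence time of all patients during the
  hour, divided by the census (a dimensionless fraction in `(0, 1]`, absent
  when the census is zero);
* **time-to-physician** — the mean realized wait, registration to first
  physician contact, over patients who were waiting at some moment of the
  hour (absent when nobody was waiting; patients never seen by a physician
  are excluded);
* **mSEAL** — the linear workload score
  `1.485 + 9.715 * patient_hours + 0.177 * time_to_physician`,
  describing crowding from 1 (none) to 6 (extreme); it is absent whenever
  either input is absent;
* **occupancy rate** — patients present at the instant `H` divided by
  treatment beds.

A visit arriving during `[H, H+1h)` is exposed to the row computed at `H`:
the most recent completed hour, which is also the only information available
in real time at arrival.

Two deliberate readings of ambiguous conventions are baked in and
documented: the census counts patients present at *any* moment of the window
(not only at a fixed instant), and time-to-physician uses the *realized*
full wait of anyone whose waiting interval overlaps the window (the data are
retrospective, so the full wait is known). An elapsed-wait variant censored
at the window end would be the real-time alternative; the realized-wait
reading is the default because the series is built after the fact.

### Clamping and why the series keeps the raw score

`mseal_score()` truncates into `[1, 6]` by default, as the score's published
range demands. The hourly series, however, stores the *unclamped* linear
score (`hourly_metrics(clamp_mseal = FALSE)` is the default). The reason is
structural: with lengths of stay of 3-5 h, most patients present during an
hour are present for most of it, so patient-hours sits near 0.7-0.9 and the
linear form exceeds 6 at practically every occupied hour. Clamping would
collapse the upper tail of the distribution onto the point 6, and empirical
85/90/95th percentiles — the heart of the exposure definition — would
degenerate (all three cutpoints equal, every occupied hour "extreme"). The
exposure construction is rank-based, so it is invariant to any monotone
transformation of the score; keeping the raw score changes nothing about
what the categories mean while keeping them well defined. The clamp remains
available for presentation and diagnostics.

## Exposure construction

Crowding is relative to site and time of day: 20 occupied beds is an
ordinary night in a large academic ED and a crisis in a 16-bed rural one.
Each metric is therefore stratified by ED and hour of day (0-23), and the
85th/90th/95th empirical percentiles are computed per stratum over the whole
study period (the design is retrospective, so full-period percentiles are
the natural choice). Quantiles use linear interpolation between order
statistics (`stats::quantile` type 7, the mainstream default); the analysis
depends on bin *proportions*, not cutpoint values, so the estimator choice
is immaterial beyond determinism.

A visit's category is the bin of its arrival-hour metric value:
`<85%` (reference), `85-90%`, `90-95%`, `>95%`, or `MISSING` when the score
could not be computed for that hour. Bins are lower-inclusive — a value
exactly at a cutpoint goes to the higher-crowding bin — a deterministic
tie-break that is conservative toward exposure. `MISSING` rows are excluded
from regression. Strata with fewer than 20 observed hours trigger an
instability warning rather than an error: scaled-down cohorts legitimately
have sparse night strata.

Repeat visits overlap follow-up windows; `left_truncate()` optionally keeps,
per patient, only visits that start at least `horizon_days` after the last
retained one. A visit exactly `horizon_days` later starts a fresh window and
is retained, consistent with the event definition below. The horizon used
for truncation equals the follow-up of the model being fitted.

## Survival model

Deaths come from a registry at day resolution. The event time for a death
`d` whole days after arrival is `d + 0.5` days — the half-day offset avoids
zero-length survival times for same-day deaths — and a visit is an event iff
`d < horizon` (so "1-day mortality" means death on the arrival day);
otherwise it is censored at the horizon. Ties are therefore massive, and the
Cox partial likelihood uses the Efron approximation. The fit itself is
delegated to `survival::coxph`; the encoding, reference levels, tie method
and Wald 95% intervals are fixed here so results are engine-independent.

Adjustment covariates, all categorical: age band (0-18, 19-39, 40-59,
60-79, 80+ — age 80 goes to the oldest band, resolving the open boundary in
the conventional band labels), sex, ambulance arrival, hospital admission,
inverted acuity and chief complaint. RETTS acuity's optional 5th category is
merged into 4 before inversion (`acuity_inv = 5 - min(acuity, 4)`), so 1 is
the lowest acuity and the reference. Acuity enters as a categorical factor
rather than a linear score: the step from acuity 2 to 1 is not the same
hazard increment as 4 to 3, and with only four levels the categorical
parameterization costs little. Chief complaints are reduced to the ten codes
with the highest *absolute* number of 30-day deaths (ties at rank ten broken
lexicographically), the rest pooled as `OTHER` (the reference). Covariates
without contrast in a given cohort are dropped from the formula instead of
crashing the fit — small simulated cohorts regularly have, say, no
ambulance arrivals at night.

## The synthetic cohort

`scenario_six_sites()` parameterizes six EDs spanning the realistic range
of Swedish sites — treatment beds 52/48/35/72/16/29, annual volumes from
about 21,000 to 88,500, admission fractions 19-28% — over the half year
2017-01-01 to 2017-06-30. With `scale = 1` this yields roughly 169,000
visits. Within `simulate_ed()`:

* Arrivals follow a nonhomogeneous Poisson process (thinning) with a
  double-peaked diurnal profile (minimum ~0.3x overnight, plateau ~1.5x
  from mid-morning to evening).
* Lengths of stay are lognormal, per-site medians 2.8-4.2 h with
  `sigma = 0.8`, giving means of about 3.2-4.9 h and an occasional stay
  above 72 h — exactly the records the cleaning filter exists to trim.
* The physician wait is exponential with mean
  `wait_base + wait_load_coef * (number concurrently waiting)`
  (defaults 0.5 h + 0.03 h per waiter), which makes waits and
  patient-hours rise together, as they do in reality. A patient whose wait
  would outlast their stay leaves unseen.
* Each ED runs on a deterministic sub-stream of the master seed, so adding
  a site leaves the others' visits bit-identical, and the whole log is
  byte-reproducible from the configuration.
* Chief complaints carry baseline 30-day mortality from 0.1% (allergy) to
  6% (altered mental status), mixing to about 1.9% overall.
* Patients return with probability 0.27 per arrival (drawn from the site's
  50 most recent patients), reproducing the roughly 1.4 visits/patient of a
  half-year ED cohort.

Mortality is generated in a second pass: the full simulated log is run
through `hourly_metrics()`, `compute_thresholds()` and `assign_exposure()` —
the very code under test — and each visit's death time is exponential with
rate `-log(1 - p30)/30 * exp(crowding_log_hr * [exposure = GT95])`, recorded
as a death date when it falls inside the 30-day horizon. Because the
generator's crowding effect is defined through the same exposure the
pipeline estimates, recovering `crowding_log_hr` exercises the entire chain
(metrics, stratified thresholds, binning, encoding, fitting) as a closed
loop, not just the Cox engine.

### What the generator does *not* emulate

Honest limits on what passing tests show about real data:

* Deaths are drawn independently per visit. A patient with several visits
  can carry inconsistent death dates across them; a real registry cannot.
  The alternative — reconciling one death per patient — couples outcomes
  across visits and contaminates the reference group with deaths generated
  at exposed visits, destroying the closed-loop recovery property, so the
  per-visit draw is kept deliberately.
* The constant within-horizon hazard matches the ~2% 30-day mortality but
  understates the front-loading of real short-term mortality, where deaths
  cluster disproportionately in the first days after the visit; an
  exponential death time spreads them uniformly in hazard over the horizon.
* Case mix is independent of arrival time and site, so the generator cannot
  produce confounding by time of day; in real data, night arrivals are
  sicker.
* No bed-blocking, boarding or staffing dynamics beyond the load-dependent
  wait; occupancy and workload co-move less richly than in reality.
* Because patient-hours sits near 0.8 at realistic stays (see the clamping
  note above), simulated raw scores live around 8-10 rather than the 3-5
  typical of published site averages; all rank-based results are unaffected.

## Numerical and degenerate-input choices

* Quantiles: type 7; bins lower-inclusive; thresholds require full stratum
  coverage at assignment time (uncovered strata are configuration errors,
  not silent `MISSING`).
* Cleaning precedence is fixed — duplicates, then stays > 72 h (strict),
  then death dates before arrival — so a record is counted once and the
  report always balances. "Duplicate" means identical
  (patient, ED, arrival minute): the only key a generic log offers that
  cannot be two real visits. A stay of exactly 72 h is retained.
* Cox: Efron ties, Wald intervals; no events, no exposure contrast, or an
  inestimable exposure coefficient are explicit errors rather than `NA`
  results.
* Exact Fisher power (`fisher_power()`) enumerates both binomial margins
  with tails truncated below `1e-12` total mass; the sample-size search
  smooths the exact test's saw-tooth by requiring the target power at both
  `n` and `n + 1`. For a design detecting 0.5% vs 0.9% mortality at 80%
  power the required total lands in the low tens of thousands of visits
  (the suite verifies the order of magnitude and checks the exact power
  against an independent Monte-Carlo oracle); whether such a design figure
  counts total or per-group visits is ambiguous, so the function reports
  both.

## Problem sizes used in the shipped tests

The validation suite runs the oracle-equivalence check on 500 random
fixtures, quantile calibration on 5,000 hours per stratum, null-effect
coverage on 100 replicates of ~20,000 visits (30-day horizon, where event
counts make Wald intervals meaningful), and effect recovery
(`crowding_log_hr = log 1.5`) on one ~200,000-visit cohort; the generator
invariant checks use 40 random configurations. These sizes were chosen as
the smallest at which each property is statistically sharp; all are
package-level choices and can be scaled up freely.
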
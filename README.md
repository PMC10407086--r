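# edcrowd

Emergency department (ED) crowding metrics and their association with
short-term mortality, from raw timestamped visit logs to adjusted Cox
proportional-hazards ratios.

`edcrowd` is for epidemiologists and ED operations researchers who have (or
want to simulate) event-level ED visit data — one row per visit with
arrival, first-physician-contact and departure timestamps, demographics,
RETTS triage acuity, chief complaint, admission flag and date of death — and
who want to ask whether arriving at an unusually crowded hour predicts death
within 1, 7 or 30 days.

## What it computes

For every ED and clock hour *H*, from the completed window *[H−1h, H)*:

- **census** — distinct patients present at any moment of the hour;
- **Patient Hours** — `sum of presence time / census`, a fraction in (0, 1];
- **Time to Physician** — mean realized registration-to-physician wait (h)
  over patients waiting during the hour;
- **mSEAL** workload score —
  `1.485 + 9.715 · PatientHours + 0.177 · TimeToPhysician`,
  describing crowding from 1 (none) to 6 (extreme);
- **occupancy rate** — patients present at instant *H* / treatment beds.

Exposure is relative: each metric is stratified by ED and hour of day, and a
visit is categorized by its arrival-hour value against the stratum's
empirical 85th/90th/95th percentiles — `<85%` (reference), `85–90%`,
`90–95%`, `>95%`, or `MISSING` when the score could not be computed. Hazard
ratios for 1-, 7- and 30-day all-cause mortality come from a Cox model
(Efron ties, Wald 95% CIs) adjusted for age band, sex, ambulance arrival,
hospital admission, inverted acuity and the top-10 chief complaints by
absolute 30-day deaths. Utilities cover the standard cleaning filters
(duplicates, stays > 72 h, death dates before arrival), left truncation of
repeat visits, descriptive site/outcome tables, an exact Fisher power
calculation, and a reproducible multi-ED synthetic visit generator with a
configurable crowding→mortality effect for end-to-end validation.

## Worked example

Simulate a half-year six-site cohort at 10% of realistic volume, clean it,
build the hourly mSEAL series, assign stratified exposure and fit the
30-day model:

```r
library(edcrowd)

cfg    <- scenario_six_sites(0.1, seed = 20170101)
visits <- clean_visits(simulate_ed(cfg))$visits
beds   <- setNames(cfg$eds$beds, cfg$eds$ed_id)

metrics <- hourly_metrics(visits, beds)
thr     <- compute_thresholds(metrics, "mseal", warn = FALSE)
visits$exposure <- assign_exposure(visits, metrics, thr)
table(visits$exposure)
#> REF_LT85   Q85_90   Q90_95     GT95  MISSING
#>     9790      572      596      611     5463

fit <- fit_cox(encode_covariates(visits, top_complaints(visits), 30))
fit
#> Cox proportional-hazards fit: 11569 rows, 222 events
#> Hazard ratios vs REF_LT85 (95% CI):
#>   Q85_90    0.82 (0.42-1.60)
#>   Q90_95    1.36 (0.82-2.27)
#>   GT95      0.58 (0.27-1.24)
```

Reading the output: among the 11,569 visits with a computable arrival-hour
score (the many `MISSING` hours at this reduced volume are sparse night
hours), 222 deaths occurred within 30 days. The generator was run with no
true crowding effect (`crowding_log_hr = 0`), and accordingly every
exposure category's confidence interval comfortably covers 1 — at this
cohort size the intervals are wide. Non-missing visits split roughly
85/5/5/5 across the categories, as the stratified percentile construction
guarantees.

`run_pipeline(pipeline_config(...))` performs the whole sequence in one
call and writes the cleaning report, thresholds, descriptive tables and
hazard-ratio tables as CSV/JSON; `inst/cli/edcrowd.R` exposes the stages as
shell subcommands (`simulate`, `metrics`, `thresholds`, `expose`, `fit`,
`report`, `power`).

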
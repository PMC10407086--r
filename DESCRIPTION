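Package: edcrowd
Title: Emergency Department Crowding Metrics and Short-Term Mortality
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to quantify emergency department (ED) crowding from
    timestamped visit logs and relate it to short-term mortality. Computes
    hourly workload measures (census, patient-hours, time-to-physician, the
    mSEAL linear score) and bed occupancy rates, derives ED- and
    hour-of-day-stratified empirical percentile exposure categories, and fits
    Cox proportional-hazards models for 1-, 7- and 30-day all-cause mortality
    with standard ED case-mix adjustment. Includes a synthetic multi-ED
    visit-log generator with diurnal arrivals, load-dependent physician waits
    and a configurable crowding effect on the death hazard, so the whole
    pipeline can be validated end to end by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    survival,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
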
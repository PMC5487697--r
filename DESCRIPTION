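Package: optimon
Title: Cost-Precision Allocation for Environmental Monitoring Surveys
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Design toolkit for marine and freshwater monitoring programs
    built on time-integrated station averages. Reduces vertical sensor
    casts to surface-band means and light extinction coefficients,
    computes time-weighted seasonal averages of irregular series with
    midpoint interval weights, summarises spatial and temporal
    variability as coefficients of variation, evaluates how far the
    sampling frequency can be reduced before the seasonal mean drifts,
    and solves the linear cost model linking budget, number of stations
    and attainable precision. Includes one-sample noncentral-t power
    analysis for detecting inter-annual change and a synthetic
    multi-station sensor-data generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), jsonlite, withr
Config/testthat/edition: 3
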
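Package: orthohrv
Title: Orthostatic Heart Rate Variability Monitoring of Stress-Recovery
    Status in Endurance Athletes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for monitoring the stress-recovery status of endurance
    athletes across a multistage event from daily supine/standing
    (orthostatic) RR-interval recordings. Provides RR-series quality
    control with local-median artifact correction and the 5% rejection
    rule, time-domain (mean RR, RMSSD, LnRMSSD) and Welch-periodogram
    frequency-domain (LF, HF, normalized units) heart rate variability
    indices, orthostatic delta statistics, Edwards TRIMP workload
    quantification from five heart-rate zones, daily well-being
    questionnaire scoring, Pearson correlation surfaces with Williams'
    test for dependent correlations, exhaustive best-subset linear model
    selection by AIC and adjusted R-squared, packaged predictive
    equations for the orthostatic RR response, and a synthetic cohort
    generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
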
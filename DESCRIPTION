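Package: watermon
Title: Time-Series Analysis of Microbial Drinking-Water Monitoring Records
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for long-term microbial drinking-water surveillance series:
    simulation of monitoring records with planted structure (regime shifts,
    annual seasonality, lagged cumulative-rainfall effects), least-squares
    multiple-breakpoint detection with BIC model selection and bootstrap
    confidence intervals for break dates, periodogram permutation tests for
    annual periodicity, Ward hierarchical clustering of monthly contamination
    profiles, and a distributed-lag ARIMA model comparison that scans
    cumulative-rainfall windows by cross-validated prediction error against
    naive seasonal-mean and no-covariate benchmarks.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), withr, mclust, jsonlite, yaml, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
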
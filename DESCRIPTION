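Package: glycotrace
Title: In-Depth Continuous Glucose Monitoring Analysis for Hepatic
    Glycogen Storage Disease
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for in-depth analysis of continuous glucose monitoring
    (CGM) traces in hepatic glycogen storage disease: ingestion of
    Dexcom-CLARITY-style CSV exports with enforcement of the 2.2 mmol/L
    device floor, descriptive and glycemic-variation statistics,
    time-in-range/under-range/above-range percentages, nocturnal
    (01:00-05:00) window extraction, starch-load curve summarisation with
    paired crossover comparison, first/second-order derivative series,
    two cumulative-sum (CUSUM) change formulations including a
    derivative-indexed hypercube predictor, per-night discrete Fourier
    amplitude spectra and night-by-night spectrograms, and a synthetic
    CGM trace generator with known ground truth for end-to-end
    verification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
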
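Package: wearcheck
Title: Non-Wear Time Detection for Accelerometer and Temperature Sensor Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects non-wear periods in long-term recordings from body-worn
    devices that combine a 3-axis accelerometer with a temperature sensor.
    Implements an event-based temperature algorithm that locates device
    removal and reattachment as peaks in the derivative of the smoothed
    temperature signal and retains them with a relative (3 degree Celsius)
    temperature-change criterion, alongside window-based temperature
    baselines (fixed and adaptive absolute thresholds), the standard
    accelerometer vector-magnitude standard-deviation detector, and an
    AND-combination of the two sensor modalities. Includes epoch-level
    validation metrics under the positive-equals-wear convention and a
    ground-truthed simulator of multi-day wear protocols (removals, pocket
    carriage, wrong-orientation reattachment, sleep) for algorithm
    evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
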
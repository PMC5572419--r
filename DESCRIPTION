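Package: turnsig
Title: Cranio-Caudal Turn Signature from Wearable Orientation Sensors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts the cranio-caudal signature of a 180-degree turn from
    head and trunk orientation time series recorded with wearable attitude
    and heading reference systems. Computes the relative head-to-trunk
    orientation, derives the axial angular-velocity profile, and decomposes
    it into a two-phase sigma-lognormal model whose parameters (command
    amplitudes, command times, log time delays and log response times)
    characterise the neuromuscular commands driving the turn. Also provides
    the traditional turn metrics (step count, mean and peak turn velocity),
    a signal-to-noise quality gate for the reconstruction, test-retest
    reliability statistics (two-way random absolute-agreement average-measures
    intraclass correlation, standard error of measurement, paired Wilcoxon
    signed-rank tests), and a synthetic-trial generator with known ground
    truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
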
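Package: wavemap
Title: Traveling-Wave Detection and Classification in Multielectrode LFP Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for analysing the spatial organisation of cortical
    oscillations recorded on 8x8 microelectrode ("Utah") arrays. Extracts
    band-limited instantaneous phase maps from local field potentials
    (zero-phase Butterworth filtering, Hilbert analytic signal, missing-site
    interpolation), detects planar traveling waves with quadrant-based
    Euclidean distance maps calibrated by a spatial-shuffling null, and
    classifies wave instants as planar or rotating via circular-circular
    correlation fingerprints matched against a simulated reference library.
    Includes a wave simulator and full synthetic-session generator with a
    working-memory trial structure, wave-speed estimation from phase
    gradients, and task-epoch statistics (wave-count timecourses, direction
    histograms, correlation-sign bias timecourses, standing-wave
    discrimination, and spike-rate comparisons by wavelength class).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
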
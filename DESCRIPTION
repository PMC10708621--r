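Package: toatrack
Title: Robust Time-of-Arrival Localization for Wildlife Tracking Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates positions of radio transmitters ('tags') attached to
    wild animals from packet time-of-arrival measurements collected by a
    network of fixed receivers with unsynchronized clocks, calibrated by
    beacon transmitters at known positions. Implements an algebraic
    closed-form solver for exactly determined multilateration problems, a
    RANSAC-style consensus pipeline that detects and discards outlier
    arrival times (e.g. from non-line-of-sight propagation), clustering and
    consensus hypothesis selection, nuisance-parameter elimination for the
    weighted least-squares objective, Levenberg-Marquardt refinement,
    first-derivative covariance estimation, terrain (DEM) constrained
    altitude, Kalman-filter track priors with ambiguity resolution, and a
    full synthetic-scenario simulator for end-to-end evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
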
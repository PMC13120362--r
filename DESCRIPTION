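Package: accelgait
Title: Treadmill Belt-Acceleration Propulsion Training: Controller
    Simulation and Gait Analysis Pipeline
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Closed-loop simulation of a treadmill belt-acceleration
    controller that perturbs the trailing limb during push-off, together
    with the offline analysis pipeline used to quantify gait propulsion
    mechanics: vertical ground reaction force event detection, peak
    anterior ground reaction force and propulsive impulse, trailing limb
    angle and stride length from marker data, EMG linear-envelope
    processing with phase resampling and automatic stride-outlier
    rejection, and protocol time-point binning. Includes a synthetic
    gait-data generator with ground-truth labels emulating post-stroke
    asymmetric walking, so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
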
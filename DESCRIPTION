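Package: canegait
Title: Gait Event Detection from a Force-Sensing Cane Handle
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects and characterizes gait events from grip-pressure
    variables measured by a 16-sensor force-sensing-resistor (FSR) array on
    a cane handle. Computes center-of-pressure and mean-pressure variables
    and their time derivatives, segments gait into phases from a reference
    kinematics stream, synchronizes the two acquisition streams by
    cross-correlation of their cane-inclination signals, smooths with a
    third-order Savitzky-Golay filter, and reports per-stride signal
    extrema relative to gait-phase onsets, keeping only events consistent
    across strides. Includes a ground-truthed synthetic gait and grip
    simulator so the whole pipeline is testable without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    pracma,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
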
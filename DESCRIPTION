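Package: gaitevents
Title: Marker-Based Gait Event Detection, Walking-Condition Segmentation
    and Validation Metrics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects initial and final foot contacts from 3D heel, toe and
    pelvis marker trajectories using ten published velocity-, position- and
    acceleration-based methods, including a fused detector that anchors
    position-based candidates with 3D-velocity refinements and falls back
    gracefully under pelvis-marker occlusion. Classifies walking conditions
    (straight, curvilinear, step negotiation), assembles strides and their
    spatio-temporal parameters, and provides the full validation-metric
    suite (tolerance-window event matching, sensitivity/PPV/F1, timing-error
    statistics, ICC(2,1), Bland-Altman limits of agreement) together with a
    synthetic gait-trajectory simulator with exact ground-truth events.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    signal,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
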
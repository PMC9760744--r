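Package: pedrecon
Title: Pedestrian-Vehicle Accident Reconstruction by Multiobjective Optimization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale forensic reconstruction of vehicle-pedestrian
    collisions. A simplified articulated rigid-body pedestrian model is
    struck by a zoned vehicle front with piecewise-linear force-deflection
    contact; the unknown pre-impact parameters (impact speed, lateral
    offset, pedestrian orientation, and head posture angles) are identified
    by multiobjective optimization (NSGA-II, NCGA, MOPSO) minimizing the
    Euclidean distances between paired collision markers on the body, the
    vehicle, and the ground. Includes design-of-experiments over marker-pair
    subsets, injury-criterion post-processing (HIC, femur axial force
    banding), pre-impact video speed estimation, and a synthetic
    ground-truth case generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
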
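Package: pbsn
Title: Proximity-Based Social Networks and Space Use from GPS Telemetry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for sociospatial analysis of GPS-collared animals:
    screening and season-partitioning of telemetry fixes, chain-rule group
    detection and simple-ratio-index social networks, kernel-density home
    ranges with reference-bandwidth smoothing, utilization-distribution
    overlap (UDOI) spatial networks and interannual site fidelity, a
    data-stream permutation null that shuffles daily movement trajectories
    within individuals, and seasonal linear mixed models contrasting observed
    and null association strength. Includes a biased correlated random-walk
    simulator with controllable conspecific attraction, resource patchiness
    and range fidelity for end-to-end testing of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    glue,
    igraph,
    lme4,
    lmerTest,
    generics,
    ggplot2,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    readr,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
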
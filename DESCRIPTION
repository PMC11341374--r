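Package: sleepscrub
Title: Automated Artifact Detection, Repair and Selection for Multichannel Sleep EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Channel-resolved artifact cleaning for overnight multichannel
    sleep EEG recordings. A customizable set of declarative detectors flags
    artifactual signal portions per channel (amplitude, envelope, gradient and
    neighbor-correlation criteria); detections are pooled into boolean
    channel-by-segment grids with spatial expansion, segment rejection and
    temporal (bad-channel) expansion; flagged channel-segment elements are
    repaired by segment-wise spherical-spline interpolation; and clean data
    bouts are extracted by sleep stage and minimum duration. Includes a
    seedable generator of stage-structured synthetic EEG with ground-truth
    artifact injections, agreement metrics against reference annotations, and
    a config-driven end-to-end pipeline with machine-readable outputs and a
    data-quality figure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    signal,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    pracma,
    patchwork,
    optparse,
    withr
Config/testthat/edition: 3
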
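Package: gazecontrast
Title: Fixation-Map and AOI Contrast Analysis for Face-Viewing Eye-Tracking
    Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for eye-tracking studies of face viewing built
    around two complementary ways of testing condition differences in fixation
    behaviour: pooled area-of-interest (AOI) relative-frequency statistics with
    planned paired contrasts, and aligned Gaussian fixation-density maps tested
    pixel-wise by Monte Carlo permutation of fixation locations (exchangeable
    only within ordinal fixation position) with false-discovery-rate
    correction. Includes one-dimensional profile-density inference,
    signal-detection behavioural measures (d-prime, criterion, reaction-time
    filtering, paired Hedges' g), and a synthetic-data generator emulating a
    three-race, four-start-position old/new face recognition design, so the
    relative sensitivity of AOI and map-based analyses can be studied under
    known effect sizes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    pracma,
    optparse
Config/testthat/edition: 3
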
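Package: vertegrow
Title: Vertebral Growth Modulation Under Posterior Tethering
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis and simulation toolkit for tether-mediated vertebral
    growth modulation in the growing kyphotic spine. Computes regional physeal
    growth rates from pulsed fluorochrome label distances, the percent growth
    modulation statistic with alternative regional schemes, and cohort
    comparisons; provides a reduced-order sagittal motion-segment model of
    tether-driven disc realignment (axis-of-rotation dependent disc height
    field, nucleus pulposus pressure, growth-plate stress), a stress-modulated
    growth law with an arrest threshold, and a longitudinal Cobb-angle
    simulator; and ships a synthetic cohort generator so every pipeline stage
    is testable without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2
Config/testthat/edition: 3
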
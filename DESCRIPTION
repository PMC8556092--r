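Package: peffkit
Title: Effective Point of Measurement of Cylindrical Ion Chambers in
    Carbon-Ion Beams
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for determining the effective point of measurement
    (P_eff) of cylindrical (Farmer-type) ionization chambers in carbon-ion
    beams: water-equivalent thickness accounting for chamber wall and
    window layer stacks, the Dutreix cavity-weighting integral for the
    classical 0.85r shift, a vertical/horizontal scatter decomposition
    driven by a screened beam-spreading ("barrier") model, Bragg-curve
    peak localization and shift extraction between a plane-parallel
    reference chamber and a cylindrical chamber, a synthetic pristine
    Bragg-curve generator with an injectable, recoverable effective-point
    shift, and Co-60-based absorbed-dose-to-water conversion with the
    carbon beam-quality factor kQ.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    pracma,
    stats,
    utils,
    yaml
Suggests:
    ggplot2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
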
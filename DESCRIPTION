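Package: sinustdm
Title: Total Difference Method for Frontal Sinus Radiographic Comparison
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Automated implementation of the Total Difference Method for
    comparing frontal sinus outlines on posterior-anterior radiographs.
    Measures a traced sinus outline with a fan of 59 rays at 3-degree
    intervals from an origin on the supraorbital baseline, standardizes the
    line lengths by baseline length, and scores antemortem-postmortem pairs
    by the sum of absolute per-angle differences (the Total Difference).
    Includes raster mask and ImageJ ROI interoperability, orbital-breadth
    scale calibration, measurement-error statistics (bias, inaccuracy,
    cube-root transform, extreme-outlier filtering, repeated-measures
    ANOVA with Holm-corrected pairwise tests), and a synthetic outline and
    observer-noise simulator so the complete workflow runs without
    external radiographs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    tools,
    utils,
    jsonlite,
    png,
    tiff
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
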
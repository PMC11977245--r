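Package: lipdesq
Title: Image-Based Quantification of Lip Desquamation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantifies lip surface desquamation (flaking) from facial or
    lip-region photographs. A rectangular target region on the lower-lip
    premucosa is located from face-mesh landmarks, converted to grayscale,
    and segmented with a standard-deviation outlier threshold
    (T = Mean + k * SD); the desquamation rate is the percentage of
    above-threshold pixels. The package also implements the calibration of
    the threshold multiplier k against visual-assessment scores, a
    tape-stripping comparator model based on corneocyte grayscale grouping,
    method-agreement statistics, cohort age/sex trend analysis with a
    piecewise-regression breakpoint scan, and ground-truthed synthetic data
    generators so the full pipeline is testable without human facial data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    png,
    stats,
    utils,
    tools,
    optparse
Suggests:
    testthat (>= 3.0.0),
    EBImage,
    jpeg
Config/testthat/edition: 3
RoxygenNote: 7.3.3
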
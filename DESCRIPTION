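Package: stnlda
Title: Mapping Subthalamic Stimulation Site to Neuropsychological Outcome
    with Fisher Discriminant Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline linking the chronic active-contact location of
    subthalamic deep brain stimulation (DBS) electrodes, expressed in MNI
    millimetre coordinates, to pre/post change on a neuropsychological test
    battery. Change scores are discretized into worsening / unchanged /
    improvement classes, a Fisher linear discriminant axis is fitted to the
    3D contact coordinates labelled by class, contacts are projected onto the
    oriented discriminant, and projection-outcome Pearson correlations are
    corrected with the Benjamini-Hochberg procedure, per hemisphere and per
    psychiatric-history subgroup. Includes a synthetic-cohort generator with
    planted spatial gradients for parameter-recovery and calibration studies,
    plus supporting cohort statistics (pre/post change tests,
    baseline-adjusted change regression, volume-of-tissue-activated summary
    comparisons).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    MASS,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    ggplot2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
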
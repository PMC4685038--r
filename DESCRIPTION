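Package: leukotrax
Title: Quantification of Leukocyte Migration in Wound-Healing Time-Lapse Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying myeloid cell migration in fluorescence
    time-lapse microscopy of larval wound-healing assays. Implements
    dual-threshold cell segmentation with lamellipodia morphometrics
    (whole-cell area, cell-body area, normalized lamellipodia area),
    criterion-based frame-to-frame track linking (size range, continuous
    presence, maximum jump of two body sizes), per-track kinematics
    (instantaneous and average speed, path length, net displacement,
    activation time), and circular statistics of displacement directions
    (Rayleigh uniformity test, rose histograms). An agent-based simulator
    generates ground-truth trajectories and rendered two-channel image
    stacks reproducing the statistical structure of wound and infection
    assays, so every pipeline stage can be validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    jsonlite,
    yaml,
    ggplot2,
    grDevices,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
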
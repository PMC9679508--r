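Package: emgait
Title: Synchronized Kinematic and Surface-EMG Gait Analysis for Quadruped Lameness
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying movement asymmetry and appendicular
    muscle-activation adaptations from synchronized motion-capture and
    surface electromyography (sEMG) recordings of trotting quadrupeds.
    Implements stride segmentation from hindlimb impact events, vertical
    displacement asymmetry indices (MinDiff, MaxDiff, hip hike), sagittal
    joint and limb pro-retraction angles, the full sEMG conditioning chain
    (40 Hz high-pass, rectification, linear envelopes, stride-wise average
    rectified values with 2-SD outlier rejection and reference-contraction
    normalization), double-threshold muscle activation onset/offset
    detection, one-dimensional statistical parametric mapping with
    random-field-theory thresholds and a permutation oracle, linear
    mixed-model condition contrasts with false-discovery-rate correction,
    and a synthetic trial generator with injectable lameness asymmetries
    that gives every stage a recoverable ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    signal,
    jsonlite,
    lme4,
    lmerTest,
    emmeans,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
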
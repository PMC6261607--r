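Package: myoscreen
Title: High-Throughput Myofibroblast Screening Assays on Synthetic Plates
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Implements the computational pipeline of two high-throughput
    screens for inhibitors of TGF-beta1-driven fibroblast-to-myofibroblast
    transition: a high-content imaging assay (nucleus detection, seeded cell
    segmentation, per-cell intensity/granularity/texture/shape features, a
    control-trained linear support-vector classifier aggregated to per-well
    percent effect) and a multiplexed impedance plus MRM protein
    quantification assay (trace normalization and baseline subtraction,
    time-point readouts, surrogate-peptide precursor and fragment m/z,
    tubulin-ratio normalization).  Includes three-parameter logistic
    IC50/EC50 fitting with censoring, Z-prime assay quality, Spearman
    rank correlation with exact permutation p-values, hit triage for
    primary/confirmation screening in prevention and reversal modes, and
    synthetic-plate generators (multi-channel cell images, impedance
    kinetics, MRM peak areas, compound libraries) with ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    e1071,
    minpack.lm,
    data.table,
    jsonlite,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
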
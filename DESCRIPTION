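Package: refstab
Title: Reference Gene Stability Evaluation and Normalization for RT-qPCR
Version: 0.1.0
Authors@R: person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Validation of candidate reference (housekeeping) genes for
    RT-qPCR normalization. Quantifies threshold-cycle (Ct) data through
    dilution-series standard curves, ranks candidate gene regions by three
    independent stability algorithms (the geNorm pairwise-variation M
    statistic with stepwise elimination and the V_n/n+1 sufficiency check,
    a NormFinder-style intra/inter-group variance decomposition, and the
    delta-Ct screening statistic), builds geometric-mean normalization
    factors from the selected references, and normalizes target-gene
    expression. Includes a synthetic Ct-data generator with known ground
    truth (gene-specific noise, group shifts, per-sample loading effects,
    dilution series, and a reverse-transcription primer bias) so every
    pipeline stage can be exercised without instrument exports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
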
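Package: mpsquant
Title: Quantification of Axonal Membrane Periodic Skeleton Periodicity
    from Single-Molecule Localizations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantifies the ~190 nm periodicity of the axonal
    membrane-associated periodic skeleton (MPS) from single-molecule
    localization microscopy (STORM/SMLM) coordinate tables. Implements the
    segment-averaged one-dimensional spatial autocorrelation of the binned
    axial localization profile and its amplitude statistic (value at the
    local maximum near 190 nm minus the value at the local minimum near
    95 nm), an occupancy-ratio procedure for two-channel wide-field images
    (spectrin coverage of skeletonized tubulin-marked axon strokes), group
    summaries with two-sided Kolmogorov-Smirnov comparisons, a synthetic
    localization and image generator emulating MPS disassembly time
    courses, and a reproducible simulate-quantify-compare pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    EBImage,
    tiff,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    png
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
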
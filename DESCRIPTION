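Package: hergtraffick
Title: Quantitative Analysis of hERG Channel Trafficking from Plate-Based
    Surface-Expression Assays
Version: 0.1.0
Authors@R:
    person("Sam", "Carter", email = "sam.carter@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying trafficking of hERG (Kv11.1) channel
    variants from two-channel On-Cell/In-Cell western plate assays:
    normalization-by-sum of raw 700/800-channel fluorescence, repeat-level
    statistics (mean +/- SEM, one-way ANOVA with Bonferroni post-hoc),
    dominant-negative and rescue metrics under heterozygous expression, a
    folding-equilibrium model converting pharmacological fold-enhancement of
    trafficking into drug binding free energies, and per-residue mutational
    tolerance classification of deep mutational scanning surface-expression
    scores with structure annotation output. Includes a seeded synthetic
    plate-data generator built on a binomial tetramer-assembly model so the
    whole pipeline is testable against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
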
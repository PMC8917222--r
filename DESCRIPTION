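Package: oslfq
Title: Peptide-Level Mixed-Model Differential Abundance and Targeted
    Lipidomics for Photoreceptor Outer-Segment Omics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Label-free quantitative proteomics and targeted lipidomics
    statistics for photoreceptor outer-segment studies. Implements
    peptide-level differential protein abundance with per-protein linear
    mixed-effects models (random peptide intercepts, Satterthwaite
    degrees of freedom), a missingness-aware pseudo fold-change procedure
    for proteins undetected in one condition, robust z-score
    normalization, protein-level pooled-variance t-tests with peptide-count
    and missingness filters, Benjamini-Hochberg and Benjamini-Krieger-
    Yekutieli two-stage false discovery rate control, volcano-style
    effect/significance classification, internal-standard lipid
    quantification with dilution-series CV quality control and median
    normalization, and a synthetic-data generator with known ground truth
    for end-to-end validation. Reads MaxQuant-style peptides.txt and
    proteinGroups.txt tables.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    lme4,
    lmerTest,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
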
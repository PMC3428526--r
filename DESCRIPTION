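Package: lfqpipe
Title: Label-Free Quantitative Tissue Proteomics Pipeline
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A data-handling pipeline for label-free shotgun proteomics of
    tissue samples, from MaxQuant-style peptide and protein quantification
    tables through log2 transformation, per-sample median centering and
    peptide filtering, pairwise-ratio protein rollup (LFQ), two complementary
    differential-expression branches (peptide-level robust ANOVA with
    Benjamini-Hochberg correction and permutation-FDR t-test refinement;
    spectral-count Fisher exact testing with downshifted-normal imputation
    and t-test refinement), bidirectional hierarchical clustering with
    Cluster 3.0-compatible output, and a replicate quality-control battery
    (identification counts, coefficients of variation, Pearson correlations,
    reproducibility tiers, set overlaps). Includes a synthetic-data generator
    with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    MASS,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
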
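Package: wpcna
Title: Weighted Protein Co-Expression Network Analysis for Label-Free
    Proteomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: End-to-end analysis of label-free proteomic cohorts across
    clinical groups: top-3 peptide ion-intensity protein quantification with
    protein-group filtering, membrane-vs-soluble enrichment decile profiling,
    bootstrap covariate regression, one-way ANOVA with Tukey post-hoc
    differential abundance, weighted signed protein co-expression network
    construction (biweight midcorrelation, soft thresholding, topological
    overlap, dynamic hybrid tree cut with a medoid assignment stage, module
    eigenproteins, kME, module merging and reassignment), gene-set and
    cell-type over-representation analysis with Benjamini-Hochberg FDR,
    cross-network module overlap, module-trait correlation, and a synthetic
    cohort generator providing ground truth for every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    data.table,
    ape,
    fgsea,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
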
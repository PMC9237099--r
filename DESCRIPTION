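Package: tensorccc
Title: Context-Aware Tensor Decomposition of Cell-Cell Communication
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds a four-dimensional communication tensor (contexts x
    ligand-receptor pairs x sender cell types x receiver cell types) from
    per-context expression data or from edge lists produced by external
    cell-cell communication tools, and deconvolves it into interpretable
    communication modules via non-negative CANDECOMP/PARAFAC decomposition
    fitted by alternating least squares. Includes rank selection by
    reconstruction-error elbow, a simulator embedding temporal communication
    patterns, decomposition comparison via the CorrIndex, factor-specific
    communication networks with Gini coefficients, pre-ranked gene-set
    enrichment on ligand-receptor loadings, group statistics and
    hierarchical clustering of sample loadings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    fgsea,
    yaml,
    optparse
Config/testthat/edition: 3
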
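Package: mdmnet
Title: Integrative Gene-Lipid-Biomarker Correlation Networks for
    Macrophage Multi-Omics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An integrative analysis pipeline for two-group macrophage
    multi-omics studies: TMM-normalized log-CPM differential expression
    with an empirical-Bayes moderated t-statistic, single-sample gene-set
    variation scoring by a rank-based random walk, association of genes
    and pathway scores with continuous serum covariates, and a thresholded
    gene-lipid-biomarker Pearson correlation network built by ranking
    lipid species on their average correlation to the top differentially
    expressed genes. Includes a seeded synthetic study generator
    (negative-binomial counts, a 13-class serum lipidome, and an
    inflammation biomarker panel coupled through a latent factor) used as
    the test bed for the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    Matrix,
    igraph,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    limma,
    edgeR
Config/testthat/edition: 3
RoxygenNote: 7.3.3
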
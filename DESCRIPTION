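Package: psnet
Title: Clinical and Biological Similarity Networks of Phenotypic Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies clinical and biological similarity between groups of
    inherited diseases (OMIM phenotypic series) from ontology annotations.
    Parses OBO ontologies (HPO, GO, DO), GAF and phenotype-annotation files,
    computes Resnik information content and most-informative common ancestors,
    reduces each series' disease annotations to representative term profiles,
    scores all series pairs with the best-match-average similarity coefficient,
    assembles weighted clinical (HPO-based) and biological (GO-based) similarity
    networks, sweeps similarity thresholds to isolate islands of highly similar
    series, clusters series by their similarity profiles (uncentered Pearson,
    average linkage), and cross-tabulates clinical versus biological similarity
    by quadrant. Includes a synthetic-cohort generator with planted group
    structure so the whole pipeline is testable without database downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    ape,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
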
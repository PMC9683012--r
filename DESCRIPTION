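Package: paleoeve
Title: Authentication and Molecular Dating of Endogenous Viral Elements
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for paleovirological analysis of ancient endogenous viral
    elements (EVEs) shared across host genomes: synteny-anchored orthology
    calling from flanking landmark genes, six-frame translated local-alignment
    homology search with Karlin-Altschul statistics and inactivating-mutation
    annotation, alignment utilities (MAF slicing, profile merging, trimming,
    p-distances), node-calibrated relaxed-clock Bayesian molecular dating with
    a Felsenstein pruning likelihood, and a resampling neutrality test against
    noncoding null regions. Includes a synthetic-genome simulator with known
    ground truth for end-to-end validation of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    ape,
    Biostrings,
    stats,
    utils,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
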
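Package: igcscan
Title: Detection of Interlocus Gene Conversion in Segmental Duplication Families
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to detect and characterize historical interlocus gene
    conversion (IGC) among paralogous segmental duplications. Implements a
    phylogenetic quartet method that classifies parsimony-informative sites as
    concordant, reticulate, or bimutational and tests for a reticulate-site
    excess against a GTR+Gamma+I simulation null; a Sawyer-style permutation
    scan for unusually long tracks of perfect identity between sequence pairs;
    conversion-track and crossover-breakpoint estimation from reticulate-site
    clusters; randomization tests for the genomic context of conversion tracks;
    and equilibrium estimators of the per-generation IGC rate. A synthetic-data
    generator produces paralog families with known injected conversion and
    crossover events for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    Rcpp,
    stats,
    utils,
    Biostrings,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr
Config/testthat/edition: 3
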
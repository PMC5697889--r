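Package: mgprofiler
Title: Gene- and Genome-Centric Functional Profiling of Herbivore Gut Metagenomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A comparative metagenomics workflow for host-associated microbial
    communities: coverage-weighted CAZyme and KEGG pathway profiles of
    assembled metagenomes, lignocellulose-degradation category tables,
    differential pathway detection (Welch's t-test with Benjamini-Hochberg
    correction), taxon-profile community structure (Bray-Curtis dissimilarity,
    UPGMA clustering), population-genome quality filtering, abundance and
    pathway-coverage metrics, a completeness-weighted differential-metabolism
    contributor score, urea-processing screening, and reciprocal-best-hit
    average amino acid identity via exact affine-gap local alignment. A
    synthetic community generator with known ground truth exercises every
    stage end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    Rcpp,
    yaml,
    ape,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
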
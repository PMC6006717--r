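Package: stoichioprot
Title: Subcellular Stoichiogenomics of Protein Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for stoichiogenomic analysis of subcellular proteomes:
    elemental (C, H, O, N, S) and charged amino-acid composition of protein
    sequences partitioned by subcellular location, isoelectric-point
    computation and electrostatic-complementarity statistics over
    protein-protein interaction pairs, bidirectional-best-hit comparison of
    subcellular proteomes against prokaryotic analogs, charged-residue
    composition of structure-derived interaction interfaces, dual-criterion
    (Mann-Whitney + Kolmogorov-Smirnov) nonparametric comparison, and a
    synthetic-data generator that emulates the statistical structure of the
    curated inputs so every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    bio3d,
    dplyr,
    generics,
    ggplot2,
    methods,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
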
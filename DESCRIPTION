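Package: astax
Title: Taxonomy-Aware Subsampling of Homologous Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Selects a taxonomically diverse, evenly spread subset of m
    representative sequences from a pool of n homologs by recursive
    proportional allocation over a rooted taxonomy (NCBI taxdump or a
    simple edge list), following the AST (automated sampling over taxa)
    algorithm. Includes similarity-rank and uniform-random baseline
    samplers, a BLAST XML report importer, simulated symmetric,
    asymmetric and random taxonomy benchmarks, and an evaluation
    harness that measures taxonomic coverage at each level of the
    hierarchy across replicate simulations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    xml2
Suggests:
    ape,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
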
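Package: pseudomap
Title: Anchoring Genome Scaffolds into Pseudomolecules with Genetic and
    Physical Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Marker-based anchoring of draft-genome scaffolds onto linkage
    groups, with dual genetic-map conflict resolution (30 cM discordance
    rule, single-dissenter removal, chimeric-scaffold splitting),
    classification of BAC-end links to physical-map contigs
    (unique/dominant/strong), neighbour propagation of placements, and
    construction of gap-padded pseudomolecules with AGP v2.1 output.
    Also provides the self-contained comparative and population
    computations used around such an assembly: Kimura two-parameter
    divergence, LTR insertion-time dating, collinearity (synteny) block
    chaining, depth-based genotype calling from genotyping-by-sequencing
    data, SNP filtering, and distance-binned linkage-disequilibrium decay.
    A seeded synthetic-genome generator produces ground-truthed scaffolds,
    dual genetic maps, BAC/physical-map evidence and a random-mating
    population in exactly the formats the pipeline reads, so the whole
    pipeline is testable end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
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
    withr
Suggests:
    ape,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
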
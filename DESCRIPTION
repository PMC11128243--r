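Package: gvlake
Title: Biogeography of Lacustrine Giant-Virus Genomes from Coverage Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies giant-virus metagenome-assembled genomes (GVMAGs)
    across lake metagenomes from per-contig read-depth tables, calls
    presence with horizontal-coverage (breadth) cutoffs, and analyses the
    resulting communities: Hellinger-transformed Bray-Curtis dissimilarity
    with NMDS ordination and PERMANOVA, unweighted UniFrac on a species
    tree with WPGMA dendrograms, UpSet-style endemism and sharing counts
    for lakes and regions, protein-cluster region distributions, and a
    random-forest co-occurrence network linking eukaryote clades to virus
    families. Includes a synthetic-community generator that emulates
    region-structured lake metagenome inputs with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    randomForest,
    stats,
    utils,
    vegan,
    yaml
Suggests:
    jsonlite,
    phyloseq,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
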
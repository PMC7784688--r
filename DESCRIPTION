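Package: prophagenet
Title: Prophage-Host Interaction Networks, Defense-System Targeting and
    Capsule-Loss Dynamics in Klebsiella
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to analyse networks of induced prophage-bacteria
    interactions in Klebsiella panels. Implements weighted gene repertoire
    relatedness (wGRR) between prophage proteomes from bidirectional best
    hits, superinfection-immunity screening via repressor similarity,
    CRISPR spacer/protospacer matching and restriction-modification
    recognition-motif scanning for defense-targeting inference, exact
    contingency statistics for capsule serotype modularity of
    all-against-all infection matrices, and area-under-the-curve analysis
    of capsule-loss trajectories from experimental evolution. Includes
    seeded synthetic-data generators emulating the statistical structure
    of such panels so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    S4Vectors,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
biocViews: Software, Genetics, Metagenomics, StatisticalMethod
RoxygenNote: 7.3.3
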
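Package: epidiatom
Title: Microscopy Versus Metabarcoding Profiles of Epibiotic Diatom
    Communities
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to compare morphology-based (light-microscopy valve
    counts) and metabarcoding-based (rbcL amplicon OTU counts) profiles of
    the same diatom biofilm communities, as sampled from individual hosts
    such as sea-turtle carapaces. Implements Bray-Curtis dissimilarity,
    non-metric multidimensional scaling, k-medoids partitioning, Mantel and
    distance-set comparison tests, Tamura-Nei (composite-frequency) genetic
    distances, greedy centroid OTU clustering, nearest-reference taxonomic
    assignment, ecological-guild profiling, and an inference chain that
    relates pairwise OTU genetic distance to co-occurrence across hosts to
    detect cryptic lineage groups within a morphospecies. A synthetic-data
    generator produces paired observation tables with explicit bias
    mechanisms (biovolume-dependent gene copy number, dead-frustule
    carryover) and full ground truth, so every stage of the pipeline is
    testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    Biostrings,
    cluster,
    optparse
Config/testthat/edition: 3
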
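Package: t6sscope
Title: Detection and Comparative Genomics of Plasmid-Encoded Type VI Secretion Systems
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for locating type VI secretion system (T6SS) gene clusters on
    ordered gene-annotation tables and classifying them as complete systems,
    incomplete clusters, orphan islands, or isolated hcp/vgrG genes; for
    characterizing the carrying replicons (megaplasmid status, conjugative
    transmissibility, GC divergence from the host chromosome, partition and
    toxin-antitoxin maintenance systems); for screening gene windows around each
    locus for mobile-genetic-element signatures; for building bipartite
    replicon-protein networks and ANI networks with Louvain community detection
    and host-range grading; for patristic-distance and closest-homolog analyses;
    and for two-state (plasmid/chromosome) ancestral reconstruction under the
    F81 model with marginal posteriors and MPPA state selection. A synthetic-data
    generator plants clusters, islands, traits, transfer communities, and
    compartment-switch events with known ground truth so every stage of the
    pipeline can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
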
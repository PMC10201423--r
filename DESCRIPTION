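Package: circstar
Title: Circular Matching of RNA 3D Structures by Conserved Stack Anchors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Detects circular (sequence-order-rotated) local matches between
    two RNA 3D structures. Conserved base-pair stacks are superposed in direct
    and strand-exchanged (rotated) orientation, internal loops and multiloops
    closed by rotated-matched stacks seed a Bron-Kerbosch style extension over
    a circular interval-compatibility relation, and the resulting compatible
    stack-pair sets are assembled into scored, RMSD-filtered nucleotide-level
    circular alignments. Includes the ACS/PCSI/PCSS alignment-quality metrics,
    a DSSR-style JSON annotation reader with a geometric fallback base-pair
    detector, and a ground-truthed synthetic structure generator (ideal
    helices, junctions, circular permutations) for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
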
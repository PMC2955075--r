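Package: adswap
Title: Detection and Alignment of 3D Domain-Swapping Proteins
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pairwise detection and alignment of three-dimensional domain
    swapping (DS) between protein structures. Secondary structural elements
    (SSEs) are vectorized and transformed into angle-distance (A-D) images;
    equivalent SSEs are extracted with a pair-graph matching algorithm that
    does not depend on structural superposition, so both the main and the
    swapped domain of a closed/open pair are matched simultaneously. A
    superposition-dependent residue alignment (anchor dynamic programming
    with iterative Kabsch refinement) then localizes candidate hinge loops
    through the profile of the angle-distance product, refines their opening
    points, and validates swapped domains. Virtual (two-transform) similarity
    measures and a trainable, normalized DS score summarize the evidence for
    a domain-swap relationship. A seeded generator of synthetic closed and
    open two-domain chains makes the whole pipeline testable without
    structure downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    bio3d,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
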
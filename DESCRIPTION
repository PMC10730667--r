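Package: mfnj
Title: Multifurcating Neighbor-Joining for Polytomic Phylogenetic Trees
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Distance-based phylogenetic tree reconstruction that resolves
    ties in the neighbor-joining selection criterion by joining whole groups
    of operational taxonomic units (OTUs) at once, yielding a unique,
    possibly multifurcating tree that does not depend on the input order of
    taxa. Includes the classic neighbor-joining algorithm, an exhaustive
    tie-break enumerator, readers and writers for PHYLIP and delimited
    distance matrices, Newick serialization with unrooted split comparison,
    and a generator of additive and star distance matrices with known
    ground truth for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
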
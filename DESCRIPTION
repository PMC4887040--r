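Package: sitematch
Title: Active-Site Matching and Side-Chain Repacking for Computational Enzyme Design
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Places a transition-state model together with a multi-residue
    catalytic motif (catalytic residues, residues stabilizing them, and
    residues binding the transition state) onto protein scaffolds by
    continuous kinematic loop closure with aggressive pruning, ranks the
    resulting matches, and evaluates them by rotamer-based side-chain
    repacking (hydrogen-bond recovery and binding energy).  Includes a
    scaffold-library filtering and screening pipeline and a synthetic-fixture
    generator that plants constraint-satisfying active sites in toy
    scaffolds so the full pipeline is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    bio3d,
    yaml,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
NeedsCompilation: yes
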
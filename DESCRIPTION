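Package: decaaf
Title: Active-Site Scaffold Matching and Superposition for Directed Evolution Target Selection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ranks candidate proteins for directed evolution by the spatial and
    electrostatic congruence of partial active-site motifs against a template
    catalytic scaffold, superimposes template and target on a three-atom partial
    match via an exact canonical-frame construction, reports steric
    neighborhoods around catalytic atoms, and proposes activity-bestowing
    mutations at target residues near unmatched template residues. Reads PDB
    and PQR structures, attaches electrostatic potentials from
    Poisson-Boltzmann solver grids (OpenDX), per-atom tables, or a built-in
    screened-Coulomb model, and includes a synthetic-structure generator so the
    whole pipeline is testable without downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
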
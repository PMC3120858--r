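Package: flipsite
Title: Hydrogen-Bond Network, Hydration and Linear Interaction Energy
    Analysis of Base-Flipping Binding Pockets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis toolkit for molecular-dynamics studies of protein-DNA
    complexes in which a modified cytosine is flipped out of the duplex into
    a protein binding pocket. Reads structures, CHARMM-style residue
    topologies with partial charges, and trajectories; constructs a
    5-hydroxymethylcytosine residue from 5-methylcytosine parameters by
    hydroxyl substitution with serine-derived charges; detects hydrogen
    bonds geometrically and builds per-frame occupancy timelines; tracks
    water entry and conserved hydration sites in the pocket; computes
    Kabsch-superposed RMSD series and RMSF profiles; estimates binding free
    energies with the Linear Interaction Energy (LIE) approximation from
    pairwise Coulomb and Lennard-Jones interaction energies with CHARMM
    switching; and quantifies two-color competitive DNA pull-down binding
    assays. Ships a synthetic toy-complex generator with planted ground
    truth so the whole pipeline is testable without simulation data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
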
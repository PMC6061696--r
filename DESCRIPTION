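Package: uturn
Title: Ensemble Analysis of RNA U-Turn Hydrogen Bonding, Ion Binding and
    NMR Observables
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for characterizing the U-turn motif of small RNA hairpins
    such as the neomycin-sensing riboswitch from multi-model coordinate
    ensembles (NMR-style multi-model PDB files or frame-series trajectories).
    Provides hydrogen-bond and water-bridge detection under configurable
    distance/angle criteria, classification of cis Watson-Crick U/U base-pair
    conformers (direct versus water-mediated arrangements) with population and
    transition statistics, r^-6 ensemble-averaged NOE distance validation,
    monovalent-cation binding-site occupancy, radial distribution functions,
    density maxima and residence-time statistics, least-squares base-plane
    fitting with plane-to-atom distance series, iterative ensemble
    superposition with per-residue RMSD, and nonlinear fitting of NMR
    titration isotherms (single-site and Hill-2 cooperative) and of
    trans-hydrogen-bond scalar couplings from constant-time intensity ratios.
    A synthetic-data layer generates Markov-switching conformer ensembles,
    two-state ion trajectories, titration curves and cosine intensity decays
    with declared statistical structure for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    bio3d,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
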
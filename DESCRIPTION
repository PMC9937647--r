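Package: polstates
Title: Conformational-State Analysis of Single-Molecule Fluorescence Polarization Traces
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for four-channel polarized fluorescence intensity
    recordings of single fluorophore-labelled membrane-protein molecules. Converts
    EMCCD camera counts to photon counts, detects orientation transitions with a
    binned-photon log-likelihood-ratio changepoint algorithm, solves fluorophore
    dipole orientations (theta, phi) with full optical corrections, sorts dwell
    events into conformational states by k-means clustering on the unit sphere with
    simulated annealing and Nelder-Mead refinement, aligns molecules into a common
    local frame, fits an eight-state ligand-binding equilibrium model to state
    probabilities across ligand concentrations with bootstrap confidence intervals,
    and relates conformational states to structural states by orthogonal-Procrustes
    permutation matching. Includes a synthetic-data generator emulating the
    microscope's photon statistics so every stage is verifiable without
    experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
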
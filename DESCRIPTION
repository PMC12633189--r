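Package: crossbridge
Title: Chemo-Mechanical Analysis of ADP Release and Cross-Bridge Kinetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis machinery for studying nucleotide handling in the
    actomyosin cross-bridge cycle. Provides descriptors of nucleotide-pocket
    dynamics from molecular-dynamics trajectories (RMSD/RMSF, residue contacts,
    ligand dihedral maps with conformational entropy and coverage, linear
    interaction energies, occupancy grids), Jarzynski free-energy analysis of
    steered-pulling work ensembles, stopped-flow competitive-binding fits of
    the apparent ADP affinity, and decomposition of myofibril force traces
    into activation kinetics and the biphasic (linear slow + exponential fast)
    relaxation. Every input class can be generated synthetically with known
    ground truth, so the full pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    minpack.lm,
    jsonlite,
    bio3d,
    car,
    emmeans,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
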
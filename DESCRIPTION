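Package: remcdock
Title: Replica-Exchange Monte Carlo Docking Samplers with Pareto-Front
    Replica Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Sampling engines for protein-small-molecule docking pose
    prediction: Metropolis Monte Carlo, replica-exchange Monte Carlo
    (parallel tempering), and two multi-objective variants that re-seed
    the replica ensemble from the Pareto front of the sampling history
    over (Monte Carlo step, total score).  Includes a coarse-grained
    contact score and a weighted full-atom score engine with simplified
    surrogate terms, ligand RMSD and binding-energy (interface delta)
    diagnostics, near-duplicate filtering and decoy ranking, temperature
    occupancy diagnostics, synthetic fixtures (discrete and double-well
    landscapes with closed-form Boltzmann behaviour, toy complexes with a
    planted binding pocket), minimal PDB input/output, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
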
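Package: rampclamp
Title: Ramp-Clamp Steered-Dynamics Trajectory Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis toolkit for "ramp-clamp" steered-dynamics studies of
    receptor-ligand complexes such as CD47/CD172a.  Provides readers and
    writers for PDB and multi-frame XYZ trajectories, atom selection,
    Kabsch superposition with Ca-RMSD/RMSF, radius of gyration,
    Shrake-Rupley solvent-accessible surface area and buried interface
    area, geometric hydrogen-bond detection with occupancy (survival
    ratio) statistics, dissociation-probability estimators and
    force-response bond typing, a generalized-Born binding-energy
    decomposition, and a coarse-grained elastic-network Langevin engine
    implementing constant-velocity (force-ramp) pulling followed by
    force-clamp holding with one- or two-anchor loading geometries.
    Seeded synthetic-data generators supply every input class with known
    ground truth so the full analysis runs end to end offline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    bio3d,
    deSolve,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
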
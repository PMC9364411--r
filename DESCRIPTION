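Package: mdlens
Title: Post-Simulation Analysis of Receptor-Ligand Molecular Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the post-simulation analysis of protein-ligand
    molecular dynamics, built around the workflow used to study agonist
    stereoselectivity in the free fatty acid receptor FFAR1: geometric
    detection of noncovalent protein-ligand interactions and per-frame
    interaction fingerprints; residue interaction networks with betweenness
    centrality and all-shortest-path enumeration for allosteric analysis;
    trajectory geometry descriptors (Kabsch superposition, RMSD, RMSF and
    B-factors, Shrake-Rupley solvent accessible surface area, helix-helix
    distances, Kabsch-Sander secondary structure and helix fractions); and
    absolute binding free energy machinery (lambda schedules, the multistate
    Bennett acceptance ratio estimator, the analytical Boresch restraint
    correction and thermodynamic-cycle composition). A synthetic-structure
    generator provides helices, helix bundles, planted-interaction complexes,
    jittered trajectories and multi-state Gaussian ensembles with known
    ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    igraph,
    yaml,
    stats,
    utils,
    tools,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
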
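# mdlens

Post-simulation analysis of receptor–ligand molecular dynamics, built
around the workflow used to dissect agonist stereoselectivity in the free
fatty acid receptor FFAR1 (GPR40), a class A GPCR and type 2 diabetes drug
target. Given structures and trajectories of a helix-bundle receptor with
a bound small-molecule agonist, the package answers the questions that
workflow asks:

- **Which noncovalent contacts hold the ligand?** Geometric detection of
  salt bridges, hydrogen bonds, π-stacks and hydrophobic contacts
  (PLIP-style rules), per-frame interaction fingerprints, and salt-bridge
  distance series such as ligand-carboxylate ↔ R183^5.39 / R258^7.35.
- **How does the signal travel?** Residue interaction networks (closest-atom
  contacts, multiple interaction types per edge), betweenness centrality,
  exhaustive shortest-path enumeration, and centrality-filtered allosteric
  paths (e.g. R258^7.35 → L112^ICL2).
- **How does the receptor move?** Kabsch superposition, ligand RMSD, RMSF
  and B-factors (B = 8π²/3 · RMSF²), Shrake–Rupley SASA of the G-protein
  cavity, TM helix–helix distance distributions, and Kabsch–Sander
  secondary structure with region helix fractions.
- **How strongly does it bind?** The absolute-binding-free-energy
  machinery: λ schedules (restraint / Coulomb / van der Waals legs), the
  multistate Bennett acceptance ratio (MBAR) estimator on reduced-potential
  matrices, the analytical Boresch six-degree-of-freedom restraint
  correction, and thermodynamic-cycle composition

  ΔG_bind = −ΔG^int_complex + ΔG^int_water + ΔG_restr_on.

A synthetic-data module generates every input with known ground truth —
ideal helices, TM-like bundles, complexes with planted interactions,
harmonically jittered trajectories, multi-state Gaussian ensembles with
closed-form free energies — so every stage is validated against analytic
or brute-force oracles.

## Worked example

```r
library(mdlens)

# a 7-helix TM-like bundle with a planted carboxylate-arginine salt bridge
b  <- build_bundle(7, 20, ring_radius = 9)
cx <- plant_complex(b, list(
  list(kind = "salt_bridge", residue = "A:510", distance = 3.0)))
detect_interactions(cx, "chain L", kinds = "salt_bridge")
#>          kind residue partner dist angle offset frame
#> 1 salt_bridge   A:510     LIG    3    NA     NA     0

# MBAR on a two-state harmonic ensemble with known answer ln(2) = 0.693
g   <- gen_ensemble(kappa = c(1, 4), n = 5000, seed = 42)
fit <- mbar_solve(g$ensemble, seed = 7)
print(fit)
#> <mbar_fit> 2 states, T = 300 K
#>   f_k (kT): 0.0000 0.6968
#>   endpoint dG = 0.4154 kcal/mol +/- 0.0055

# compose a published thermodynamic cycle (kcal/mol)
print(compose_cycle(-121.602, 103.941, 6.559, se = c(0.524, 0.254, 0)))
#> <cycle_result> (kcal/mol)
#>   -dG_complex    -121.602
#>    dG_water       103.941
#>    dG_restr_on      6.559
#>    dG_bind        -11.102 +/- 0.582
```

The fingerprint/network/descriptor stages run end to end from one YAML
config via `run_pipeline()` (see `?run_pipeline`), with a thin shell
wrapper in `inst/scripts/run_pipeline.R`.

## Documentation

The methods vignette (`vignettes/mdlens-methods.Rmd`) describes the
geometric criteria and their defaults, the network conventions, the MBAR
and Boresch derivations with their numerical tolerances, what the
synthetic generators do and do not emulate, and the package's known
limitations.
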
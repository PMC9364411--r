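---
title: "mdlens: methods, defaults and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{mdlens: methods, defaults and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`mdlens` implements the post-simulation analysis workflow used to study
agonist stereoselectivity in FFAR1, a class A GPCR: protein–ligand
interaction profiling, residue-interaction-network (RIN) allosteric
analysis, trajectory geometry descriptors, and absolute binding free
energy (ABFE) estimation. This vignette records the models, the tunable
parameters and their defaults, the numerical choices, and the design
decisions taken where the problem left the design open. It states no
empirical result that the test suite and `scripts/acceptance.R` do not
themselves compute.

## Structures, trajectories and selections

Structures are ordered atom tables; residue identity is the triple
(chain, residue number, insertion code), taken verbatim from the input —
no renumbering ever happens silently. Alternate locations other than
`''`/`'A'` are dropped so geometry is deterministic. Hydrogens are kept
when present; each detector states whether it needs them. Trajectories
are multi-model PDB files (one MODEL per frame, topology from MODEL 1);
frame stride is whatever the user wrote out — the package never infers a
time step, and windows in the pipeline are therefore expressed as frame
fractions (first 20 %, last 50 %, …) rather than nanoseconds.

Generic residue numbering (Ballesteros–Weinstein labels such as `5.39`,
or region labels such as `ICL2` shared by several residues) is attached
from a 4-column TSV and addressed in the selection language via
`label 5.39`. Selections are conjunctions of simple clauses and always
resolve to an ordered, duplicate-free atom set.

## Interaction detection (contacts)

Detection is purely geometric, with PLIP-like default criteria; the
profiling tool this emulates publishes rules, not per-study thresholds,
so every cutoff is a config value in `contact_params()`:

| kind        | rule                                                        | default |
|-------------|-------------------------------------------------------------|---------|
| salt bridge | centroid distance between opposite formal-charge groups     | ≤ 5.5 Å |
| H-bond      | donor–acceptor distance, and D–H···A angle when H present   | ≤ 3.6 Å, ≥ 120° |
| H-bond (no H) | heavy-atom fallback for hydrogen-free donors              | ≤ 3.5 Å |
| π-stack     | ring-centroid distance; inter-plane angle parallel or T-shaped; in-plane offset | ≤ 5.5 Å; ≤ 30° or 60–90°; ≤ 2.0 Å |
| hydrophobic | apolar carbon pair distance                                 | ≤ 4.0 Å |

Protein chemistry comes from built-in residue templates: Asp/Glu
carboxylates, Lys ε-amine and Arg guanidinium are charged at pH 7, His
only when explicitly flagged protonated (the modelled receptor carries no
protonated histidine). Ligand chemistry is supplied as a small TSV
(atom → role: `acid_O`, `base_N`, `ring`, `donor`, `acceptor`,
`apolar`), because ligand protonation and aromaticity are facts about the
molecule, not something a geometric detector should guess. The
heavy-atom H-bond fallback exists because trajectory dialects often strip
hydrogens; which mode applied is visible from the angle column (NA under
fallback). Ties at identical minimum distances resolve to the first pair
in atom order.

Fingerprints report, per (residue, kind), the fraction of window frames
in which the interaction is detected; rows are limited to residues that
actually contact the ligand. Occupancies are monotone non-increasing
under any cutoff tightening, which the suite checks. Salt-bridge series
take the per-frame minimum over all (acidic O, basic N) pairs, matching
how carboxylate–arginine distances are conventionally tracked.

## Residue interaction networks (rinnet)

Edges follow the closest-atom ("Closest") convention with multiple
("Multiple") interaction-type labels: residues i, j are connected when at
least one kind qualifies — hydrogen bond (donor/acceptor heavy atoms
≤ 3.5 Å), ionic (opposite-charge centroids ≤ 4.0 Å), π-stack (ring
centroids ≤ 6.5 Å), or van der Waals (closest atoms within Bondi radii
sum + 0.5 Å). Same-chain neighbours with |Δresno| < 2 are excluded,
mirroring the usual contact-map convention; the threshold is a parameter.
Multiple kinds never multiply edge weight: graphs are unweighted for path
analysis, because the allosteric question is counted in traversed nodes,
not interaction energies.

Betweenness is pair-count betweenness with fractional credit across
degenerate shortest paths, computed per component (optionally normalised
by (n−1)(n−2)/2); `rin_shortest_paths()` enumerates *all* minimal-hop
paths, ordered lexicographically so output is deterministic.
`filter_paths()` keeps paths whose intermediate nodes all sit at or above
a betweenness percentile — default 75th, a choice this package makes
explicitly since "high betweenness" has no canonical cutoff — and
annotates each survivor with the mean betweenness of its intermediates.
Both operations are validated against brute-force path enumeration on
random graphs up to 30 nodes.

Network input from a trajectory window is the **medoid** frame (minimum
summed pairwise superposed RMSD), not a coordinate-average structure:
averaging deforms bond geometry and would feed the detectors unphysical
coordinates. This deliberately replaces the "average structure from
cluster analysis" device; the medoid is the analogous representative that
is guaranteed to be a real frame.

## Trajectory descriptors

* **Superposition** is closed-form Kabsch via SVD with a determinant
  correction (proper rotations only); degenerate (collinear, < 3 atom)
  inputs error out. Ligand RMSD superposes each frame on a receptor
  selection and measures the ligand without refitting.
* **RMSF** is computed about the mean structure after two superposition
  passes (align to frame 1, re-align to the mean), averaged within
  residues, and converted to B-factors as B = (8π²/3)·RMSF². Note the
  fit itself absorbs six rigid degrees of freedom, so recovery of a
  planted isotropic fluctuation σ (RMSF → √3 σ) is exact only as the atom
  count grows; with ≳ 100 fitted atoms the bias is below 1 %.
* **SASA** is Shrake–Rupley with a deterministic golden-spiral point set
  (default 960 points, probe 1.4 Å, Bondi radii, overridable by TSV).
  Quadrature error against the closed-form sphere and two-sphere
  spherical-cap results is within 1–2 % at the default point count.
  Cavity SASA sums per-atom areas of a fixed residue list (e.g. the 45
  G-protein-cavity residues mapped from a β2AR template) computed in the
  context of the whole structure — the cavity list is an input, never
  inferred.
* **Helix–helix distances** are distances between Cα centroids of two
  user-specified residue ranges. The upstream workflow does not define
  its distance groups, so the ranges live in config where they are
  explicit and reproducible; both per-frame series (time-average) and the
  medoid-structure measurement are available, since either reading of a
  "helix deflection" is defensible.
* **Secondary structure** is a reduced Kabsch–Sander assignment (H/E/C):
  backbone H-bonds scored by E = 0.084·332·(1/d_ON + 1/d_CH − 1/d_OH −
  1/d_CN) kcal/mol with the −0.5 kcal/mol threshold, helix from two
  consecutive i→i+4 turns, strand from minimal parallel/antiparallel
  bridge patterns. Amide hydrogens are reconstructed at 1.01 Å from N
  opposite the C(i−1)–N–Cα bisector when absent. Full 8-state DSSP
  parity is a non-goal; only helix fractions are consumed downstream.

## ABFE machinery (abfe)

**λ schedules.** Three legs — restraint switching, charge decoupling,
Lennard-Jones decoupling — each strictly increasing from 0 to 1. The
reference protocol shipped in `reference_schedule()` has 11 + 5 + 16
windows; the validator reports window counts rather than assuming a
total, because published window tallies are easy to miscount across
complex and solution legs.

**MBAR.** Reduced potentials u[k, n] (units of k_BT) with per-state
counts N_k. The self-consistent equations are solved by minimising the
equivalent convex objective with BFGS (analytic gradient), then polishing
by self-consistent iteration to 1e-8 k_BT, anchored at f_1 = 0. Free
energies are gauge-invariant: adding a constant to one state's reduced
potentials shifts only that state's f, which the suite asserts.
Uncertainties come from a seeded block bootstrap (default 200 resamples,
block length 1 — samples are assumed decorrelated; a statistical-
inefficiency subsampler is provided but off by default, and raising the
block length handles correlated input). For two states MBAR reduces to
BAR; the suite checks agreement with an independent scalar-root BAR
solver to 1e-6 k_BT.

**Boresch restraint correction.** For one distance, two angles and three
dihedrals with half-convention force constants k (u = (k/2)(ξ−ξ₀)²; a
`full` flag converts K → 2K, since published force-constant conventions
are frequently ambiguous):

ΔG_on = k_BT · ln[ 8π² V₀ √(∏k) / ( d² sinθ_A sinθ_B (2π k_BT)³ ) ]

with V₀ = 1660 Å³ (1 M standard state; stated explicitly because it is
rarely printed). This is the stiff-spring (harmonic) closed form. Its
error relative to the exact restrained configurational integral is of
order k_BT·σ²/2 per angular degree of freedom with σ² = k_BT/k: about
0.017 kcal/mol at k = 20 kcal mol⁻¹ rad⁻² (typical published ABFE
stiffness, where the approximation is accepted as part of the method) and
below 10⁻³ kcal/mol only for k ≳ 350. The quadrature-agreement property
test therefore samples the stiff regime (k ∈ [400, 1200]) where closed
form and integral must coincide to 1e-3 kcal/mol, and a separate test
pins the k = 20 discrepancy at its predicted ~0.02 kcal/mol scale.
Results carry a reliability flag that trips when any angular width
√(k_BT/k) exceeds 30°. ΔG_on *increases* with temperature (restraining
costs more entropy when fluctuations are larger); the suite checks the
sign of the trend against the quadrature oracle.

**Cycle composition** is exact arithmetic,
ΔG_bind = −ΔG^int_complex + ΔG^int_water + ΔG_restr_on, with component
uncertainties combined in quadrature. The shipped component table for the
two AM-8596 epimers reproduces the published ΔG_bind values to the
printed three decimals, which is what `scripts/acceptance.R` recomputes.

**Ensemble format.** A TSV with a `#T_kelvin=` metadata line, a header of
state columns, and one row per sample labelled with its origin state;
round-trips exactly and feeds `mbar_solve()` directly.

## Synthetic generators (synthgen)

The generators define the validation conditions; they are deterministic
given their seed.

* `build_helix()` constructs backbone (+ amide H, + Cβ stub) from
  standard internal coordinates at given φ/ψ; the α defaults give a
  ~1.5 Å/residue Cα rise. `build_bundle()` rings helices at a given
  radius (default 9 Å, chosen so a 7-helix ring is mutually in van der
  Waals contact without clashing — the scale of a TM bundle's packing),
  labelling helices TM1..TMn.
* `plant_complex()` places idealised ligand groups (carboxylate, benzene
  ring, H-bond nitrogen, apolar carbon) so each requested interaction
  holds by construction, mutating the target residue to a type carrying
  the matching group (Arg guanidinium, Phe ring) as an idealised
  side-chain stub. Placement searches a deterministic list of candidate
  directions (away from the local helix axis, away from the bundle,
  tilted variants) and errors as unsatisfiable if no clash-free geometry
  exists — inward-facing residues genuinely cannot host a planted surface
  ligand, which is a property of the geometry, not a failure of the
  detector. Randomised plant→detect tests therefore draw from
  satisfiable plans, consistent with the plant-specification invariant
  that planted geometries be clash-free.
* `jitter_trajectory()` adds i.i.d. Gaussian noise — an equilibrium
  fluctuation model with known RMSF (√3 σ) and pair-distance spread
  (√2 σ).
* `gen_ensemble()` draws from 1-D harmonic states u_k = κ_k(x−μ_k)²/2,
  where Δf = ½ ln(κ_j/κ_i) in closed form. One-dimensional toys are used
  deliberately: the estimator consumes only reduced potentials and is
  dimension-agnostic, while 1-D states keep the ground truth analytic.

What the generators do **not** emulate: force-field energetics,
anharmonic and correlated fluctuations, solvent and membrane, side-chain
rotamers, or conformational transitions. Passing tests demonstrate the
*analysis* is correct on data whose answer is known — not that any MD
sampling was converged.

## Pipeline and problem sizes

`run_pipeline()` executes contacts → networks → descriptors → ABFE per
system from one YAML config, deterministically under the config seed,
writing TSV tables stamped with config hash, seed and package version.
Replicate simulations are handled as separate systems and aggregated via
`compare_reports()`, which tabulates per-system metrics and antisymmetric
pairwise deltas without inventing significance tests.

Validation problem sizes are desk-scale by design: 7×20-residue bundles
(140 residues), trajectories of up to 5000 jittered frames for
fluctuation recovery, ensembles of 5000 samples per state for the
harmonic MBAR checks, 100 random graphs of ≤ 30 nodes for the path
oracles, and 50 randomised plants for detector round-trips. These sizes
make every oracle exhaustive or analytic while keeping the full suite in
tens of seconds.

## Known limitations

* PDB only (no mmCIF); multi-model PDB is the one mandatory trajectory
  dialect; no bond perception beyond the residue/ligand templates.
* No halogen bonds, water bridges, or cation–π detection; charges come
  from templates, not pKa calculation.
* Networks are structural, not energy-weighted or correlation-based.
* The Boresch correction is harmonic; soft restraints (widths > 30°) are
  flagged, not corrected.
* The package consumes trajectories and energy tables; it never runs
  dynamics, evaluates soft-core potentials, or computes cavity topography
  (the cavity residue list is an input).
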
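---
title: "Modelling saponin–sterol membrane interactions with frondosim"
author: "frondosim authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling saponin-sterol membrane interactions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(frondosim)
```

## The scientific question

Sea cucumbers (holothuroids) secrete triterpene saponins — amphiphilic
glycosides such as Frondoside A — as a chemical defense, yet their own
membranes tolerate these membranolytic compounds. A long-standing
explanation is the sterol composition of holothuroid membranes: instead of
cholesterol they carry Δ7 sterols (5α-cholest-7-en-3β-ol), whose 7,8
double bond bends the molecule into an "L" shape. Saponins permeabilize
membranes by sequestering sterols into large clusters; a sterol whose
shape resists that sequestration would protect the cell.

`frondosim` implements, as reusable and tested components, the
computational chain with which this hypothesis can be examined at coarse
desk scale:

1. **Implicit-bilayer insertion profiling** (`insertionScan`): where does
   an amphiphile sit in a membrane?
2. **Pairwise interface docking** (`dockPair`, `buildInteractionMatrix`):
   how strongly does the saponin couple to each lipid, per heavy atom?
3. **Lattice monolayer Monte Carlo** (`initLattice`, `mcMinimize`): what
   phase pattern do those couplings produce in a 200 × 200 molecular
   monolayer?
4. **Domain quantification and comparison** (`labelDomains`,
   `domainStats`, `welchTest`, `compareSystems`): are sterol clusters
   large and few, or small and many?
5. **Wet-lab arithmetic** (`leakagePercent`, `subtractBlanks`,
   `fitBindingIsotherm`, `deriveThermodynamics`): the calcein-release
   normalization and ITC thermodynamics that anchor the in vitro side.

A sixth module of seeded generators (`fixtureMolecule`,
`syntheticInteractionMatrix`, `simulateItcTrace`,
`simulateLeakageTrace`) produces every input the pipeline needs, so the
whole chain runs end-to-end without proprietary data.

## The implicit membrane

The bilayer is described by a single empirical hydration function of
depth $z$ (Å, origin at the bilayer center),

$$C(z) = 1 - \frac{1}{1 + e^{\alpha(|z| - z_0)}},$$

running from ~0 (hydrophobic core) to ~1 (bulk water), with steepness
$\alpha = 1.99$ and the hydrophilic/hydrophobic interface at
$|z| = z_0$. The bilayer is 36 Å thick (half thickness 18 Å). $z_0$ is
not uniquely fixed by that description; we use 13.5 Å, the conventional
polar-head/alkyl-chain boundary for a 36 Å bilayer, and expose it as a
parameter of `implicitMembrane()`.

A molecule placed in this membrane is scored by two per-atom restraints:

* hydrophobic: $-\sum_i S(i)\,E_{tr}(i)\,C(z_i)$, where $S(i)$ is the
  accessible surface (Å²) and $E_{tr}(i)$ the atomic transfer energy per
  unit surface (kJ mol⁻¹ Å⁻²; negative for apolar atoms). Apolar surface
  is penalized in water and relieved in the core, polar surface the
  reverse.
* lipid perturbation: $a_{lip}\sum_i S(i)(1 - C(z_i))$ with
  $a_{lip} = 0.0753$ kJ mol⁻¹ Å⁻² — any matter inside the bilayer
  disturbs lipid packing.

Note the units: some descriptions quote $E_{tr}$ as an energy in kJ/mol;
the restraint sum is only dimensionally consistent when $E_{tr}$ is per
unit surface, which is the convention of the editable parameter table
shipped in `inst/extdata/atom_params.csv`. Because $a_{lip}$ is smaller
than $|E_{tr}(C)|$, apolar matter nets into the membrane and polar matter
into water, which is the behavior every downstream contract relies on;
the exact value is otherwise uncritical and swappable.

`insertionScan` translates the molecular center in 1 Å steps across the
bilayer plus an 18 Å bulk-water margin on each side (so an "outside"
optimum is representable) and minimizes the restraint sum over a full
grid of the two in-plane tilt angles. The rotation about the membrane
normal leaves the restraints exactly invariant and is therefore not
enumerated. Because a full tilt grid is closed under the reflection
$(r_x, r_y) \to (r_x + 180°, -r_y)$, the resulting profile is symmetric
in $z$ to machine precision — a useful internal consistency check that
the test suite asserts at $10^{-6}$ kJ/mol. Use an angular step that
divides 180 to keep that closure exact.

## Interface docking and the interaction matrix

All molecules are first oriented at the hydrophobic/hydrophilic
interface: `orientAtInterface` aligns the axis from the apolar-weighted
to the polar-weighted centroid (weights $S \cdot E_{tr}$) with $+z$ and
puts the amphiphilic balance point — the $|S \cdot E_{tr}|$-weighted
centroid, where polar and apolar torques about the interface plane
cancel — at $z = 0$. Docking then explores only interface-preserving
moves: azimuthal placement around the central molecule, radial distance,
ligand self-rotation about $z$, and a small vertical offset. A full
rigid-body search would break the interfacial orientation that defines
the method.

Pose energies decompose into

* a 6–12 van der Waals term over heavy-atom pairs
  ($\varepsilon[(r_m/r)^{12} - 2(r_m/r)^6]$, $r_m = r_i + r_j$),
* a Coulomb term with distance-dependent dielectric
  $\varepsilon(r) = 3r$,
* a hydrophobic contact term
  $-w\,(S_i|E_{tr,i}| + S_j|E_{tr,j}|)$ for apolar–apolar pairs within
  $r_i + r_j + 1.4$ Å.

The published force field behind the original method is not public; this
empirical field is built to reproduce the *qualitative* contracts the
analysis rests on (signs, orderings, shape sensitivity), with every
constant exposed in `forceFieldParams()`. Poses with non-bonded overlap
below $0.7 (r_i + r_j)$ are rejected with sentinel energy.

Best-pose totals are divided by the number of heavy atoms to remove
molecule-size bias. For a pair we divide by the *sum* of both partners'
heavy atoms (the available descriptions leave the pair divisor open; a
single shared divisor keeps self- and cross-pairs comparable).
`buildInteractionMatrix` averages the two role assignments of each
unordered pair into a symmetric per-heavy-atom coupling table — the
input of the lattice simulation. The default `dockGrid()` is a coarse
~5 × 10³-pose grid for desk-scale work; `dockGrid("production")`
enumerates the fine grid (≥ 10⁷ poses over a molecule set) that the
method historically used. Refining a grid can only improve best-pose
energies (the test suite asserts this monotonicity).

## Fixture molecules

Chemically accurate sterol and saponin conformers are not available
(no deposited coordinates), and the scientific claims under test are
*orderings*, not calorimetric numbers. The shipped fixtures are
therefore idealized coarse geometries that make the orderings design
guarantees rather than force-field accidents:

* `cholesterol_like`: an elongated apolar rod (8 carbons, 1.8 Å spacing)
  under one polar head atom;
* `delta7_like`: the *same atoms and parameter multiset* with the lower
  half of the rod bent 90° — the "L" shape; identical formula, different
  geometry, as for the real sterol pair;
* `frondoside_like`: an amphiphilic cone — a 13-carbon apolar chain
  under a wide two-layer crown of ten polar (sugar-like) oxygens;
* `dmpc_like`: a zwitterionic head (paired ±0.35 e charges) over two
  6-carbon acyl tails.

These shapes produce, by construction: a larger interfacial footprint
for the bent sterol than for the rod; saponin–phospholipid coupling more
favorable than saponin–sterol; and saponin–cholesterol more favorable
than saponin–Δ7 (the rod packs against the saponin's chain along its
whole length, while the bent sterol cannot reach the deep aglycone).
What passing these contracts shows is that the *pipeline* propagates
shape differences of this kind into the published orderings — not that
the real molecules have these energies.

## The lattice monolayer simulation

A monolayer is a side × side grid (200 historically; tests and the
acceptance script use 100 or less) with one molecule per cell.
`initLattice` realizes a molar composition with largest-remainder
rounding (counts sum exactly to side²) and a seeded uniform shuffle. Two
compositions are preset: 67/23/10 DMPC/sterol/saponin (default) and
63/27/10 — both are in circulation for this system, so both ship and the
choice is explicit.

Energy is the sum over nearest-neighbor pairs (4-neighborhood, periodic
boundary by default; clipped available for figure-matching) of the
per-heavy-atom couplings. Minimization is Kawasaki-exchange Monte Carlo:
a proposed move exchanges the occupants of two sites — any two sites by
default (fast equilibration of a conserved mixture), or nearest
neighbors for kinetic realism — and is accepted by the Metropolis rule.
Composition is conserved exactly by construction. The temperature enters
through a dimensionless $\beta = 1/(\text{scale} \cdot T)$ because the
couplings are coarse per-heavy-atom energies: only the ratio of coupling
to temperature is meaningful. "Minimization" uses a geometric annealing
schedule (default hot = 1.2, cold = 0.05 in coupling units, 2 × 10⁶
proposals for a 100 × 100 grid in `runScenarioReplicate`) — settled once
by inspecting energy plateaus on the synthetic scenarios. The inner loop
is compiled (Rcpp) with a self-contained mt19937_64 RNG, so trajectories
are bit-reproducible per seed; incremental energies agree with full
recomputation to < 10⁻⁶ relative after 10⁶ moves (asserted in tests).

On tiny lattices the sampler can record thinned state codes
(`sampleEvery`); at fixed temperature the empirical distribution over
all $\binom{9}{4}$ arrangements of a 3 × 3 two-type lattice matches the
exact Boltzmann enumeration (chi-square, α = 0.01). Samples are thinned
(every 20 proposals) because the chain is autocorrelated and the
chi-square test assumes approximately independent draws.

## Scenario matrices

`syntheticInteractionMatrix` encodes two scenarios whose *orderings* are
fixed by construction (values in kJ/mol per heavy atom):

| pair | cholesterol_system | delta7_system |
|---|---|---|
| SAP/DMPC | −1.40 | −1.40 |
| SAP/sterol | −1.00 | −0.70 |
| sterol/sterol | −1.20 | −0.75 |
| DMPC/sterol | −0.55 | −0.62 |
| DMPC/DMPC | −0.60 | −0.60 |
| SAP/SAP | −0.90 | −0.90 |

The cholesterol system demixes strongly
($E_{SS} + E_{DD} - 2E_{SD} = -0.70$), the Δ7 system barely ($-0.11$):
annealing therefore produces few large sterol domains in the former and
many small scattered clusters in the latter — the synthetic analogue of
the observed contrast. A `null_system` (all zero) gives free dynamics
for null tests. Optional seeded jitter perturbs entries without breaking
the orderings at small standard deviations.

## Domain statistics

`labelDomains` is a connected-component labeling of the sterol-occupied
cells — the in-code equivalent of an image-analysis "particle analysis"
— with configurable connectivity (8 by default, the common particle
default) and boundary (clipped by default, since rendered grids are
analyzed as images; periodic available). Which types count as "sterol"
is an explicit parameter: saponin-associated sterol clusters can be
measured by passing the sterol + saponin type set rather than by a
hard-wired guess. Per system we report mean domain size divided by the
total sterol area (relative mean size, which removes composition
differences), log-transformed (natural log; the comparison is
base-invariant) because between-system variances differ by orders of
magnitude. Replicate vectors are compared with Welch's unequal-variance
t test (delegated to `stats::t.test`; the test suite checks it against
the closed-form Welch/Satterthwaite expressions to $10^{-12}$).

## ITC and leakage arithmetic

Calcein release is normalized between the methanol (minimal) and Triton
X-100 (maximal) controls,
$\%L = 100\,(F_t - F_{contr})/(F_{tot} - F_{contr})$ — an exact,
affine-invariant identity. Values outside [0, 100] from noisy inputs are
reported as-is with a flag.

ITC series carry per-injection heats (µJ) for 10 µL injections of a
5 mM lipid suspension into a ~20 µM saponin cell at 26 °C (299.15 K),
the standard protocol for this system; both blank titrations
(lipid-into-buffer, buffer-into-saponin) are subtracted element-wise.
The vendor fitting model behind published constants is not documented,
so two explicit models ship: a lipid-partition isotherm (default —
appropriate when liposomes are titrated into a dilute surfactant: bound
fraction $K[L]/(1 + K[L])$ with per-injection dilution bookkeeping) and
a stoichiometric one-site model. Fitted constants are only comparable
within a model. $K$ is fitted on a log scale by Levenberg–Marquardt
least squares (`minpack.lm`); noiseless synthetic series are recovered
to well under 1% over two orders of magnitude in $K$, and 5% noise
stays within 15% at the tested seed. A series that saturates on the
first injection triggers an identifiability warning — the analogue of
titrations that cannot be treated analytically.

Thermodynamics use $\Delta G = -RT\ln(K c^\circ)$ with standard state
$c^\circ = 1$ M ($K$ in mM⁻¹ is converted to M⁻¹ inside the log; the
only convention that makes the logarithm dimensionless — stated
prominently because published tables rarely say so) and
$T\Delta S = \Delta H - \Delta G$, both exact identities. Entropy is
reported as $T\Delta S$ in kJ/mol.

## Numerical choices and degenerate inputs

* Accessible surfaces: deterministic Shrake–Rupley with a 242-point
  Fibonacci sphere per atom and probe 1.4 Å — exact for isolated spheres,
  reproducible everywhere.
* Clash criterion: non-bonded distance < 0.7 × radius sum, configurable.
* Conformer torsion grids are *offsets* from the input geometry, so the
  input conformation is always on the grid and a rigid molecule returns
  itself; grids are capped (default 10⁵ points) with a refusal, not a
  silent truncation. Returned + clash-rejected conformers always equal
  the grid cardinality.
* The logistic hydration saturates to 1.0 in double precision beyond
  ~28 Å; strict-bound tests are asserted on the representable range.
* Molecules with no amphiphilic contrast orient as the identity with a
  warning; an empty interfacial slab gives area 0 with a warning; a
  zero-variance-equal-means Welch comparison returns p = 1 by
  convention.
* Greedy assemblies (`buildAssembly`) only accept energy-lowering
  placements, so total assembly energy is monotone while placement
  succeeds; otherwise they truncate with a warning.

## Problem sizes and what the tests show

The shipped defaults are desk-scale: 30° angular grids for insertion
scans, the ~5 × 10³-pose coarse docking grid, 100 × 100 lattices with
2 × 10⁶ proposals and 5 replicates per scenario. These sizes were chosen
so that the full chain (and its test suite) runs in well under a minute
while every qualitative contract — profile symmetry, interface
localization of the amphiphile, docking orderings, domain-size contrast
with Welch p < 0.05 — is comfortably resolved; all knobs scale up to the
historical sizes (200 × 200, ≥ 10⁷ poses).

The synthetic generators emulate the *structure* of the real inputs
(shapes, orderings, saturating isotherms, plateauing fluorescence), not
their values. Passing tests therefore demonstrate correctness of the
machinery and reproducibility of the qualitative phenomenon — saponins
agglomerate rod-like sterols into large domains but leave bent sterols
scattered — under controlled conditions; they do not validate the
force field against experiment.

## Known limitations

* No explicit lipids, curvature, leaflet asymmetry or kinetics: the
  membrane is a 1-D hydration profile, the monolayer a lattice.
* Rigid-body scans only; conformational flexibility enters solely
  through the (separate) torsion enumeration.
* The docking force field is empirical and uncalibrated against binding
  data; only orderings and signs should be interpreted.
* Fixture molecules are cartoons with the right shape logic, not sterol
  chemistry.
* Move counts in the Monte Carlo minimization have no kinetic meaning.
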
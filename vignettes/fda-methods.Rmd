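---
title: "Force distribution analysis: models, methods and the synthetic benchmark"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Force distribution analysis: models, methods and the synthetic benchmark}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(fdanet)
```

## The problem and the method

Allosteric proteins couple distant functional sites: ligand binding at one
site changes behaviour at another, often through only minor conformational
distortions of a stiff core. Coordinate-based analyses (correlated motions,
normal modes) are poor probes of such stiff-pathway signaling because the
carriers barely move. Force distribution analysis (FDA) instead monitors
*pairwise inter-atomic forces*: in a near-rigid element, a small strain
carries a large force, so signal propagation is visible in the forces long
before it is visible in the coordinates.

`fdanet` implements the full FDA pipeline for two-state comparisons:

1. **Pairwise forces.** For every frame of a trajectory, each interaction
   term — harmonic bonds, harmonic angles, periodic dihedrals, Coulomb and
   Lennard-Jones within cutoffs — is attributed to atom pairs, giving a
   sparse matrix \(F_{ij}\).
2. **Scalarization.** Pair force *vectors* rotate with the molecule, so the
   stored quantity is the vector norm signed by its projection on the
   interatomic axis: positive repulsive, negative attractive. All downstream
   statistics use this signed scalar (in pN).
3. **Averaging.** Forces are averaged per replica trajectory, then across
   replicas (unweighted mean of replica means; SDs across replica means).
4. **Differencing.** \(\Delta F_{ij}\) is the difference of the averaged
   forces of two states, conventionally ligand-free (apo) minus
   ligand-bound (holo).
5. **Punctual stress.** \(\Delta F_i = \sum_j |\Delta F_{ij}|\) is a
   per-atom perturbation measure; absolute values are summed because signed
   differences balance by construction.
6. **Network.** Residue pairs with \(|\Delta F_{ij}|\) *strictly above* a
   force cutoff become edges; the largest connected component (by vertex
   count) is the candidate signaling network, and the cutoff is chosen by
   scanning: the largest value at which every source residue (binding site)
   still reaches every target residue (hinge) through that component.
7. **Geometry.** Three-point C\(\alpha\) bending angles quantify hinge
   motion per state (replica mean ± SD), with differences propagated in
   quadrature; a geometric hydrogen-bond detector and Kabsch superposition
   support the structural interpretation.

### Multi-body terms as central pair forces

Bonds and nonbonded terms are central two-body forces by nature. Angle and
dihedral forces are converted to pair forces by solving for signed
magnitudes on every atom-pair axis of the term such that the per-atom sums
reproduce the term's analytic atomic forces. For both 3-body and 4-body
terms the solution is generically exact: a translation-free, torque-free
force set on \(m\) atoms has \(3m-6\) degrees of freedom, which equals the
number of pair axes for \(m = 3, 4\). Degenerate geometries (collinear
angle, planar-degenerate dihedral) fall back to the minimum-norm
least-squares solution and are counted in `attr(x, "n_degenerate")`.

The whole engine is validated against central finite differences of the
total energy: per-atom sums of all pair forces must reproduce
\(-\nabla U\) to better than \(10^{-5}\) relative (see the acceptance
suite).

### Conventions worth knowing

- Internal units: nm, kJ/mol, kJ/mol/nm; reported units: pN (1 kJ/mol/nm =
  1.660539 pN), degrees, Å. Indices are 1-based everywhere user-facing.
- A pair absent from a frame contributes zero force to that frame's
  average; a pair absent from one *state* is treated as zero-mean there.
  Dropping such pairs instead would discard exactly the
  ligand-binding-induced signal the method is after.
- Residue-wise binding-pocket forces sum *signed scalars* over spanning
  atom pairs and report the absolute value of the sum. The network edge
  rule, in contrast, thresholds the *maximum* \(|\Delta F_{ij}|\) over
  spanning atom pairs ("atomic max", scale-free in residue size); a
  "residue_sum" mode is available.
- Strict inequality at the cutoff: ties at exactly the cutoff are excluded.
- Coulomb and Lennard-Jones have independent plain cutoffs (`cutoff`,
  `lj_cutoff`). There is no reciprocal-space (mesh-Ewald) term: beyond-cutoff
  electrostatic forces are not pairwise-attributable, which is a known and
  documented discrepancy from production MD setups. A plain truncation also
  makes the potential discontinuous at the cutoff; any *designed*
  interaction should live well inside it (see the benchmark's choice below).

## The synthetic two-domain benchmark

Real inputs to FDA studies are hundreds of nanoseconds of all-atom MD —
out of scope at desk scale. The `synthetic_system` module provides a
two-state, replica-ensemble stand-in with exact ground truth, so the whole
pipeline can be validated end to end.

### Architecture

- **Protein.** Two domains of 30 C\(\alpha\) beads (one bead = one
  residue), each a helical rod (radius 0.23 nm, 90° turn per bead, ~0.38 nm
  backbone spacing), joined end to end and bent by 140° at the junction so
  the two rods form a V-shaped cleft of roughly 40° interior angle.
  Backbone springs (k = 500 kJ mol\(^{-1}\) nm\(^{-2}\)) plus an
  *intra-domain* elastic network (i±2..4 neighbours within 0.75 nm,
  k = 100) make each domain semi-rigid. The junction is crossed only by one
  backbone bond, the designed pathway spring, and a stiff three-point angle
  restraint (k\(_\theta\) = 4·10\(^5\) kJ mol\(^{-1}\) rad\(^{-2}\)) on the
  triplet 3–27–51 that defines the interdomain hinge angle.
- **Designed pathway.** Every fourth bead from 3 to 51 — a straight line of
  beads up one face of each rod, crossing the hinge pair 27/31 — is chained
  by springs stiffened 150-fold over the background network (plus
  half-stiffness next-nearest "skip" springs within each domain for
  redundancy), and decorated with alternating ±0.1 e charges.
- **Ligands.** Two single beads, substrate analogues with charges −4 e and
  −3 e, each bound by pre-tensioned springs (rest length shortened by
  0.15 nm) to anchor residues on *opposite* domains (7/11 and 43/47). The
  two ligands repel each other electrostatically across the cleft
  (a few hundred pN at their ~3.5 nm separation).
- **Holo state.** Identical to apo except for the ligand terms and the
  hinge equilibrium angle, which *opens* by the designed 20° — the sign
  convention matches a straightening secondary-structure element, whose
  apo-minus-complex bending angle is negative.

### Why this design transmits force along the designed pathway

A static perturbation inside a free elastic body produces stress only
*between* its source and sink: an isolated force dipole (a ligand squeezing
its local binding site) relaxes within a few beads and transmits nothing.
The benchmark therefore places the two poles of the designed perturbation
on the two different domains: the inter-ligand Coulomb repulsion pushes
domain A and domain B apart, and at mechanical equilibrium that force flux
must flow through the only interdomain connections — overwhelmingly through
the 150-fold stiffened chain. Every chain edge between the anchors and the
hinge carries a conserved share of the flux, far above both the thermal
noise floor of the replica averages (a few pN) and the residual strains
elsewhere (tens of pN). The hinge-angle shift adds local strain at the
joint, and the angle restraint's own triplet beads lie *on* the chain so
its residual forces stay on designed residues.

Two numerical consequences of this design are deliberate:

- The Coulomb cutoff of the benchmark (6 nm) exceeds the system extent, so
  the designed inter-ligand repulsion is never truncated (a pair sitting at
  a plain-truncation boundary would both break energy conservation and make
  the designed signal flicker). The Lennard-Jones cutoff stays at the
  conventional 1.2 nm.
- The hinge restraint is much stiffer than everything that resists the
  rotation (the crossing springs contribute an effective angular stiffness
  of order 10\(^3\) kJ mol\(^{-1}\) rad\(^{-2}\)), so the minimum-energy
  hinge angle tracks \(\theta_0\) to better than 0.1°.

### Sampling

Ensembles are generated by overdamped Langevin dynamics (Euler–Maruyama,
\(dx = F/\gamma\,dt + \sqrt{2 k_B T\,dt/\gamma}\,dW\)) at 300 K with
friction \(\gamma = 50\) kJ ps mol\(^{-1}\) nm\(^{-2}\) and
\(dt = 5\cdot10^{-4}\) ps, recording every 10th step after a 2000-step
burn-in, starting from the energy-minimized state geometry. The stiffest
effective mode (the hinge restraint projected on the triplet beads,
~4·10\(^4\) kJ mol\(^{-1}\) nm\(^{-2}\)) gives \(k\,dt/\gamma \approx 0.4\),
inside the Euler stability region; step-size errors bias mode variances by
tens of percent at worst but leave the means — which carry all the designed
signal — unbiased for this harmonic-dominated model. The inner loop is
compiled (Rcpp) and draws its noise from R's RNG, so an ensemble is an
exact function of `set.seed()`; the R-level integrator (used as reference
and as fallback for systems with dihedrals) is checked against the compiled
forces to \(10^{-10}\).

The default ensemble size — 5 replicas × 2000 frames per state — runs in
about two minutes on one CPU and leaves the designed edges 10–50 standard
errors above the noise.

### What the generator does and does not emulate

It emulates: two-state replica ensembles, a designed binding-site-to-hinge
force pathway embedded in background elasticity, a designed hinge-angle
change, thermal force fluctuations, and a ligand-size asymmetry between
the two binding sites. It does **not** emulate solvent (and hence
solvent-mediated pair forces), realistic force-field energetics,
anharmonic conformational transitions, or the specific published values of
any real enzyme (those derive from 900 ns of explicit-solvent all-atom MD
and are out of reach by design). A green end-to-end test therefore
establishes that the *pipeline* recovers a known embedded signal at the
stated noise level — not that it would recover any particular real
protein's pathway.

### Negative control

`negative_control_spec()` removes every designed signal (no pathway
stiffening or charges, no ligands, zero angle change) while keeping the
architecture. The pipeline must then report a broken path at every scanned
cutoff, and the maximal punctual stress must stay below 30% of the
positive control's — empirically it is an order of magnitude lower, pure
averaging noise.

## Tunable parameters that matter

| Parameter | Default | Unit | Why |
|---|---|---|---|
| network cutoff | 90 | pN | reported analysis constant; in practice chosen by `scan_cutoffs()` |
| scan grid | 30–240 step 30 (API) / 20–400 step 20 (benchmark bundle) | pN | the former brackets the 90 pN analysis constant; the latter the benchmark's designed signal window |
| nonbonded cutoff | 1.2 (analysis) / 6 (benchmark) | nm | conventional vdW range; benchmark avoids truncating the designed repulsion |
| H-bond `d_max` | 3.5 | Å | conventional donor–acceptor distance criterion |
| H-bond `angle_min` | 120 | ° | conventional D–H···A angle criterion (applied only when a hydrogen is given) |
| H-bond `occ_min` | 0.5 | fraction | report only bonds present most of the time |
| `scale14` | 1 | – | 1–4 nonbonded pairs at full strength; configurable |
| stress `residue_mode` | sum | – | atomic values are the primary output; residue aggregate is a convenience |

## Numerical choices and degenerate inputs

- Energy minimization: L-BFGS-B on the analytic gradient
  (`factr = 10`, up to 2·10\(^4\) iterations); adequate for a few hundred
  degrees of freedom.
- Streaming averages precompute a fixed pair universe from the first frame
  with a 0.4 nm skin; pairs that wander into the cutoff from outside the
  candidate list are missed, which is negligible for near-equilibrium
  ensembles but makes the streaming route inappropriate for large
  conformational transitions (use the per-frame route then).
- Collinear angle triplets: the bending angle itself is well-defined
  (180°), but the pair decomposition is rank-deficient and falls back to
  minimum norm, flagging the frame.
- Superposition requires ≥3 non-collinear atoms; reflections are excluded
  by the determinant correction in the Kabsch step.
- Ties: the largest-component tie-break is the smallest minimum residue
  index, making reports deterministic.
- Angles are computed at full precision and conventionally *reported*
  rounded to 0.1°; quadrature error propagation
  \(\sqrt{\sigma_a^2+\sigma_b^2}\) reproduces the reference table's
  difference row in five of six columns to ±0.1° — the sixth (loop F7) is
  internally inconsistent in the source (printed difference −2.3 vs
  printed means differing by −2.4) and is reported at full precision here
  rather than matched.

## Known limitations

- No reciprocal-space electrostatics: beyond-cutoff Coulomb forces are
  absent, so absolute interaction energies are rough and long-range
  perturbation networks in highly charged systems may be underestimated.
- The overdamped sampler has no inertial dynamics; time correlations are
  not physical, only the stationary distribution is meaningful.
- Exclusion generation (1-2/1-3) and 1-4 scaling operate on *chemical*
  bonds only; elastic-network restraint springs (`chemical = FALSE` in the
  topology dialect) intentionally do not suppress nonbonded interactions.
- Solvent is entirely absent; whether solvent-mediated pair forces matter
  to detected networks is untested here.
- Periodic boundary handling is limited to what the trajectory provides;
  no minimum-image reconstruction is attempted beyond orthorhombic boxes.
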
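---
title: "Grid-based docking with Coulomb and Poisson-Boltzmann electrostatics"
author: "pbdock"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grid-based docking with Coulomb and Poisson-Boltzmann electrostatics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pbdock)
```

## The scientific problem

Force-field docking scores a rigid ligand pose against a rigid receptor as a
sum of polar (electrostatic) and van der Waals terms. How the polar term is
modeled matters: a bare Coulomb sum with a distance-dependent dielectric
(`eps = r`, giving `1/r^2` energy decay) is cheap but ignores solvent
screening, and is known to overestimate charge-charge interactions by an
order of magnitude relative to a continuum (Poisson-Boltzmann) treatment.
`pbdock` implements both models behind the same grid-based scoring machinery
so that their effect on pose reproduction and on active/decoy enrichment can
be compared end to end, together with a soft-core Lennard-Jones term whose
smoothing length `delta_vdw` tunes the tolerance to small steric clashes.

## The scoring model

The binding energy of a ligand pose is

$$E_{bind} = \sum_{j \in lig} q_j\,\phi(r_j)
  + \sum_{i \in rec}\sum_{j \in lig}
    \frac{A_{ij}}{(r_{ij}^6 + \delta^6)^2}
  - \frac{B_{ij}}{r_{ij}^6 + \delta^6},$$

with per-atom Lennard-Jones coefficients $A_i = \varepsilon_i (2 r_{0,i})^{12}$
and $B_i = 2 \varepsilon_i (2 r_{0,i})^6$ combined by geometric means
($A_{ij} = \sqrt{A_i A_j}$, $B_{ij} = \sqrt{B_i B_j}$), so that a like pair
has its minimum at $2 r_0$ with depth $\varepsilon$, and $\delta$
(`delta_vdw`, in Angstrom) softens the repulsive wall: $\delta = 0$ recovers
the exact 6-12 potential, $\delta = 2$ caps the wall at
$A_{ij}/\delta^{12} - B_{ij}/\delta^6$. Geometric-mean combining makes the
double sum separable, which is what permits pre-computed receptor grids:
each grid node stores $\sum_i \sqrt{A_i}/(r_i^6+\delta^6)^2$ and
$\sum_i \sqrt{B_i}/(r_i^6+\delta^6)$, and a ligand atom contributes
$\sqrt{A_j}\,\mathrm{Asum} - \sqrt{B_j}\,\mathrm{Bsum}$. The decomposition
is algebraically exact, not an approximation.

The electrostatic potential $\phi$ is either

* **coulomb** - $\phi(r) = C \sum_i q_i / r_i^2$ with
  $C = 332.0637$ kcal A/(mol e^2) (the `eps = r` distance-dependent
  dielectric), or
* **pb** - a linearized Poisson-Boltzmann potential map computed by the
  built-in finite-difference solver (or imported from an OpenDX file
  written by any other PB solver), converted to kcal/(mol e) with
  $k_BT = 0.5925$ kcal/mol at 298.15 K.

vdW parameters (`r0` = Rmin/2, well depth) are assigned per SYBYL atom type
from a bundled table transcribed from the published AMBER ff14SB set (GAFF
for halogens), with element-level fallbacks. The SYBYL-to-AMBER
correspondence is an approximation documented in the table file itself;
partial charges are always taken from the input MOL2 file, never computed.

## Pose initialization by Gaussian overlay

Each atom carries an isotropic Gaussian density
$\rho_i(r) = p_i \exp(-\alpha_i |r - r_i|^2)$ with amplitude
$p_i = 2\sqrt{2}$ and exponent
$\alpha_i = \pi (3 p_i / 4\pi\sigma_i^3)^{2/3}$, $\sigma_i$ the vdW radius —
the choice that makes the per-atom Gaussian integrate to the volume of its
hard sphere. The overlap volume $V_{AB}$ between two molecules is the
closed-form double sum of Gaussian pair integrals over three channels:
shape (all atoms), positive charge, and negative charge (membership by the
sign of the partial charge, weights 1). The search ligand is placed by
maximizing $V_{AB}$ against the reference ligand over the six rigid degrees
of freedom with a seeded multi-start quasi-Newton ascent (principal-axes
alignments plus random rotations); similarity is reported as the Hodgkin
index $SI = 2 V_{AB} / (V_{AA} + V_{BB})$. Only first-order (pair) overlap
terms are used, matching the double-sum definition; no higher-order
inclusion-exclusion corrections are applied.

Docking then minimizes the grid-interpolated $E_{bind}$ globally over a
unit-quaternion rotation and a translation bounded to the grid box, using
seeded differential evolution with the overlay pose injected into the
initial population and a simplex polish of both the overlay pose and the
best evolved member. The lower of the two is returned, so the final energy
can never exceed the initial one. The ligand is rigid; conformational
flexibility is supported only by docking multiple input conformers
independently.

## The PB solver

The linearized PB equation
$\nabla\!\cdot\!(\varepsilon\nabla\phi) - \bar\kappa^2\phi = -4\pi(e^2/kT)\rho$
is discretized with the standard 7-point stencil on a uniform grid,
face-centered dielectrics, and solved by red-black successive
over-relaxation with the Chebyshev omega schedule. Defaults follow the
docking protocol the package implements: interior dielectric 2.06, exterior
78.5, 145 mM monovalent salt (Debye length 8.0 A), 30 A box at 0.4 A
spacing (75 nodes per axis), two-step focusing in which a coarse solve with
the molecule spanning half the box supplies boundary values for the fine
box centered on the reference ligand.

Numerical choices worth knowing about:

* **Dielectric boundary** - hard two-valued assignment on vdW spheres (edge
  midpoint inside any sphere takes `eps_in`); no solvent-probe reentrant
  surface and no Gaussian-smoothed dielectric. The Stern ion-exclusion
  layer (default 2 A) zeroes the screening term around the solute.
* **Charge spreading** - each point charge is deposited as a spherical
  Gaussian cloud of width one grid spacing (3.5-sigma support), normalized
  to conserve charge. Compared with trilinear cloud-in-cell (still
  available via `spread = "cic"`), the spherical cloud suppresses the
  anisotropic near-field error of the 7-point lattice: the uniform-dielectric
  solve then tracks the Coulomb form within ~1.3% from three grid spacings
  outward, where CIC leaves ~4% errors on the axes. Self-energy artifacts
  cancel in reaction-field differences because both solves spread charges
  identically.
* **Boundary conditions** - analytic Debye-Hueckel values on the box faces;
  focused solves interpolate boundary values trilinearly from the coarse
  map. Atoms outside a focused fine box keep their dielectric sphere
  intersections but drop their source charges - their field enters through
  the boundary, which is exact for the linear equation.
* **Convergence** - sweeps stop when the max node update falls below 1e-4
  kT/e (cap 10,000). The exposed `energy_trace` records the discrete
  Dirichlet energy, which decreases monotonically for any relaxation factor
  in (0, 2) and is the solver's convergence certificate; the max-update
  trace itself oscillates mildly, as it does for any SOR variant.
* **Units** - the solver works in kT/e; grids convert with
  $k_BT = 0.5925$ kcal/mol (298.15 K); the electrostatic constant is
  332.0637 kcal A/(mol e^2).

Validation is by classical closed forms: the Born ion reaction-field energy
(within ~1.5% at 0.25 A spacing), the uniform-dielectric Coulomb limit,
superposition and charge-scaling at fixed dielectric geometry, and
focusing against a single fine solve of the whole domain.

## Grid interpolation accuracy

Trilinear interpolation of fields that diverge like $r^{-24}$ near atoms
cannot be accurate close to the repulsive wall. The vdW component grids are
therefore interpolated on their 8th- and 2nd-root transforms (both vary as
roughly $r^{-3}$) and raised back, which is exact at nodes and reduces
off-node errors near contact by an order of magnitude. With this scheme,
grid energies of clash-free poses (no receptor-ligand pair compressed below
~92% of its Lennard-Jones contact distance) agree with the exact pairwise
sums to within 2%; poses with deep interpenetration remain less accurate,
which is immaterial because the optimizer rejects them. Coulomb grid nodes
closer than 0.5 A to a receptor atom are clamped to the value at 0.5 A,
and `delta = 0` vdW node sums are capped at 1e12 — nodes inside receptor
atoms are never visited by accepted poses. Ligand atoms that leave the box
during the search are charged a 1e6 kcal/mol penalty each (booked under the
vdW term so that `E_total = E_elec + E_vdw` stays exact).

## Evaluation metrics

* **RMSD** - `all_atom` (hydrogens included; the primary pose metric),
  `heavy_atom`, and `heavy_symmetry`, which minimizes over within-element
  atom assignments (exact search, element classes capped at eight atoms)
  without refitting the pose. Other symmetry-corrected variants encountered
  in the literature are not uniquely defined and are not reproduced here.
* **Enrichment** - compounds are ranked by ascending final energy (ties
  collapse into diagonal ROC segments; stable input order breaks exact
  ties). The adjusted LogAUC integrates TPR over $\log_{10}$ FPR across
  three decades (FPR in $[10^{-3}, 1]$; earlier points are clipped to the
  limit, not dropped), normalizes to percent, and subtracts the analytic
  random area $100 (1 - 10^{-3}) / (3 \ln 10) = 14.46$ — so a random
  ranking scores 0, a perfect one 85.5.
* **Charge analysis** - the net-charge histogram of the top-scored fraction
  of a screen, the diagnostic for electrostatic overestimation favoring
  multiply-charged compounds.

## Synthetic fixtures and what they do (and do not) show

All tests run on seeded generators, not on curated complexes:

* **Ligands** are compact clusters of parameterized pseudo-atoms grown at
  ~1.5 A spacing: carbon scaffolds with oxygen-/nitrogen-like charged sites
  (by default one -0.5 e and one +0.5 e site, i.e. neutral), or with a
  requested net charge spread in 0.5 e increments.
* **Pockets** are hemispherical shells of ~35 carbon-like atoms built
  around a native ligand, each shell atom placed along a ray from the
  ligand centroid at exactly the Lennard-Jones contact distance
  ($2\sqrt{r_{0,i} r_{0,j}}$) from its nearest ligand atom, with a conical
  opening and two +/-0.5 e complementary polar contacts. The native pose
  is then relaxed to the nearby local minimum of the grid-free reference
  force field — the synthetic analogue of a crystal pose sitting at a
  minimum of the true physics. A *charge-decoyed* variant plants a cluster
  of three -0.8 e atoms outside the pocket mouth: an electrostatic trap
  that an unscreened `eps = r` Coulomb model overweights (pulling a
  positively charged ligand out of the site at soft-core `delta_vdw = 2`)
  while the PB model, which screens solvent-exposed charges by ~80x,
  leaves the shape-complementary pose in place. This reproduces the
  mechanism behind the Coulomb model's soft-core failure directionally.
* **Screens** pair jittered copies of the native ligand (actives) with
  size-matched random clusters whose net charges follow a configurable
  distribution (defaults 66% at 0 e, 30% at -1 e, 4% at -2 e, matching the
  net charges typical of actual binders).

Because the fixtures are tens of atoms with idealized geometry, passing
tests demonstrate the correctness and the directional behavior of the
machinery — not absolute pose-reproduction rates or enrichment values on
real receptor-ligand data, which depend on curated structures, charge
models and decoy design outside this package's scope. Problem sizes in the
test-suite and acceptance runs (35-atom pockets, 8-atom ligands, 20
self-docking repeats, 5 decoyed pockets, 33-compound screens, 0.25-0.4 A
PB grids) were chosen as the smallest that exercise every code path with
stable statistics.

## Design choices on genuinely open points

* The Gaussian amplitude is $2\sqrt 2$, the hard-sphere-volume-matching
  value standard in Gaussian-shape overlay methods.
* Charge-channel membership is by sign only; zero-charge atoms belong to
  the shape channel alone. Channel weights default to 1.
* The per-atom LJ coefficient is $A_i = \varepsilon_i (2r_0)^{12}$ (with
  $B_i = 2\varepsilon_i(2r_0)^6$): the unique reading under geometric-mean
  combining that reproduces the AMBER self-pair minimum ($2r_0$, depth
  $\varepsilon_i$) while keeping the grids separable.
* The global optimizer is differential evolution (population 30, 120
  generations by default) over a normalized quaternion and a bounded
  translation, with Nelder-Mead polish; evaluation budgets were sized to
  pass the self-recovery properties with margin. Any seeded global
  optimizer over the same objective would do.
* Ranking ties break by stable input order; the ROC uses average-step tie
  interpolation, which makes AUC plus label-flipped AUC exactly 100%.

## Known limitations

Rigid ligands (no torsional search); hard dielectric boundary (no
molecular-surface or Gaussian-smoothed dielectric variants); linearized PB
only; no desolvation or occupancy grids; no receptor flexibility; the
symmetry-corrected RMSD is exact-search and thus limited to small element
classes; and the bundled SYBYL-to-AMBER parameter mapping is a documented
approximation intended for the bundled fixtures and for structures whose
charges are already assigned.
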
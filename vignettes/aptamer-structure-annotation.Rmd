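---
title: "Annotating mirror-image aptamer complexes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating mirror-image aptamer complexes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aptastruct)
```

`aptastruct` analyzes crystal structures of mirror-image (L-configured)
aptamers — Spiegelmers — bound to protein targets, and the surface plasmon
resonance (SPR) experiments used to characterize their binding. This
vignette is the package's own account of the methods: the conventions and
models it implements, the tunable parameters and why their defaults are what
they are, what the synthetic generators do and do not emulate, and the
numerical choices a maintainer should know about.

## Chirality and the mirror transform

A Spiegelmer is built from L-nucleotides, so a deposited model is the exact
mirror image of a natural nucleic acid. The package detects sugar
handedness from the sign of the improper (out-of-plane) configuration at
C4′ — the triple product of the C4′→C3′, C4′→O4′ and C4′→C5′ bond vectors —
which is positive for natural D-sugars and negative for L. The mirror
transform inverts the sign of every z coordinate. Any reflection plane is
equivalent up to rotation; the z plane is the convention used when
mirror-image models are built in practice, and it is adopted exactly.
Reflection preserves all interatomic distances bit-exactly and negates all
torsion angles, and `mirror_structure()` is an exact involution — these are
asserted as tests, not assumed.

**Nomenclature convention.** All conformational descriptors (χ and
syn/anti, pseudorotation phase and pucker names) are computed after
mirroring L residues to the D frame, i.e. torsions of L residues are
negated. The alternative — reporting raw torsions — would force a parallel
"L vocabulary" (left-handed 3′-endo lives at P + 180°); the mirrored-to-D
convention keeps the standard vocabulary unchanged, which is how such
structures are described in the literature. `frame = "as-deposited"` exposes
the raw values.

## Conformational annotation

* Glycosidic torsion χ: O4′–C1′–N9–C4 (purines), O4′–C1′–N1–C2
  (pyrimidines). **syn iff |χ| ≤ 90°.** Published structure descriptions
  give verdicts, not boundaries; the symmetric bisection at 90° is the
  conventional choice, is invariant under χ → −χ (hence mirror-invariant),
  and any call within 5° of the boundary is flagged `chi_ambiguous` instead
  of being silently asserted.
* Sugar pucker: Altona–Sundaralingam phase from the five endocyclic
  torsions, tan P = ((ν₄+ν₁) − (ν₃+ν₀)) / (2ν₂(sin 36° + sin 72°)), +180°
  when ν₂ < 0; amplitude τ_m = ν₂ / cos P. Pucker names are the nearest
  canonical envelope/twist on the 18° wheel (3′-endo ≈ 18°, 4′-exo ≈ 54°,
  O4′-endo ≈ 90°, 1′-exo ≈ 126°, 2′-endo ≈ 162°, …, 2′-exo ≈ 342°);
  amplitudes below 5° are named `planar/indeterminate`, and phases within 5°
  of a sector edge are flagged ambiguous. Naming is verified against an
  exhaustive arg-min over the ten sector centers on 1000 seeded phases.

## Hydrogen bonds, base pairs, quadruplexes

Crystal structures at 1.8–2.0 Å resolution carry no hydrogens, so all
criteria are heavy-atom based:

* **H-bond:** donor and acceptor atoms (name tables per residue kind)
  within 3.5 Å (default; configurable within 2.4–4.0 Å), excluding
  same-residue pairs and atoms covalently linked across the backbone.
* **Base pair:** ≥ 2 inter-base hydrogen bonds on the base edges, base
  normals within 30°, and an out-of-plane offset ≤ 2 Å (this last condition
  is what separates paired from stacked bases, which can also be coplanar
  and close). Watson–Crick means the canonical G–C (O6–N4, N1–N3, N2–O2) or
  A–U/T (N6–O4, N1–N3) atom pattern; G·U wobble and everything else is
  `non_watson_crick`.
* **Stacking:** ring-centroid separation ≤ 4.5 Å and normals within 30°.
* **G-tetrad:** directed graph over guanines with an edge i → j when
  N1(i)…O6(j) ≤ 3.5 Å *and* N2(i)…N7(j) ≤ 3.5 Å; tetrads are directed
  4-cycles, so the Hoogsteen polarity is consistent by construction. When
  cycles share guanines the disjoint set is chosen greedily by smallest
  mean H-bond distance (the deposited quadruplex is unambiguous; synthetic
  edge cases need the rule).
* **Quadruplex:** tetrads stack when mean-plane centroids are 2.8–4.5 Å
  apart with normals within 30°. The **twist** is the mean rotation about
  the stacking axis that maps each tetrad-1 C1′ onto its nearest stacked
  counterpart, folded into [0°, 90°]; C1′ atoms are used because they are
  the farthest ring-anchored atoms from the axis, hence numerically stable.
  No published definition of the printed twist exists, so this metric is a
  package choice and deposited-value comparisons carry a ±10° tolerance.
  Strand orientation is the consensus of glycosidic circulation senses
  (all alike → parallel, 2+2 → antiparallel, 3+1 → mixed).

## Ion identity from coordination distances

`coordination_sphere()` collects O/N ligands within 3.0 Å (default; the
K–O mean of 2.81 Å plus margin, while excluding the second shell) and
`score_ion_identity()` scores each candidate species by the absolute
z-score |mean distance − μ| / σ with canonical statistics Mg 2.08 ± 0.06,
Ca 2.43 ± 0.11, K 2.81 ± 0.10, Na 2.38 ± 0.10 Å and plausible
coordination-number ranges. The assignment is the best CN-compatible
species, **but** the ambiguity margin (best two scores closer than 1.0) is
evaluated over all species: Ca and Na overlap so strongly in distance that
a distance-only classifier must report "ambiguous" rather than let a CN
range manufacture certainty — discriminating them for real takes anomalous
scattering, which is out of scope here. A site at 2.47 Å with CN 7 thus
scores Ca best (z ≈ 0.36), rejects K (z ≈ 3.4) and is flagged Ca-vs-Na
ambiguous.

## Surface areas and interfaces

SASA is Shrake–Rupley with a deterministic golden-spiral lattice (960
points/atom by default; probe 1.4 Å; radii C 1.70, N 1.55, O 1.52, P 1.80,
S 1.80 Å, overridable — the published interface area was computed with
AREAIMOL whose radii are not stated, hence the ±5% tolerance on that
comparison). Coordinates are first rotated to an orientation-canonical
frame (principal axes, axis signs fixed by the third moment), which makes
the quadrature *exactly* invariant under rotation, translation and mirror
instead of invariant only to ~0.1% lattice error. Buried area is the
two-sided convention BSA = SASA(A) + SASA(B) − SASA(AB); waters, ions and
alternate conformers are excluded by default. A residue is in the interface
footprint when it loses ≥ 1 Å² of accessible area or has any heavy atom
within 4 Å of the partner. Accuracy anchors: a single sphere is within 1%
of 4π(r+probe)² at 960 points; seeded 20-atom clusters agree with a
10⁴-point quadrature within 2%; the two-sphere overlap matches the analytic
spherical-cap loss.

## Superposition

Kabsch via SVD with the determinant correction, so reflections are never
applied — a mirror-image pair reports a large RMSD instead of silently
inverting. Atom pairing is by (chain, residue number, insertion code, atom
name) after an optional chain mapping; waters, ions and hydrogens are
excluded, alternate-location atoms collapsed to the highest-occupancy
conformer. Degenerate (collinear) point sets raise an error naming the
degeneracy. Per-base rotations between conformers are the rotation angle of
the optimal proper rotation mapping the base ring atoms about their
centroid after a context superposition of everything else.

## SPR: 1:1 Langmuir with mass transport

The binding model is dR/dt = k_a·C_s·(R_max − R) − k_d·R with the surface
concentration from the two-compartment quasi-steady-state balance
C_s = (k_t·C + k_d·R)/(k_t + k_a·(R_max − R)); during dissociation C = 0,
so dissociation is rebinding-limited when transport is slow. Vendor
software does not document its exact transport variant; this standard form
is stated explicitly so fits are reproducible. Defaults follow the standard
direct-binding protocol: 240 s association, 240 s dissociation, a two-fold
concentration series from 500 nM, and k_t = 1 × 10⁷ RU·M⁻¹·s⁻¹ held fixed
(optionally free). Integration uses `deSolve::lsoda` (absolute tolerance
10⁻⁶ RU; the transport-coupled equation is mildly stiff at high
k_a·R_max), with the association/dissociation discontinuity handled as a
phase boundary, not an event inside a step. In the transport-free limit the
simulator matches the closed-form Langmuir solution to < 0.01 RU.

Fitting is global nonlinear least squares (Levenberg–Marquardt,
`minpack.lm`) sharing k_a, k_d, R_max across all curves, parameters on the
log scale to enforce positivity; K_d is reported as k_d/k_a exactly.
Non-convergence is flagged, never thrown. Noiseless self-consistency
recovers parameters to ≪ 1%; with 2 RU Gaussian noise, seeded replicates
recover K_d within 10% (typically 2–3%).

The competitive assay format pre-equilibrates the analyte with a competitor
in solution; the free-analyte concentration comes from the closed-form root
of the 1:1 binding quadratic, A_free = ((A − B − K_d) +
√((A − B − K_d)² + 4·K_d·A))/2, and the report-point signal is the
simulated binding of A_free relative to the no-competitor signal — a curve
that is 1 at zero competitor, monotone non-increasing, and 0 in the
sequestration limit. Ion-dependence experiments are represented only as
scenario configurations scaling k_a (the observed effect channel); no
mechanistic ion-binding model is invented. Experimentally measured
affinities are treated as plausible simulation parameters, never as
computable outputs.

## What the synthetic generators emulate — and what they do not

The generators exist so every algorithm is exercised, under its published
acceptance geometry, with no external data:

* `make_duplex()` poses ideal bases (frozen chemical-component geometry) at
  canonical Watson–Crick hydrogen-bond distances (G–C 2.91/2.95/2.86 Å, A–U
  2.95/2.82 Å, C1′–C1′ 10.4 Å), attaches C3′-endo/anti sugars rigidly, and
  stacks pairs at the A-form fiber rise (2.81 Å) and twist (32.7°/bp). The
  base-pair centroid is kept on the helix axis so that every consecutive
  step sits inside the 4.5 Å stacking window; the true A-form axis
  displacement and base inclination are **not** reproduced. The backbone is
  geometrically plausible but not covalently refined (O3′–P closure is not
  enforced) — sufficient for pairing/conformation/surface tests, not for
  refinement. The L variant is the exact mirror of the D build, hence
  left-handed.
* `make_tetrad_stack()` solves a three-parameter in-plane pose (four-fold
  symmetric) for closed Hoogsteen N1…O6/N2…N7 contacts at 2.9 Å with the
  O6 radius fixed by the requested channel-ion distance. Tight channels
  make this a least-squares compromise of a few hundredths of an Ångström,
  so a requested 2.48 Å ion–O6 distance is realized as ≈ 2.51 Å. Loops and
  connecting phosphodiesters of a real unimolecular quadruplex are not
  modelled.
* `make_ion_site()` places water oxygens on regular coordination polyhedra
  (tetrahedron through tricapped trigonal prism) with seeded radial jitter;
  real sites mix ligand classes and distort angularly.
* `make_sensorgram_set()` adds seeded i.i.d. Gaussian noise per time point;
  drift and bulk refractive-index jumps are deliberately out of scope
  (double-referencing removes them in practice).

Passing tests on these fixtures demonstrates the *algorithms* — counts,
classes, angles, recoveries — under ideal and noise-controlled conditions.
They do not demonstrate robustness to crystallographic disorder,
incomplete residues, or modelling error in real deposits; the pipeline
handles those through altloc policy, missing-atom warnings and ambiguity
flags, but only deposited coordinates exercise them fully.

## Reproducing published descriptors from deposited entries

`run_pipeline()` with local copies of the deposited entries (4WB2, 4WB3,
4P3A) recomputes the full descriptor set in `reference_descriptors()`:
buried interface area (±5%), the three superposition r.m.s.d. values
(±0.1 Å — the exact atom selections behind the printed values are
unstated, which this tolerance absorbs), Watson–Crick stem pairs, tetrad
count and residue sets, quadruplex twist (±10°, metric choice), channel-ion
coordination, the Mg ion–oxygen mean distance (±0.03 Å), ions per aptamer
chain, and the dU30 base rotation between the two complexes of the
asymmetric unit (±10°). Chains are selected by content (a ≥ 30-nt nucleic
chain; protein chains paired by contact count), never by hard-coded
identifiers, since chain naming conventions differ between deposits.
Coordinate files are supplied locally; nothing in the package, its tests or
its scripts requires network access.

## Problem sizes and determinism

The test suite and `scripts/acceptance.R` run on 8-bp duplexes (~340
atoms), two-tetrad stacks (~180 atoms), 20-atom SASA clusters, 1000-phase
pucker sweeps, 5-curve noiseless and 4-curve noisy sensorgram series (20
seeded replicates in the acceptance tests, 8 in the script) — sizes chosen
so the whole suite completes in about two minutes while every acceptance
property is measured at its stated tolerance. All randomness is seeded
through a local RNG scope that restores the caller's stream; the SASA
lattice and all fixture constructions are RNG-free or seeded, so identical
configurations produce identical bytes.

## Known limitations

* Base-pair taxonomy is WC / non-WC / other, not the full 12-family
  edge-and-orientation classification.
* Backbone suite rotamers (α–ζ) are not named.
* Ion identification uses distances and coordination numbers only; no
  anomalous-scattering or occupancy evidence, hence honest Ca/Na ambiguity.
* No shape-complementarity statistic; complementarity is expressed through
  buried area and footprints.
* The mmCIF writer emits the `atom_site` category only (sufficient for
  round-tripping coordinates, not a full PDBx archive file).
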
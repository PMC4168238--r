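---
title: "Enforced stretching of pyranose oligomers: models and methods"
output: rmarkdown::html_vignette
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The simulated experiment

Single-molecule force spectroscopy stretches a polysaccharide chain
between an AFM tip and a substrate and records force against extension.
For axially linked pyranoses such as α-D-galacturonic acid — the backbone
unit of pectin — the glycosidic (C1–O) and aglycone (O–C4) bonds are both
axial in the resting ⁴C₁ chair. They act as mechanical levers: tension on
the chain applies a torque to each ring, and above a threshold force the
ring flips, chair → inverted chair (¹C₄), passing through the twist-boat
band. The flip lengthens the monomer's anchor-oxygen span from about
4.5 Å to about 5.5 Å and shows up as a plateau in the force–extension
curve.

`egopull` reproduces this experiment *in silico* by Enforced Geometry
Optimization (EGO): geometry minimization on the force-modified surface

$$E_\mathrm{eff}(x) \;=\; E(x) \; - \; f\, d(x),$$

where $E$ is the molecular energy, $d$ the distance between the two
anchor oxygens (O4ᵃ and O1ᵃ, the terminal hydroxyl oxygens at C4 and C1),
and $f$ a constant pulling force in atomic units (1 Hartree/Bohr =
82.387 nN). The force pair is equal, opposite and collinear, so it exerts
no net force or torque on the molecule. EGO is defined here in Cartesian
coordinates; whether a force-modified optimizer adds the force before or
after an internal-coordinate transformation is implementation-defined in
the literature, and the Cartesian convention is stated explicitly so
results are reproducible.

The full protocol is *stretch–relax*: optimize under force from a common
zero-force reference, then re-optimize with the force removed. A
conformational change is **permanent** when the relaxed structure's
canonical ring label differs from the start — the relaxed identity, not
the stressed geometry, is the criterion.

# The energy backend

All chemistry enters through one contract: `evaluate(coords)` returns the
energy (Hartree) and the per-atom gradient (Hartree/Bohr). Any provider —
including an external quantum-chemistry code — can stand behind it. The
built-in desk-scale backend (`toy_ff_build()`) is a small molecular
mechanics model:

* **Bonds — Morse**, $V = D(1 - e^{-a(r-r_0)})^2$ with $a=\sqrt{k/2D}$,
  so the curvature at $r_0$ is the familiar harmonic constant $k$ while
  the transmissible tension is bounded by $aD/2$. This is not a cosmetic
  choice: with strictly harmonic bonds and angles the stretched chair
  remains a stable minimum of $E_\mathrm{eff}$ at *any* force — the
  molecule simply elongates elastically forever and no flip can occur. A
  finite force capacity is the minimal anharmonicity that lets the pulled
  chair become mechanically unstable. Defaults (v1 parameter file):
  k = 0.7–1.2 Ha/Å², D = 0.45–0.55 Ha, giving bond rupture near 0.13 au —
  above the conformational threshold, and the first bonds to break under
  anchor pulling are C1–O1 and C4–O4, as expected for this pulling
  geometry.
* **Angles — cosine-harmonic**, $V = k_c(\cos\theta-\cos\theta_0)^2$,
  matched to a harmonic constant of 0.15 Ha/rad² at $\theta_0$
  (109.47° sp³ C, 120° sp², 113° at O). Torque is bounded and vanishes at
  the linear limit, again preventing unbounded elastic absorption of the
  pull.
* **Torsions** — a 3-fold cosine on every bonded quadruple
  (k₃ = 0.0004 Ha), plus the **ring profile**: endocyclic ring bonds get
  a two-term series $k_2(1+\cos 2\varphi) + k_3'(1+\cos 3\varphi)$
  (k₂ = k₃′ = 0.0005 Ha per ring bond, spread over that bond's
  quadruples). Maxima at planar and anti, minima near ±65°: the isolated
  six-ring has a chair global minimum, genuine twist-boat local minima,
  and an inverted-chair minimum, with inversion passing through the
  twist-boat band.
* **Nonbonded** — a soft quadratic repulsion
  $\varepsilon(1-r/\sigma)^2$ for $r<\sigma$ (ε = 0.008 Ha; σ = 1.8/2.2/
  2.7 Å for H–H/X–H/X–X), pairs within three bonds excluded.

Parameters live in a versioned file
(`inst/extdata/toyff_params_v1.json`), loaded by `toy_ff_params()`, so
the test baseline is reproducible across releases. On these defaults the
chair monomer flips permanently to ¹C₄ between 0.055 and 0.0575 au
(established by a brute-force pre-scan and then frozen) — inside the
standard 0.02–0.08 au ladder, though the exact threshold is a property
of the backend, not of the molecule. The toy
backend makes no thermochemical claims — no electrostatics, solvent,
anomeric stereoelectronics or hydrogen-bond directionality — so passing
tests demonstrate the *mechanism* (threshold behaviour, twist-boat
pathway, elongation-then-flip order, characteristic lengths), not
quantum-level numbers. Quantities such as Hartree energies and exact
transition windows are backend-level and reachable only through an
external quantum provider implementing the same contract.

# The optimizer

`optimize_enforced()` is BFGS with a backtracking Armijo line search on
$E_\mathrm{eff}$, in Cartesians. Convergence follows the usual compliance
criteria of geometry optimizers, all four at once: max gradient component
≤ 4.5·10⁻⁴ au, RMS gradient ≤ 3·10⁻⁴ au, |ΔE| ≤ 10⁻⁶ Ha, max atom
displacement ≤ 1.8·10⁻³ Å. Each accepted cycle records backbone energy E,
effective energy, anchor distance and gradient norm; frames are kept so
structural series can be extracted afterwards. Cycle counts are an
optimizer property: landmark *topology* (two backbone-energy maxima and
two minima along a super-threshold monomer stretch, first barrier
highest) is reproducible, absolute cycle numbers are not.

Two numerical knobs deserve note:

* `max_step` (default 0.3 Å per atom per cycle) caps displacement. A
  descent method with large steps can hop a nearly-vanished barrier
  slightly *before* its saddle-node force; with `max_step = 0.05` the
  recovered tipping force of an analytic quartic double-well agrees with
  the closed form $f^* = \mathrm{bohr}\cdot 8Aw^3/(3\sqrt3)$ to the
  bisection resolution (5·10⁻⁴ au). The tests use the tight cap for
  oracle comparisons and the default elsewhere.
* `rupture_factor` (default 2.0): any bonded pair exceeding twice its
  reference length is logged as a rupture event; optimization continues,
  and a non-finite energy aborts with the diagnostic trace attached.

`vibrational_stability()` builds the mass-weighted Hessian from central
differences of the analytic gradient (step 10⁻³ Å), projects out the
rigid-body modes (6, or 5 for linear molecules, identified by QR rank of
the translation/rotation basis), and reports the lowest nontrivial
frequency with negative eigenvalues flagged as imaginary modes. On a
harmonic dimer the frequency matches $\sqrt{k/\mu}$ to numerical
precision.

# Ring pucker analysis

`puckering_coordinates()` implements the standard six-ring puckering
analysis relative to the mean plane: amplitude Q, phase angles θ (chairs
at the poles) and φ, components (q₂, q₃) with q₂²+q₃² = Q². Atom order is
O5, C1…C5 with the IUPAC torsion sign convention; this fixes the φ
origin, so labels are reproducible. The canonical table of 38 conformers
(2 chairs, 6 boats, 6 skews, 12 envelopes, 12 half-chairs) is *generated*
from the defining out-of-plane patterns through the same transform, which
makes table and classifier exactly self-consistent: ⁴C₁ sits at θ = 0,
boats/skews alternate every 30° on the θ = 90° equator (⁵S₁ at φ = 90°,
²S_O at 150°, ᴼS₂ at 330°), envelopes and half-chairs on the
θ ≈ 54.7°/125.3° tropics. `classify_canonical()` takes the nearest
canonical form by great-circle distance; exact ties break
deterministically to lower ideal θ, then lower ideal φ. Rings with
Q below 0.05 Å are "planar" and refuse a label rather than guessing.

`decompose_torsions()` is the independent second route: least-squares
coefficients of the observed endocyclic-torsion 6-vector in the ideal
basis {¹C₄, ¹,⁴B, ᴼS₂} (which spans the three pucker degrees of freedom),
plus the closest canonical form by cosine similarity over all 38 ideal
torsion vectors. The two classifiers agree exactly on every ideal
conformer and, on random rings, disagree only inside a narrow boundary
band (within ~8° of a label boundary on the pucker sphere) where the two
metrics legitimately warp differently.

`label_by_length()` is the coarse, comparison-oriented labelling by
characteristic relaxed unit length: c = 4.5, b1 = 4.3, b2 = 5.1,
ic = 5.5 Å, capture radius ±0.25 Å, ties to the lower-energy family
(c, ic, b1, b2). Pucker-based classification is primary; length bins
conflate ring pucker with exocyclic bond orientation and are kept only
because relaxed unit lengths are what stretch–relax tables report.

# Synthetic structures

`build_ring_from_pucker()` inverts the pucker transform: out-of-plane
displacements are set from (Q, θ, φ) and the in-plane polygon is the
unique convex cyclic hexagon whose 3-D edge lengths equal the requested
bond lengths (circumradius by 1-D root finding). Round-trip recovery of
(Q, θ, φ) is exact to 10⁻⁶, which is the oracle the pucker tests lean on.

The default amplitude is the one minimizing summed squared deviation of
the endocyclic angles from tetrahedral at the requested phase — ≈0.61 Å
at the chair poles and ≈0.70 Å on the equator. Twist-boats genuinely
pucker harder than chairs (cyclohexane: 0.63 vs 0.75 Å), and a single
fixed amplitude would build equatorial conformers with unrealistically
flat rings and wrong anchor spans.

`build_galacturonic_monomer()` decorates the ring into the 23-atom
C₆H₁₀O₇ unit (hydroxyls at C1–C4, carboxyl at C5) using standard bond
lengths (C–C 1.52, C–O ring 1.43, C–O–H 1.42, C=O 1.21, O–H 0.97, C–H
1.10 Å) and tetrahedral/trigonal placement. Stereochemistry is encoded as
a conformation-independent branch sign per ring atom, recorded once in
the reference ⁴C₁ chair with O1 and O4 axial (the α-anomeric and galacto
configuration); re-applying the same signs at any other pucker converts
axial to equatorial exactly as ring inversion does physically. The
resulting anchor spans are 4.37 (⁴C₁), 5.50 (¹C₄), 5.13 (²S_O) and
4.50 Å (⁵S₁). `build_oligomer()` chains units through C1–O–C4′ glycosidic
bonds by internal-coordinate placement (bond 1.42 Å, angle 117°,
dihedrals set exactly); condensation removes one water per linkage
(23n − 3(n−1) atoms). Default linkage dihedrals (φ = −35°, ψ = −25°,
hydrogen-referenced convention H1–C1–O–C4′ / C1–O–C4′–H4′) give an
extended clash-free chain; a clash below 1.0 Å between atoms more than
two bonds apart triggers a retry with nudged dihedrals, then an error
naming the pair. Anionic units are formal-charge bookkeeping only (the
carboxyl proton is removed); their energetics are backend-level and
untested on the toy model.

# Protocol and analysis choices

* Every ladder force starts from the same pre-relaxed reference (the
  experiment's protocol), not quasi-static continuation.
* Regions are maximal runs of constant relaxed label vector below the
  first rupture force; transition forces are the region boundaries.
* `find_minimal_transition_force()` walks the ladder to a bracket and
  bisects to `refine_resolution` — the principled replacement for an
  irregular hand-tuned fine grid, and the bracket is returned so the
  bisection invariant is checkable.
* `detect_plateaus()` needs an operational definition (none exists in
  the force-spectroscopy literature at this granularity): a consecutive
  span whose extension jumps by ≥ `jump_threshold` (default 0.3 Å) per
  ladder step while force advances ≤ 2 steps, onset at the force where
  the jumped extension is first attained. The default suits toy-backend
  jumps (the monomer flip jump is ≈0.3 Å); sub-0.1 Å plateaus reported
  at electronic-structure scale are below this resolution, so the
  threshold is a documented, configurable parameter.
* `structural_trace()` exposes the two-phase narrative check directly:
  anchor length per cycle (which saturates first), glycosidic φ/ψ (unit
  rotation), and the O4ᵃ–C4–C3–C2 dihedral of the O4-terminal ring
  (which jumps when the ring flips).

# Problem sizes and testing scope

The shipped tests run the full pipeline at desk scale: monomer
stretch–relax ladders (13 forces and coarser), dimer/trimer/hexamer
builds, 1,000-ring classification sweeps, 100-probe gradient checks. The
whole suite completes in well under a minute on one core. Known
limitations: the toy backend's thresholds are not the DFT thresholds (by
design); oligomer per-position transition patterns are reproduced only
qualitatively (mixtures of ¹C₄/⁵S₁/²S_O appear, but which terminal
carries the full flip can differ from the reference calculations);
5- and 7-membered rings and branched or esterified pectin fragments are
out of scope.
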
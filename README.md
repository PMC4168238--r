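# egopull

Simulated single-molecule force spectroscopy of pyranose oligomers by
**Enforced Geometry Optimization (EGO)** — geometry minimization on the
force-modified energy surface

```
E_eff(x) = E(x) − f · d(x)
```

where `d` is the distance between two anchor atoms and `f` a constant
stretching force in atomic units (1 Hartree/Bohr = 82.387 nN ≈ 82.39 nN).

The package is aimed at people studying the nanomechanics of pectin-like
polysaccharides. α-D-galacturonic acid — the backbone unit of
homogalacturonan — carries its glycosidic (C1–O) and aglycone (O–C4)
bonds axially in the resting ⁴C₁ chair. Under tension these bonds act as
levers that torque the ring, and above a threshold force the ring flips
permanently into the inverted chair ¹C₄ through the twist-boat band,
lengthening the unit from ≈4.5 Å to ≈5.5 Å. `egopull` implements the
whole computational experiment around that mechanism:

* a molecular structure model with XYZ/PDB readers and writers
  (`molecule()`, `read_structure()`, `write_structure()`);
* an energy-backend contract plus a built-in molecular-mechanics model
  whose six-rings have chair, twist-boat and inverted-chair basins
  (`toy_ff_build()`); any external quantum code can stand behind the same
  contract;
* the EGO engine: quasi-Newton descent on `E_eff`, per-cycle traces,
  bond-rupture logging, numerical vibrational analysis
  (`optimize_enforced()`, `relax()`, `vibrational_stability()`);
* ring-pucker analysis: puckering coordinates (Q, θ, φ), the canonical
  38-conformer classification, torsion-basis decomposition, and
  characteristic-length bins (`puckering_coordinates()`,
  `classify_canonical()`, `decompose_torsions()`, `label_by_length()`);
* the stretch–relax protocol: force ladders, region segmentation,
  adaptive minimal-transition-force search, per-unit transition labels
  (`run_stretch_relax_scan()`, `find_minimal_transition_force()`);
* force–extension curves, plateau detection and optimization-history
  landmarks (`build_force_extension_curve()`, `detect_plateaus()`,
  `find_history_landmarks()`, `structural_trace()`);
* a synthetic builder for rings at arbitrary pucker, galacturonic
  monomers and (1→4)-linked oligomers up to hexamers and beyond
  (`build_ring_from_pucker()`, `build_galacturonic_monomer()`,
  `build_oligomer()`).

## Worked example

Stretch a single galacturonic unit over the standard 0.02–0.08 au force
ladder and ask what survives relaxation:

```r
library(egopull)

convert_force(c(0.07, 0.041), "au", "nN")
#> [1] 5.767 3.378          # printed 2-decimal pairs: 5.77, 3.38 nN

mono  <- build_galacturonic_monomer("4C1")
measure_unit_lengths(mono$mol, mono$topo)$L
#> [1] 4.365                # chair anchor span, Angstrom

model <- toy_ff_build(mono$mol, mono$topo)
scan  <- run_stretch_relax_scan(mono$mol, mono$topo, model, force_ladder())
scan
#> <scan_result> 13 forces in [0.0200, 0.0800] au
#>   start labels: 4C1
#>   region 1: f in [0.0200, 0.0550] -> 4C1
#>   region 2: f in [0.0600, 0.0800] -> 1C4
```

Below 0.055 au the pull is elastic: relaxation returns the ⁴C₁ chair.
From 0.06 au the relaxed structure is the inverted chair, and its anchor
span has jumped to the characteristic inverted-chair length:

```r
scan$summary$L_relaxed[scan$summary$f == 0.06]
#> [1] 5.525                # relaxed 1C4 length, vs 4.365 at the start

find_minimal_transition_force(mono$mol, mono$topo, model,
  force_ladder(0.02, 0.08, 0.01, refine_resolution = 0.00125))
#> <transition_force> ok: f* = 0.0565625 au, bracket [0.05625, 0.056875]
```

The force–extension curve shows the flip as a plateau:

```r
curve <- build_force_extension_curve(scan)
detect_plateaus(curve, jump_threshold = 0.2)
#> <plateau_set> 1 plateau(s):
#>   onset f = 0.0600 au, delta L = 0.30 A
```

and `structural_trace()` on the stretched trajectory shows the two-phase
course: the anchor distance saturates within the first tens of cycles
(chain elongation and bond alignment), the ring dihedral jumps much
later (the flip). A trajectory pucker trace passes through the
twist-boat band (θ ≈ 90°) on its way from chair (θ ≈ 0°) to inverted
chair (θ ≈ 180°).

The optional command-line front end wraps the same functions:

```sh
Rscript inst/cli/egopull.R build --n-units 3 --out trimer.xyz --topo trimer.json
Rscript inst/cli/egopull.R scan  --in trimer.xyz --topo trimer.json --outdir out/
```

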
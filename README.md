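# gastroflow

Comparative biofluid modeling of gastric emptying after the two bypass
operations used for gastric outlet obstruction (GOO): **conventional
gastrojejunostomy (CGJ)** — a side-to-side connection of the stomach's
greater curvature to the jejunum, stomach left undivided — and
**stomach-partitioning gastrojejunostomy (SPGJ)** — the same bypass plus a
near-complete staple partition leaving a ~20 mm channel along the lesser
curvature. Clinically SPGJ shows far less delayed gastric emptying (DGE);
`gastroflow` provides the simulation and statistics machinery to study why,
for surgeons and modelers interested in post-surgical upper-GI flow.

The package has two arms:

* **Physics.** A parametric, watertight upper-GI lumen (esophagus, J-shaped
  stomach, pyloric canal, duodenojejunal loop, gastrojejunal anastomosis,
  efferent limb) with CGJ/SPGJ virtual surgery; a voxel finite-volume
  solver for the steady incompressible Navier–Stokes equations
  (SIMPLE pressure–velocity coupling, second-order upwind momentum,
  scaled residuals to 1e-5) with fixed inflow (0.04 m/s), traction-free
  outflow and no-slip rigid walls; and Lagrangian food-particle tracking
  (drag law `F_D = 18 mu / (rho_p d_p^2) * C_D Re / 24` with
  Schiller–Naumann `C_D`, semi-implicit trapezoidal integration, elastic
  wall collisions, escape boundaries at inlet and outlet). Comparative
  metrics: pyloric flow split, inlet–outlet pressure drop, particle
  retention time and mean instantaneous speed.
* **Clinical statistics.** CONUT nutritional scoring (albumin +
  lymphocyte + cholesterol sub-scores, bands normal/light/moderate/severe),
  GOOSS and ISGPS-DGE grading as labels, Fisher's exact test by
  hypergeometric enumeration with Pearson/Yates chi-square cross-checks,
  exact reconstruction of the published SPGJ (n = 48) vs CGJ (n = 25)
  summary tables, and a synthetic cohort generator matched to the published
  marginals.

## Worked example: the clinical tables

```r
library(gastroflow)

incidence(1, 48)   # DGE incidence after SPGJ -> 2.1 (%)
incidence(9, 25)   # after CGJ                -> 36 (%)

# the published DGE 2x2 (1/47 vs 9/16)
fisher_exact(matrix(c(1, 9, 47, 16), 2))  # 0.000163  (printed bound: <0.001)

conut_score(32, 1.0, 3.0)
#>   albumin_score lymphocyte_score cholesterol_score score band
#> 1             2                2                 2     6 moderate

rebuild_tables()
#> Rebuilt study tables (SPGJ n = 48, CGJ n = 25)
#> Percentage cells: 12 of 12 match the printed value
#> Categorical contrasts: 17 of 17 consistent with the printed p
```

Every derivable percentage cell of the published tables matches after the
printed rounding, and every categorical contrast falls on the printed side
of its significance bound.

## Worked example: the flow comparison

```r
results <- lapply(c(CGJ = "CGJ", SPGJ = "SPGJ"), function(variant) {
  geom   <- build_lumen(anatomy_params(), variant)
  mesh   <- discretize(geom, 4)          # 4 mm voxels
  field  <- solve_steady(mesh)           # water, 0.04 m/s inflow
  cohort <- track_cohort(field, mesh, particle_spec(n = 1000, seed = 11))
  model_result(variant, field, mesh, cohort)
})
build_report(results$CGJ, results$SPGJ)
#> CGJ vs SPGJ gastric-emptying comparison
#>   pyloric flow, SPGJ / CGJ:        88.7%
#>   pressure-drop reduction (SPGJ):  0.2%  (3.784 vs 3.791 Pa)
#>   mean retention ratio CGJ/SPGJ:   1.07  (34.0 vs 31.6 s)
#>   mean particle speed:             CGJ 29.1, SPGJ 29.2 mm/s
```

All four comparisons point the way the published patient-specific study
found (partitioning suppresses pyloric flow, lowers the pressure drop,
shortens retention, speeds particles up), and the particle speeds land in
the published 22–29 mm/s range; the *magnitudes* of the pyloric
suppression and pressure-drop reduction are geometry-specific and are much
weaker on this generic parametric stomach — see the methods vignette
(`vignettes/gastric-emptying-model.Rmd`) for the model, its assumptions and
its limitations.

Solver validation rests on closed forms: Hagen–Poiseuille pressure gradient
within 3%, Stokes-regime linearity, exact global mass balance, the 5%
mesh-independence gate, exponential drag relaxation within 1%, and
tracer-limit equivalence of particle trajectories and streamlines within 2%.

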
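---
title: "Modeling gastric emptying after CGJ and SPGJ reconstruction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling gastric emptying after CGJ and SPGJ reconstruction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(gastroflow)
```

## The question

Gastric outlet obstruction (GOO) blocks the pylorus or duodenum, usually by
a distal gastric or pancreatic tumor. Two bypass operations restore oral
intake: conventional gastrojejunostomy (CGJ), a side-to-side connection of
the greater curvature to the jejunum with the stomach left undivided, and
stomach-partitioning gastrojejunostomy (SPGJ), the same bypass plus a
near-complete staple partition of the stomach that leaves a 2–3 cm channel
along the lesser curvature. Clinically, SPGJ shows markedly less delayed
gastric emptying (DGE). `gastroflow` implements a comparative biofluid
model of the two reconstructions — steady laminar flow of gastric contents
through parametric post-surgical anatomy, with Lagrangian food-particle
tracking — alongside a clinical-statistics module that reproduces the
published cohort comparisons and generates matched synthetic cohorts.

## The parametric anatomy

No patient imaging ships with the package. `build_lumen()` constructs a
watertight implicit (signed-field) lumen from swept capsule chains with
elliptical cross-sections, laid out in the sagittal-like x–z plane:

* esophagus: straight vertical tube, 100 mm long, 24 mm inner diameter;
* stomach: J-shaped sweep, greater-curvature arc 280 mm, widest lumen
  80 mm, flattened 0.7:1 in the anterior–posterior direction — dimensions
  of a normal-stature adult with a distended (gastric-filling) stomach;
  a lesser-curvature fill tube keeps the lumen continuous across the
  incisura, where a bare capsule chain would pinch off;
* pyloric canal 15 mm in diameter (times an optional `stenosis_factor`,
  default patent), continuing into a 25 mm bowel swept through an anterior
  duodenojejunal loop whose length is calibrated to 350 mm from pylorus to
  anastomosis;
* a 45 mm side-to-side gastrojejunal anastomosis at the lowermost point of
  the greater curvature, modeled as a capsule bridge between the stomach
  and the jejunal contact segment;
* an efferent limb of 150 mm from the anastomosis to the outlet (not
  reported for the original models; chosen so the outlet sits far from the
  junction recirculation).

The SPGJ variant adds a 10 mm-thick stapled partition wall just distal to
the anastomosis, pierced by an explicit residual channel of diameter
`partition_channel_width` (default 20 mm, configurable 20–30 mm) hugging
the lesser curvature. Both variants are bit-identical outside the
partition neighborhood, which is the variant contract the tests verify.
Every dimension above is a field of `anatomy_params()`.

Stomach-body shape, the anastomosis bridge construction, and the efferent
routing are package design choices: the source models were patient-specific
CT segmentations that are not available, so the generator exposes the
printed dimensions as parameters and fills the gaps with standard anatomy.

## Discretization

`discretize()` voxelizes the implicit lumen into uniform cubic cells (cells
whose center lies inside the surface), tags inlet and outlet as the top and
bottom grid planes, keeps the inlet-connected component, and stores oriented
staircase cuts for the pyloric and anastomotic cross-sections. By
incompressibility a staircase cut carries exactly the flux of the plane it
approximates, so flow splits are conservative by construction. Cell sizes
are the user's accuracy dial: the included validations use 1–2 mm tubes and
4–5 mm anatomy meshes (the problem sizes used throughout the tests and the
acceptance script), with the 5 % mesh-independence criterion
(`mesh_independence_check()`) as the quality gate.

## Flow model

Steady incompressible Navier–Stokes with water properties
(`fluid_properties()`: density 998.2 kg/m³, viscosity 1.003 mPa s), uniform
0.04 m/s inflow at the esophageal inlet, traction-free outlet (zero gauge
pressure, zero normal gradient) and rigid no-slip walls. The configuration
Reynolds number is about 950 — laminar, so no turbulence model. The solver
(`solve_steady()`) is a SIMPLE finite-volume scheme on a staggered voxel
grid:

* momentum convection is deferred-correction second-order upwind (pure
  first-order for the opening iterations for robustness);
* wall no-slip enters through one-sided diffusion links whose wall
  distances are bisected from the implicit geometry rather than taken as
  half a cell — this largely removes the stair-step bias in wall shear and
  is what lets a voxel mesh reproduce the Hagen–Poiseuille pressure
  gradient within 3 % at R/h = 8;
* pressure correction solves a pure-Neumann Poisson system by conjugate
  gradients with the mean projected out; the outlet flux is a zero-gradient
  extrapolation with a uniform additive shift enforcing global mass
  balance, and gauge pressure is referenced to a zero outlet mean;
* convergence requires all scaled residuals (normalized by their largest
  early-iteration values) below 1e-5; under-relaxation defaults are 0.5
  (velocity) and 0.2 (pressure), chosen because the standard 0.7/0.3 pair
  diverges at this Reynolds number on these meshes.

For validation, `boundary_conditions(profile = "parabolic")` imposes a
fully developed inflow: at 0.04 m/s the laminar entrance length (~1.4 m) is
far longer than the 100 mm validation tube, so the flat-inlet configuration
never reaches the fully developed gradient that the closed-form
Hagen–Poiseuille expression describes. The anatomy runs use the flat
profile.

## Particle model

`track_cohort()` integrates one-way-coupled food particles (density
1300 kg/m³, diameter 50 nm as published — the value may well be a typo for
50 µm, but both are far inside the tracer regime, with momentum response
times of 1e-10–1e-4 s, so the emptying metrics are insensitive; a
`diameter` override is provided). Drag uses the Schiller–Naumann
correlation, which reduces to Stokes drag at the operative particle
Reynolds numbers (~1e-4); a pure-Stokes option exists for the closed-form
oracle tests. The optional body force is off by default (the source model
states no gravity vector); `gravity_preset()` supplies the
buoyancy-corrected acceleration for sensitivity studies.

Integration is the semi-implicit trapezoidal rule: implicit in particle
velocity, explicit in the fluid velocity interpolated (trilinearly,
component-wise on the staggered grid) at the old position, with positions
advanced by the trapezoid of old and new particle velocities. The scheme is
unconditionally stable for the linear drag term. In the stiff tracer limit
the velocity iterate oscillates around the local fluid velocity without
decaying (the rule is A-stable but not L-stable); the displacement per
step — the trapezoid average — is smooth, so recorded instantaneous speeds
are the displacement rates, and injection rejects starting points that the
voxelization classifies as wall. Walls reflect specularly with speed
preserved to machine precision; the inlet and outlet planes are escape
boundaries, and retention time is the injection-to-escape interval.
Particles are injected uniformly over the inlet disc with a fixed seed;
identical seeds give bit-identical trajectories. Time steps are bounded by
0.2 cells of travel per step. "Mean instantaneous speed" is the
sample-weighted mean over a uniform 0.1 s output grid of escaped particles'
speed records (time- and sample-weighting coincide on a uniform grid);
escaped-only is the default because timed-out particles have censored
histories.

## Comparative metrics

`model_result()` and `build_report()` assemble the four published
comparisons: pyloric flow in SPGJ as a percentage of CGJ, relative
pressure-drop reduction, mean retention-time ratio (CGJ/SPGJ) and mean
particle speeds in mm/s. One behavior of the synthetic anatomy deserves
note: the steady pyloric flow is a junction-driven recirculation — the
anastomotic stream entrains flow around the duodenal loop, so the net
pyloric flux is small and retrograde (duodenum toward stomach, a few
percent of the inflow) in both variants. This is the countercurrent
duodenal flow the source study also describes. The pyloric flow ratio is
therefore computed on flux magnitudes, with a warning whenever retrograde
flow is detected.

What passing tests show — and what they do not: the published comparative
values came from one patient's CT-derived geometry; on the parametric
anatomy the directional findings are reproducible, and particle speeds land
in the published range, but the pyloric suppression (published: SPGJ flow
5 % of CGJ) and the 9 % pressure-drop reduction depend on how completely
the partition intercepts the antral stream in that specific stomach, and a
generic parametric stomach with a patent 20 mm channel does not reproduce
their magnitudes. Rigid walls, no peristalsis, no particle-particle
interaction and steady inflow are shared simplifications of model and
source.

## Clinical statistics

The clinical module embeds every categorical count of the published
baseline and outcome tables (SPGJ n = 48 vs CGJ n = 25).
`rebuild_tables()` recomputes all derivable percentage cells (they match
the printed values exactly after one-decimal rounding) and re-runs the
categorical contrasts with Fisher's exact test — implemented by
hypergeometric enumeration, the reproducible standard since the source
names only "non-parametric tests" — plus Pearson and Yates chi-squares as
cross-checks. Printed bounds ("<0.001") are checked strictly against the
exact test; numeric printed p-values are checked for agreement on the side
of the 0.05 significance level, because the source mixes test conventions
across rows (its sex and disease rows reproduce the uncorrected Pearson
p-values, the surgical-approach row the Yates-corrected one, and the
anastomotic-stenosis row the exact test — consistent with default SPSS
reporting).

CONUT scoring uses the standard component cutoffs in SI units (albumin
g/L: 35/30/25; lymphocytes 1e9/L: 1.6/1.2/0.8; cholesterol mmol/L:
4.66/3.62/2.59) with the published severity bands (normal 0–1, light 2–4,
moderate 5–8, severe 9–12); only the bands are printed in the source, the
cutoffs come from the cited CONUT standard.

`generate_cohort()` builds synthetic per-patient records whose categorical
marginals (sex, disease, complications with Clavien–Dindo grades, DGE
grades, GOOSS levels, CONUT bands) match the published counts exactly, with
laboratory values sampled inside the component-cutoff intervals of each
patient's assigned band and recovery times drawn from discretized
log-normals matched to the published medians and interquartile ranges. The
cohort emulates marginal summaries only — it carries none of the real
registry's joint structure (correlations between nutrition, disease stage
and outcomes), so it supports testing the scoring and tabulation machinery,
not clinical inference.

## Reproducing the comparison

```{r, eval = FALSE}
library(gastroflow)

results <- lapply(c(CGJ = "CGJ", SPGJ = "SPGJ"), function(variant) {
  geom <- build_lumen(anatomy_params(), variant)
  mesh <- discretize(geom, 4)                        # mm
  field <- solve_steady(mesh)                        # 0.04 m/s inflow
  cohort <- track_cohort(field, mesh, particle_spec(n = 1000, seed = 11))
  model_result(variant, field, mesh, cohort)
})
build_report(results$CGJ, results$SPGJ)
```

`scripts/acceptance.R` wraps exactly this pipeline (plus the
mesh-independence gate) and writes the headline numbers as JSON.

## Known limitations

Rigid walls and steady inflow (no peristalsis, no swallowing cycle); voxel
walls with first-order-corrected shear rather than body-fitted cells;
single-phase Newtonian contents; one-way particle coupling without
Brownian motion; a generic parametric stomach standing in for
patient-specific shape, which is the dominant reason the pyloric-suppression
and pressure-drop magnitudes of the source study are not reproduced
quantitatively.
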
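---
title: "Strain-adaptive periprosthetic remodeling of the proximal tibia: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Strain-adaptive periprosthetic remodeling of the proximal tibia: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# Scope

`tkaremod` simulates long-term bone remodeling around a cemented tibial
tray after total knee arthroplasty (TKA), over a population of synthetic
subjects, and evaluates the result the way a longitudinal densitometry
study would: as areal bone mineral density (BMD) in three periprosthetic
regions of interest (ROIs) on an anterior–posterior (AP) projection.  The
pipeline is:

1. **Synthetic cohort** — subject records (sex, age, body weight, height,
   BMI, knee alignment angles, tray size) with exact alignment-by-sex
   marginal counts, plus a parametric proximal tibia per knee.
2. **Virtual TKA** — resection, cement mantle, tray with keel, and PE
   insert on the same conforming grid as the intact bone.
3. **Material mapping** — apparent density per element, power-law
   modulus–density relations, optional calibration of a CT-like volume via
   air/fat/muscle histogram peaks.
4. **FE solves** — linear tetrahedral elasticity under activity peak loads
   (gait, step down, deep knee bend), preoperatively through cartilage
   springs, postoperatively on the insert contact patches.
5. **Strain-adaptive remodeling** — the lazy-zone rate law iterated in
   computer time units (CTU) over 15 years.
6. **Virtual DEXA** — fine voxelization, AP projection, ROI evaluation.
7. **Population statistics** — two-tailed Z-tests, Pearson correlations,
   alignment/sex subgroups.

All stochastic stages derive their seeds from one master seed through
named substreams, so one integer reproduces a whole run.

# The remodeling model

The stimulus for density change is strain energy density (SED) per unit
bone mass.  A preoperative solve under native-alignment loading defines
the element-wise reference `Sref = U_pre / rho`; every iteration of the
postoperative simulation recomputes `S = U_post / rho` with moduli
refreshed from the current density field.  The rate law has a dead band
("lazy zone") of half-width `s = 0.35`:

* `drho/dt = a(rho) * (S - (1 + s) * Sref)` when `S/Sref - 1 >= s`,
* `drho/dt = 0` when `|S/Sref - 1| < s`,
* `drho/dt = a(rho) * (S - (1 - s) * Sref)` when `S/Sref - 1 <= -s`,

which is continuous (rate → 0) at both zone boundaries.  `a(rho)` is the
available free (internal) bone surface, evaluated from a quintic
polynomial in porosity `p = 1 - rho/1.73`
(`a = 32.3p - 93.9p² + 134p³ - 101p⁴ + 28.8p⁵`, the standard specific-
surface fit); denser bone exposes less surface and responds more slowly.
Time is counted in CTU with 30 CTU per postoperative year and a 15-year
horizon.

## Time integration

The stepping rule is an adaptive forward Euler:
`dt = min(dt_max, drho_cap / max|drho/dt|)` with `drho_cap = 0.05` g/cm³
per iteration, clamping densities to `[0.01, 1.73]` g/cm³ (zero rate at an
active bound).  When every element falls inside the lazy zone the field is
an exact fixed point — recomputing S would reproduce itself — so the
remaining horizon is fast-forwarded without further solves.  Follow-up
snapshots (default 0.5, 1, 1.5, 2, 3, 4, 5, 11.6, 15 years) are linearly
interpolated in t between iterations.  Elements whose reference stimulus
falls below `sref_floor = 1e-9` are treated as lazy to avoid division
blow-ups in nearly unloaded marrow space.  The `dt_max` cap is 1 CTU for
reference runs; the coarse profile (below) raises it to 10 CTU, which the
single-element convergence test bounds against a fine-step reference.

# Loading

Condyle peak forces for gait, step down (SD) and deep knee bend (DKB) are
tabulated per native alignment group in percent body weight and scaled as
`F[N] = (%BW/100) · BW[kg] · 9.81`; knees with unknown body weight use the
59 kg average female body weight of the population.  Medial and lateral
centers of pressure (COPs) sit at ±25% of the tray ML width; the AP
offset is configurable (default 0).

*Preoperative* models are rotated to the native joint-line convention
(varus +5° VV, neutral 0°, valgus −3°) and loaded through cartilage
springs: surface nodes are recruited nearest-first until their tributary
areas fill the condyle contact area (default 300 mm²), each spring with
`k = E_cart · A_i / L_i` and `E_cart = 9` MPa.

*Postoperative* models are mechanically aligned, and the package's default
applies the **neutral-alignment load rows** on the insert contact patches.
The tabulated rows are implant loads per *native* alignment, and whether
the original analysis kept the native row after mechanical alignment is
ambiguous; both modes are implemented
(`loads$postop_alignment = "neutral"` or `"native"`).  Neutral is the
default here because mechanical alignment is exactly what the virtual
surgery enforces, and because the load redistribution it implies (medial
unloading of constitutional varus knees, lateral re-loading) is the
mechanism behind the alignment-dependent remodeling differences the
analysis is meant to expose.  With `"native"` the between-group contrasts
shrink accordingly.

The distal 150 mm cut is fully constrained (a standard far-field
simplification that keeps the periprosthetic region of interest away from
the boundary).

# The synthetic cohort: what it emulates, and what it does not

No public imaging accompanies the modeled population, so the cohort is
synthetic by construction and every stage is testable without downloads.

**Geometry.** The tibia is a lofted solid of elliptical cross sections
(condylar plateau, metaphyseal flare, shaft), meshed by splitting a
structured grid into conforming tetrahedra and keeping elements inside the
solid.  Implant parts are classified on the *same* grid, so bone–cement–
tray–insert contact is tied by shared nodes and every retained bone
element maps to its preoperative self exactly (element-wise SED
comparison needs no interpolation).  A fine grid band spans the resection
interface so the 0.75 mm cement mantle is resolved in its own element
layer.  Resection: 8 mm below the plateau apex with a 5° posterior slope;
the keel (30 mm, radius scaled with the tray) is carved from the bone;
the cement layer spreads over the entire cut surface so the cortical rim
participates in load transfer at any mesh resolution.  Tray footprints
scale with the bone cross-section by a linear size table, giving ~87%
bone coverage at the median size.

**Density field.** Cancellous density decays from a subchondral plateau
value (0.38 g/cm³) toward marrow (0.05 g/cm³) with a medial–lateral
gradient by native alignment (varus denser medially, valgus laterally),
multiplied by a subject-level density factor (log-SD 0.14, weakly
positively coupled to age and BMI) and element-level log-normal noise
(SD 0.08).  A second subject factor scales the cross-sections (log-SD
0.05, about the anatomical coefficient of variation of plateau width
within one population, coupled to height), so baseline areal BMD varies
through both bone size and bone density — as in a real cohort.  The mix
matters: density-driven baseline variation couples negatively to
subsequent net bone loss (denser compartments have more to lose and, in
varus knees, lose their load surplus under mechanical alignment), while
pure size variation leaves the stimulus ratio nearly unchanged; the
defaults keep density the dominant source so the cohort reproduces the
assumed baseline-vs-remodeling correlation structure.

**The cortical shell** is one element layer thick at any mesh edge and is
an *equivalent-projection* construct: its density is
`1.5 g/cm³ · min(1, t_c/h)` (metaphyseal `t_c` 0.75 mm tapering to a
2.35 mm diaphyseal shell), so a projection ray crossing the shell picks up
the areal surface density of a thin dense cortex regardless of element
size `h`.  Its stiffness follows a linear law anchored at the true
cortical modulus (`E = E_cort(1.5)/1.5 · rho`): membrane stiffness of a
thinning dense plate, not a porosity power law.  Its remodeling surface
`a` is evaluated at the fully dense density, because thinning reduces the
equivalent density without making the cortex porous.  At a 2 mm mesh the
construct converges to literal dense cortex.

**What passing tests do not show about real data.** The generator
reproduces the *statistical structure* the analysis assumes — baseline ROI
levels and their spread, ML asymmetry by alignment, covariate
correlations — not real anatomy: no subject-specific shape variation
beyond isotropic scaling, no OA subchondral sclerosis beyond the ML
gradient, no soft tissue in the projections (clinical DEXA includes it),
and smooth implant geometry instead of CAD surfaces.  Cohort-level
magnitudes of simulated BMD change are therefore indicative, not
calibrated; the acceptance checks of the cohort stage are sign patterns,
not magnitudes.

# Material model

Cancellous bone: `E = 6850 · rho^1.49` MPa; cortical (above 1.2 g/cm³):
`E = 10200 · rho^2.01` MPa — widely used published defaults, fully
configurable, and no downstream check depends on the constants.  Fixed
moduli: CoCr tray 210 GPa, PE insert 588 MPa, cement 2551 MPa; Poisson
ratio 0.3 everywhere.

**HU calibration.** Synthetic CT volumes paint bone voxels with
`HU = (rho - intercept)/slope` (default slope 0.001 g/cm³/HU, intercept
1.0, so air at −1000 HU maps to density 0) plus elliptical fat and muscle
halo shells at their density-equivalent HU, and optional additive speckle.
`calibrate_hu_to_bmd()` finds the air/fat/muscle peaks as local maxima of
a smoothed histogram inside nominal HU windows, refines each peak as the
count-weighted centroid of nearby raw intensities (sub-bin accuracy), and
fits the line by least squares; an undetectable fat peak — as under heavy
speckle — falls back to the exact two-point air–muscle line with a
warning.  Tissue reference densities default to air 0, fat 0.95, muscle
1.05 g/cm³-equivalent and are configurable.

# Virtual DEXA

Element ids are mapped into a cubic voxel grid (0.2 mm edge in the
reference profile) and areal BMD is the AP column sum of `rho ·
voxel_edge`.  Voxel sampling points carry a fixed sub-voxel irrational
offset so they never fall exactly on element faces (ties would bias
per-element voxel counts on a structured mesh).  The projection is built
once per model as a sparse pixels-by-elements operator, so a full
remodeling trajectory of ROI values costs one dot product per snapshot.
Projection includes bone only by default, matching densitometry of the
segmented tibia; cement inclusion is available as an option.

ROIs are 1 cm² squares placed relative to the tray: medial and lateral
top edges 1 cm distal to the baseplate plane with outer edges on the
projected cortical silhouette, and the distal ROI 4 cm below the
baseplate, ML-centered on the keel.  The baseplate reference height is
the sloped resection plane at the ML axis plus the cement thickness.
"0.2 mm cubic voxels" is read as cubic voxels of 0.2 mm edge length.

# Statistics

Group comparisons use the two-sample Z-test on summary statistics
(`z = (m1 - m2)/sqrt(sd1²/n1 + sd2²/n2)`, two-tailed normal p), assuming
normality and applying no multiple-testing adjustment — both stated
properties of the emulated analysis, recorded in the output metadata.
Pearson correlations get two-tailed p-values from the t-approximation
with n − 2 degrees of freedom, pairwise-complete over missing covariates;
zero-variance inputs are flagged undefined rather than dropped silently.
Outcome deltas are per-subject (`delta_abs = bmd(t) − bmd(0)`,
`delta_rel` in percent of baseline), so group SDs of the deltas are
meaningful.  Groups with fewer than two knees (the single valgus knee)
are summarized without tests.

# Problem sizes and profiles

Two bundled profiles share identical physics:

| | fine | coarse |
|---|---|---|
| mesh edge | 2 mm | 8 mm |
| `dt_max` | 1 CTU | 10 CTU |
| DEXA voxel | 0.2 mm | 0.8 mm |

The coarse profile is the package's desk-scale choice for cohort runs,
tests and the acceptance script (a 26-knee, 15-year cohort completes in
minutes); the fine profile reproduces the reference problem sizes.  Mass
conservation of the projection is verified to 2% at 0.2 mm voxels on
generic-position test meshes and to 5% at coarse voxels on the tibia.

# Known limitations

* Constant-strain tetrahedra are stiff in bending; the coarse profile
  inherits the usual CST accuracy limits (the refinement test verifies
  the expected O(h) energy-norm convergence).
* The insert–tray articulation is tied, not a rotating-platform contact;
  activity peaks stand in for full load cycles; muscle and ligament
  forces are absent, so distal load paths are least trustworthy — the
  simulated distal ROI shows strong keel-tip-driven formation.
* Formation and resorption share one rate law; no systemic age-related
  bone loss over follow-up; no post-yield behavior.
* The synthetic CT's HU scale is self-consistent with its calibration
  line but is not a radiological HU scale for bone (apparent bone
  densities sit below the fat reference on that line); calibration
  windows are set accordingly.
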
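---
title: "Traction biomechanics for endoscopic thyroidectomy planning: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Traction biomechanics for endoscopic thyroidectomy planning: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The clinical question and the model chain

During total endoscopic thyroidectomy via the areola approach (ETA), the
instruments work caudal-to-cranial and the clavicle and sternum hide the
deepest central-compartment nodes (level VII, between the clavicular plane
and the innominate artery). Whether those nodes can be cleared depends on how
far the overlying soft tissue can be pulled by the grasper. `etaplan`
implements a desk-scale version of the full decision chain:

1. a parametric tissue–artery geometry with a tagged tetrahedral mesh;
2. a static finite-strain solve of the tissue (Neo-Hookean) and artery wall
   under instrument traction (0.5–2 N);
3. steady laminar blood flow in the lumen, staggered-coupled to the wall
   motion;
4. the clearance rule: level VII counts as clearable when the simulated
   tissue deformation reaches the patient's clavicle-to-artery distance DD3;
5. cohort statistics (Welch ANOVA, chi-square, Pearson) over synthetic
   patient cohorts with the study's structure.

## Geometry: a mobile tissue plate over a perivascular bed

Patient-specific CT geometry is out of scope; the stand-in is parametric. The
design is driven by one hard empirical constraint: the reported deformation
falls steeply with tissue thickness (1.8 / 0.96 / 0.47 cm at 2 N for 5 / 10 /
20 mm) while a 5 mm layer deflects by more than three times its own
thickness. Only plate/membrane mechanics of a layer whose *structural*
thickness is the stratum thickness reproduces both facts: bending stiffness
scales as $t^3$ for the thick strata and the large-deflection membrane regime
takes over for the thin ones. Two alternative readings fail qualitatively: a
tissue block with the artery embedded at depth responds mainly through the
block's overall depth (deformation *increases* with the stratum thickness),
and grasping directly above a wall bonded to the tissue caps the excursion
at a fraction of the reported values for any force in range (the anchored
column would need a stretch of ~4.6).

Hence the default geometry (all lengths are configuration knobs):

* a 60 × 40 mm tissue plate of height exactly `tissue_thickness`, fixed at
  both ends along the vessel axis;
* beneath the plate, a loose-tissue gap layer (`areolar_gap`, 1.5 mm or one
  element) and then the artery: outer diameter 12 mm, wall 1 mm, lumen
  10 mm — an adult innominate-artery calibre giving Re < 2300 with the
  stated blood constants;
* a perivascular collar (3 mm) couples plate and vessel *outside* a central
  20 mm `dissection_window`; inside the window the tissue has been dissected
  off the vessel, which is exactly the state in which the traction is
  applied during clearance;
* the traction patch (12 × 12 mm) sits just lateral to the projected artery
  edge: the grasper holds the node-bearing tissue beside the vessel, never
  the vessel itself. The default 12 mm footprint represents the tissue fold
  held by the jaw rather than the jaw's contact area; with a much smaller
  patch the response degenerates into a thickness-independent local
  punch-out of the patch (2 N over 25 mm² is 80 kPa on 10 kPa-shear tissue),
  which inverts the study's central thickness trend.

The solid (plate + wall) is meshed as a conforming structured grid split
into six tetrahedra per cell; the lumen is a separately meshed smooth
extruded polar cylinder, as in partitioned FSI practice, coupled across the
`fsi_wall` tag by interpolation. Mean radius-ratio quality of the defaults
is ≈ 0.70 (a regular tetrahedron scores 1).

## Solid mechanics

Tissue is compressible Neo-Hookean,
$W = C_1(\bar I_1 - 3) + \tfrac{1}{D_1}(J-1)^2$ with $C_1 = 5000$ Pa and
$D_1 = 1.4\times10^{-7}$ Pa⁻¹, i.e. shear modulus $\mu = 2C_1 = 10$ kPa and
bulk modulus $K = 2/D_1 \approx 14.3$ MPa ($\mu/K \approx 7\times10^{-4}$,
nearly incompressible). The volumetric term is written $(J-1)^2$, the form
that vanishes in the reference state, and $K = 2/D_1$ follows the standard
convention consistent with $D_1$'s units. The artery wall (E = 5 MPa,
ν = 0.49) runs through the same finite-strain machinery with matched
moduli; at its sub-percent strains this coincides with linear elasticity.

Near-incompressibility locks plain linear tetrahedra, so the tissue
volumetric energy uses the average-nodal-pressure element: the nodal
dilatation $\bar J_a$ is the volume-weighted mean of element $J$ over the
node's patch, and a nodal pressure field enters as an independent unknown
(mixed u–p). One refinement proved necessary: on thin plates the pure nodal
scheme admits spurious pressure checkerboards (the classic equal-order
instability), which stall the Newton iteration. A small local volumetric
penalty — 1 % of K per element, in parallel with the nodal term — suppresses
them without re-introducing locking; it also keeps element-level $|J-1|$
moderate at the patch-edge stress concentration. The near-incompressibility
of the *formulation* is measured on $\bar J$: at all study loads
$\max|\bar J - 1| < 0.05$, while raw element $J$ at the singular patch
corner reflects the averaged-pressure discretization rather than physical
dilatation.

The solver is an exact-Jacobian Newton on the saddle system, with the
diagonal pressure block eliminated by static condensation; the condensed
symmetric positive-definite matrix is factorized by supernodal Cholesky with
the symbolic analysis cached across iterations (an indefinite tangent far
from equilibrium triggers a Levenberg-style diagonal shift). Loading is
incremental (0.2 N steps, so ten increments at the 2 N study load) with
linear extrapolation predictors and adaptive step bisection; each step
converges to a relative force residual of 1e-6 with a residual-merit line
search. Dead traction is applied as force / tagged-facet-area on the patch.

Verification: a uniaxial patch test reproduces $FL/(EA)$; the assembled
residual is the exact gradient of the discrete energy (finite-difference
check); the converged solutions match an independently coded dense-assembly
Newton solver to 1e-8 on small meshes; the small-load response is linear to
1 %.

The reported deformation metric is the patch-average displacement magnitude
(the grasped-tissue excursion) in cm, with the tissue-wide maximum attached;
the wall metric is the volume-weighted mean von Mises stress over wall
elements, with the peak attached.

## Hemodynamics

Steady incompressible Navier–Stokes (written with the conventional
$\tfrac{1}{\rho}\nabla p$ term) with blood density 1060 kg/m³ and viscosity
0.003 Pa·s; Re = ρvL/μ with the lumen diameter as L, so the defaults give
Re = 2120 < 2300 and the solver refuses higher-Re inputs unless overridden.
Discretization is equal-order P1/P1 with PSPG pressure stabilization and
SUPG streamline stabilization; the convective term is Picard-linearized,
initialized from the Stokes solution, with Aitken Δ² adaptive relaxation
(plain under-relaxation falls into limit cycles near the upper laminar
range). Velocity inlet, no-slip walls, natural (0 Pa) pressure outlet.

The default inlet is the fully developed parabolic profile. At Re ≈ 2100
the laminar entrance length (≈ 0.06·Re·D ≈ 1.3 m) vastly exceeds the 60 mm
segment, so a plug inlet can never develop inside the domain and the
mid-plane metric would measure an arbitrary truncation artifact; the
physiological upstream vessel is long. A plug profile remains available.

The headline flow metric is the cross-section-average axial speed at the
mid-lumen node layer, computed as flux over projected (vector-sum) area so
that morph-induced warping of the triangulated section does not bias it.
Verification: the profile matches the Poiseuille parabola within 5 % of the
peak speed pointwise, discrete mass conservation holds within 0.5 % at every
section, the error halves under refinement, and mirror-symmetric geometry
yields a mirror-symmetric field.

## Coupling and what the model says about the reported flow numbers

One-way coupling (default, matching the causal narrative: traction → wall
motion → flow) interpolates the solid wall displacement onto the lumen
boundary, extends it harmonically into the interior (with a transfinite
re-mesh fallback should an element invert), and re-solves the flow;
two-way coupling iterates with the lumen pressure applied to the solid wall
until the wall displacement stops changing (tolerance 1e-5 m, outer budget
20 — the steady-state reinterpretation of the source's solver-product
"time step" setting).

The desk model predicts mid-lumen speed changes of at most ≈ ±0.1 % across
the study grid: with a velocity inlet, the sectional mean speed is flux over
area, and the wall (5 MPa) under ~7 kPa mean von Mises stress strains by
~0.1 %, so the lumen area barely changes — if anything the nearly
incompressible perivascular tissue, stretched vertically, necks inward and
pinches the vessel slightly. A −5 % speed change would require ~5 % area
growth, i.e. wall strains two orders of magnitude larger than the reported
wall stresses allow. The reported slowdown (−1.7 % to −5 %) is therefore not
reproducible from the quoted constants; the package reports the honestly
computed near-zero change, and the acceptance suite documents the
discrepancy rather than masking it. The absolute mid-lumen speed at the
study cells (~57–58 cm/s) does agree with the reported 57 cm/s.

## Clearance rule and stratification

DD1 (thyroid pole → artery), DD2 (pole → clavicular head) and
DD3 = DD1 − DD2 are *signed* projections on the craniocaudal axis, caudal
positive: printed DD3 values are negative for some patients (structures
already visible), which a Euclidean distance cannot express, and the cohort
means satisfy the subtraction identity. Strata: < 5 mm, 5–13 mm (both
bounds inclusive), > 13 mm, with values over 20 mm flagged. The verdict is
`deformation >= DD3` (equality counts as cleared; the difference is
measure-zero and the convention is documented). `critical_distance()`
returns the upper bound of the deepest stratum cleared at the maximum
force — 13 mm for the reported deformations and group-mean DD3 values
(0.01 / 0.86 / 1.63 cm).

## Synthetic cohorts

The generator reproduces the observable structure: (DD1, DD2) from a
bivariate normal truncated to the printed ranges, with DD3 = DD1 − DD2 also
range-limited. The DD1–DD2 correlation (0.571) is back-derived from
Var(DD3) = Var(DD1) + Var(DD2) − 2 Cov = 0.49, the unique value making all
three printed SDs mutually consistent. Because the printed moments describe
the truncated data, the latent normal parameters are calibrated by a short
deterministic Monte-Carlo fixed point (shift means, rescale sds, nudge the
correlation; six iterations at n = 20 000) — without this, truncation
biases the DD2 mean by ≈ +0.08 cm. Lymph-node counts are moment-matched
negative binomials per stratum (Poisson fallback with a warning when
sd² ≤ mean); metastatic counts are binomial thinnings of the totals, which
enforces metastatic ≤ total by construction while matching the printed
means (the metastatic SDs are then implied, not separately matched);
recurrence is assigned only within configured strata, with presets
`c(0,0,3)` (primary cohort) and `c(0,0,7)` (the external validation
series). Everything is reproducible bitwise from one seed (R's default
Mersenne-Twister).

What the generator does *not* emulate: real CT measurement error,
correlations between demographics and anatomy beyond the per-stratum sex
fractions, and any within-patient longitudinal structure. Tests passing on
these cohorts validate the statistical machinery and the pipeline plumbing,
not the clinical representativeness of the data.

## Statistics

Group comparisons go through base R (`oneway.test`, `chisq.test`,
`cor.test`); the summary-statistics Welch t is closed-form and tested to
1e-10 against the raw-data test. Welch ANOVA is preferred over classical
ANOVA when a median-centred Levene test has p < 0.05; both are always
reported. No multiple-testing correction is applied by default (matching
the source analysis); a Holm flag is available. The chi-square continuity
correction is off by default and switchable. Type-I error of all three
tests is calibrated by 10 000-replicate null simulations to 0.05 ± 0.007.

## Problem sizes and numerical defaults

Desk-scale resolutions: study fixtures use three element layers through
thin plates (5/3 mm at the 5 mm stratum) and 2.5 mm elements otherwise,
giving 10⁴–10⁵ solid tetrahedra; the verification meshes are smaller. The
default 1 mm element size on the full geometry yields ~2.7 × 10⁵ solid
elements — the same order as the reference model's mesh. Key tolerances:
Newton 1e-6 (relative force residual), Picard 1e-6 (relative velocity
change), wall-coupling 1e-5 m, clearance arithmetic exact.

## Known limitations

* The stand-in geometry is generic, not patient-specific; agreement with
  the reported simulation surfaces is order-of-magnitude/trend level
  (factor of two), and the 20 mm / 1 N deformation cell sits at the edge of
  that band.
* Quasi-static, isotropic, non-viscoelastic tissue; steady flow without
  pulsatility — both inherited from the source model's own scope.
* The reported flow-velocity reductions are not reproducible from the
  quoted material constants (see the coupling section); the package treats
  the direction-of-effect claim qualitatively.
* Linear tetrahedra with nodal pressure are first-order accurate; thin
  plates are resolved with at least three element layers but remain on the
  stiff side, which is visible in the thin-stratum deformation values.
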
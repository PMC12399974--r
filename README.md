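# etaplan

Preoperative biomechanics for total endoscopic thyroidectomy via the areola
approach (ETA). During ETA the clavicle and sternum hide the deepest
central-compartment lymph nodes (level VII, bounded below by the innominate
artery), and whether they can be cleared depends on how far the overlying
soft tissue moves under instrument traction. `etaplan` implements the whole
decision chain at desk scale, for surgeons and modellers who want a
reproducible, inspectable version of the analysis:

* **Geometry / meshing** — a parametric tissue-plate-over-artery model with
  a tagged tetrahedral mesh (regions `tissue`, `artery_wall`, `lumen`;
  boundary tags for fixed ends, traction patch, inlet/outlet, FSI wall),
  VTK and Gmsh export/import.
* **Solid mechanics** — static finite-strain FEM: compressible Neo-Hookean
  tissue, `W = C1 (Ī₁ − 3) + (1/D1)(J − 1)²` with C1 = 5000 Pa,
  D1 = 1.4×10⁻⁷ Pa⁻¹, and a stiff artery wall (E = 5 MPa, ν = 0.49), under
  0.5–2 N grasper traction. Anti-locking mixed nodal-pressure tetrahedra,
  exact-Jacobian Newton with incremental loading.
* **Hemodynamics** — steady laminar incompressible flow in the lumen
  (ρ = 1060 kg/m³, μ = 0.003 Pa·s, 60 cm/s velocity inlet, 0 Pa outlet;
  Re = ρvL/μ = 2120 < 2300), P1/P1 FEM with PSPG/SUPG stabilization and
  Picard iteration, validated against the Poiseuille closed form.
* **FSI coupling** — one-way (traction → wall → flow) or two-way staggered
  coupling with harmonic lumen morphing.
* **Clearance rule** — CT landmark distances DD1/DD2/DD3 (signed
  craniocaudal projections; DD3 = DD1 − DD2), the <5 / 5–13 / >13 mm
  stratification, and the verdict *level VII is clearable when simulated
  deformation ≥ DD3*, including the critical-distance threshold.
* **Cohort statistics & synthetic data** — Welch t from summaries, one-way
  and Welch ANOVA, chi-square, Pearson correlation, Table-style cohort
  summaries, and a seeded synthetic cohort generator (truncated correlated
  bivariate-normal distances, negative-binomial node counts).

## Worked example

```r
library(etaplan)

# middle stratum (10 mm tissue) under a 2 N grasp
mesh <- build_tissue_artery_geometry(geometry_fixture("middle"))
sol  <- solve_static(solid_mesh(mesh), neo_hookean_material(),
                     linear_elastic_material(),
                     traction_load(force_magnitude = 2))
tissue_deformation_metric(sol)   # patch-average excursion, cm
#> [1] 0.8624  (attr max_tissue_cm: 1.2646)
artery_wall_stress(sol)          # mean wall von Mises, Pa
#> [1] 10518  (attr peak_Pa: 45460)

cpl <- run_fsi(mesh, load = traction_load(force_magnitude = 2))
cpl$flow$mean_mid_speed          # mid-lumen mean speed, cm/s
#> [1] 57.69
cpl$velocity_change_percent      # vs rigid-lumen baseline
#> [1] 0.116

# the clearance threshold from the reference deformation table
critical_distance(study_deformation_table(), c(0.01, 0.86, 1.63), 2)
#> [1] 13
```

So at 2 N the 10 mm-stratum tissue travels ≈ 0.86 cm while the group-mean
clavicle-to-artery gap is 0.86 cm — the middle stratum clears, the deep
(>13 mm) stratum does not, and the critical clavicle-to-innominate-artery
distance comes out at 13 mm. The coupled flow barely changes (≈ 0.1 %),
i.e. the traction is hemodynamically benign at these magnitudes.

A YAML-driven pipeline wraps the same calls (`run_case()`,
`run_sweep_tables()`, `classify_patients()`, `cohort_report()`); see
`inst/extdata/default_config.yaml` and the methods vignette
(`vignettes/methods.Rmd`) for the model assumptions, parameter meanings and
numerical choices.

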
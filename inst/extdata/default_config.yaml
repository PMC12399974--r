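# Example pipeline configuration (desk-scale resolutions).
geometry:
  tissue_thickness: 10      # mm; study strata are 5 / 10 / 20
  target_element_size: 2.5  # mm
materials:
  C1: 5000                  # Pa, Neo-Hookean deviatoric constant
  D1: 1.4e-07               # 1/Pa, volumetric compliance (K = 2/D1)
  youngs_modulus: 5.0e+06   # Pa, artery wall
  poisson_ratio: 0.49
traction:
  force_magnitude: 2        # N (study values 0.5, 1, 2)
flow:
  density: 1060             # kg/m^3
  dynamic_viscosity: 0.003  # Pa s
  inlet_mean_velocity: 0.60 # m/s
  outlet_pressure: 0        # Pa
  profile: parabolic
coupling:
  mode: one_way
  wall_displacement_tolerance: 1.0e-05
  max_outer_iterations: 20
sweep:
  thicknesses: [5, 10, 20]
  forces: [0.5, 1, 2]
stats:
  chisq_correct: false
  group_dd3: [0.01, 0.86, 1.63]  # cm, per-stratum mean clavicle-artery gap
synthetic:
  n_patients: 178
output_dir: etaplan-output
seed: 20250101
log_level: info
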
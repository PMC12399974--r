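# Pipeline orchestration: a single YAML configuration drives the solid,
# flow and coupled analyses, the study sweeps, patient classification and
# the synthetic-cohort statistics. All randomness flows from the root seed.

CONFIG_SECTIONS <- list(
  geometry = c("tissue_thickness", "slab_length", "slab_width",
               "artery_outer_diameter", "artery_wall_thickness",
               "lumen_length", "traction_patch_width",
               "traction_patch_length", "traction_patch_offset",
               "target_element_size", "bottom_margin", "support_collar",
               "areolar_gap", "dissection_window"),
  materials = c("C1", "D1", "youngs_modulus", "poisson_ratio"),
  traction = c("force_magnitude", "direction", "patch_tag"),
  flow = c("density", "dynamic_viscosity", "inlet_mean_velocity",
           "outlet_pressure", "profile"),
  coupling = c("mode", "wall_displacement_tolerance",
               "max_outer_iterations"),
  sweep = c("thicknesses", "forces"),
  stats = c("chisq_correct", "holm_adjust", "group_dd3"),
  synthetic = c("n_patients", "dd1_mean", "dd1_sd", "dd2_mean", "dd2_sd",
                "dd1_dd2_correlation", "dd1_range", "dd2_range", "dd3_range",
                "cln_mean", "cln_sd", "metastatic_mean", "recurrence_count",
                "female_fraction", "age_mean", "age_sd", "tumor_mean",
                "tumor_sd", "multiple_lesion_fraction",
                "total_thyroidectomy_fraction", "hashimoto_fraction"))
CONFIG_TOP <- c(names(CONFIG_SECTIONS), "output_dir", "seed", "log_level")

#' Read and validate a pipeline configuration
#'
#' The YAML file may contain the sections `geometry`, `materials`,
#' `traction`, `flow`, `coupling`, `sweep`, `stats`, `synthetic` plus
#' `output_dir`, `seed` and `log_level`. Unknown keys are rejected with the
#' offending path.
#'
#' @param path Path to a YAML file, or NULL for the packaged defaults.
#' @return An object of class `run_config`.
#' @export
read_run_config <- function(path = NULL) {
  raw <- if (is.null(path)) list() else yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  bad <- setdiff(names(raw), CONFIG_TOP)
  if (length(bad))
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
  for (sec in names(CONFIG_SECTIONS)) {
    extra <- setdiff(names(raw[[sec]]), CONFIG_SECTIONS[[sec]])
    if (length(extra))
      stop("unknown key(s) in section '", sec, "': ",
           paste(extra, collapse = ", "))
  }
  num <- function(x, d) if (is.null(x)) d else as.numeric(x)
  geom_raw <- lapply(as_list(raw$geometry), as.numeric)
  cpl_raw <- as_list(raw$coupling)
  if (!is.null(cpl_raw$wall_displacement_tolerance))
    cpl_raw$wall_displacement_tolerance <-
      as.numeric(cpl_raw$wall_displacement_tolerance)
  cfg <- list(
    geometry = do.call(geometry_params, geom_raw),
    tissue = neo_hookean_material(
      C1 = num(raw$materials$C1, 5000),
      D1 = num(raw$materials$D1, 1.4e-7)),
    artery = linear_elastic_material(
      youngs_modulus = num(raw$materials$youngs_modulus, 5e6),
      poisson_ratio = num(raw$materials$poisson_ratio, 0.49)),
    traction = do.call(traction_load, as_list(raw$traction)),
    blood = blood_properties(
      density = num(raw$flow$density, 1060),
      dynamic_viscosity = num(raw$flow$dynamic_viscosity, 0.003)),
    bc = flow_bc(
      inlet_mean_velocity = num(raw$flow$inlet_mean_velocity, 0.60),
      outlet_pressure = num(raw$flow$outlet_pressure, 0),
      profile = raw$flow$profile %||% "parabolic"),
    coupling = do.call(coupling_config, cpl_raw),
    sweep = list(
      thicknesses = raw$sweep$thicknesses %||% c(5, 10, 20),
      forces = raw$sweep$forces %||% c(0.5, 1, 2)),
    stats = list(
      chisq_correct = raw$stats$chisq_correct %||% FALSE,
      holm_adjust = raw$stats$holm_adjust %||% FALSE,
      group_dd3 = raw$stats$group_dd3 %||% c(0.01, 0.86, 1.63)),
    synthetic_raw = as_list(raw$synthetic),
    output_dir = raw$output_dir %||% "etaplan-output",
    seed = as.integer(raw$seed %||% 20250101L),
    log_level = raw$log_level %||% "info")
  structure(cfg, class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
as_list <- function(x) if (is.null(x)) list() else as.list(x)

log_msg <- function(cfg, ...) {
  if (!identical(cfg$log_level, "quiet")) message("[etaplan] ", ...)
}

prepare_output <- function(cfg, config_path = NULL) {
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  info <- list(seed = cfg$seed,
               package_version = as.character(utils::packageVersion("etaplan")),
               r_version = R.version.string,
               config_md5 = if (!is.null(config_path))
                 unname(tools::md5sum(config_path)) else NA_character_)
  jsonlite::write_json(info, file.path(cfg$output_dir, "run_info.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(cfg$output_dir)
}

#' Simulate one (thickness, force) case
#'
#' Runs the coupled analysis for the configured geometry and traction,
#' writes the solid and flow fields (VTK) and a metrics JSON, and returns
#' the metrics.
#'
#' @param config A [read_run_config()] object or YAML path.
#' @return List of metrics (deformation, wall stress, flow speeds),
#'   invisibly; also written to `output_dir/metrics.json`.
#' @export
run_case <- function(config = read_run_config()) {
  cfg <- if (inherits(config, "run_config")) config else
    read_run_config(config)
  prepare_output(cfg, if (is.character(config)) config else NULL)
  set.seed(cfg$seed)
  log_msg(cfg, "building geometry (thickness ",
          cfg$geometry$tissue_thickness, " mm)")
  mesh <- build_tissue_artery_geometry(cfg$geometry)
  cpl <- run_fsi(mesh, cfg$tissue, cfg$artery, cfg$traction, cfg$blood,
                 cfg$bc, cfg$coupling)
  metrics <- list(
    thickness_mm = cfg$geometry$tissue_thickness,
    force_N = cfg$traction$force_magnitude,
    deformation_cm = if (is.null(cpl$solid)) 0 else
      as.numeric(tissue_deformation_metric(cpl$solid)),
    max_deformation_cm = if (is.null(cpl$solid)) 0 else
      attr(tissue_deformation_metric(cpl$solid), "max_tissue_cm"),
    wall_stress_Pa = if (is.null(cpl$solid)) 0 else
      as.numeric(artery_wall_stress(cpl$solid)),
    mean_mid_speed_cm_s = cpl$flow$mean_mid_speed,
    baseline_speed_cm_s = cpl$baseline$mean_mid_speed,
    velocity_change_percent = cpl$velocity_change_percent,
    mesh_elements = nrow(mesh$elems),
    mesh_quality = as.numeric(mesh_quality(mesh)))
  jsonlite::write_json(metrics, file.path(cfg$output_dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(cpl$solid))
    write_solid_vtk(cpl$solid, file.path(cfg$output_dir, "solid.vtk"))
  write_flow_vtk(cpl$flow, file.path(cfg$output_dir, "flow.vtk"))
  write_profile_csv(cpl$flow, file.path(cfg$output_dir, "profile.csv"))
  log_msg(cfg, sprintf("case done: deformation %.3f cm, wall %.0f Pa, flow %+0.2f%%",
                       metrics$deformation_cm, metrics$wall_stress_Pa,
                       metrics$velocity_change_percent))
  invisible(metrics)
}

#' Run the study sweeps
#'
#' Produces the deformation/stress table and the traction-flow table over
#' the configured (thickness, force) grid, written as CSV.
#'
#' @param config A [read_run_config()] object or YAML path.
#' @param flow Also run the coupled flow sweep (slower).
#' @return List with `solid` and (optionally) `flow` data frames.
#' @export
run_sweep_tables <- function(config = read_run_config(), flow = TRUE) {
  cfg <- if (inherits(config, "run_config")) config else
    read_run_config(config)
  prepare_output(cfg, if (is.character(config)) config else NULL)
  set.seed(cfg$seed)
  ths <- cfg$sweep$thicknesses
  plist <- lapply(ths, function(th) {
    gp <- cfg$geometry
    gp$tissue_thickness <- th
    gp$target_element_size <- fixture_element_size(th)
    do.call(geometry_params, unclass(gp))
  })
  log_msg(cfg, "solid sweep over ", length(ths), " x ",
          length(cfg$sweep$forces), " grid")
  solid <- force_sweep(plist, cfg$sweep$forces, cfg$tissue, cfg$artery,
                       file = file.path(cfg$output_dir,
                                        "deformation_stress_sweep.csv"))
  out <- list(solid = solid)
  if (flow) {
    log_msg(cfg, "coupled flow sweep")
    out$flow <- traction_flow_sweep(
      ths, cfg$sweep$forces, cfg$coupling, cfg$tissue, cfg$artery,
      cfg$blood, cfg$bc,
      file = file.path(cfg$output_dir, "traction_flow_sweep.csv"))
  }
  invisible(out)
}

#' Classify patients for level-VII clearability
#'
#' Applies [classify_cohort()] to a landmark CSV using either a computed
#' sweep table or the reference deformation table, and reports the critical
#' clavicle-to-artery distance.
#'
#' @param landmarks_csv Path to the landmark CSV.
#' @param config A [read_run_config()] object or YAML path.
#' @param sweep_csv Optional CSV from [run_sweep_tables()] /
#'   [force_sweep()]; defaults to the reference table.
#' @return The per-patient report data frame (also written to
#'   `output_dir/clearance_report.csv`); the critical distance (mm) is in
#'   attribute `critical_distance_mm`.
#' @export
classify_patients <- function(landmarks_csv, config = read_run_config(),
                              sweep_csv = NULL) {
  cfg <- if (inherits(config, "run_config")) config else
    read_run_config(config)
  prepare_output(cfg, if (is.character(config)) config else NULL)
  tab <- if (is.null(sweep_csv)) study_deformation_table() else
    utils::read.csv(sweep_csv)
  report <- classify_cohort(landmarks_csv, tab)
  cd <- tryCatch(critical_distance(tab, cfg$stats$group_dd3, 2),
                 error = function(e) NA_real_)
  utils::write.csv(report, file.path(cfg$output_dir, "clearance_report.csv"),
                   row.names = FALSE)
  log_msg(cfg, nrow(report), " patients classified; critical distance ",
          as.numeric(cd), " mm")
  structure(report, critical_distance_mm = as.numeric(cd),
            errors = attr(report, "errors"))
}

#' Generate and summarize a synthetic cohort
#'
#' Draws the synthetic cohort from the configured generator (seeded by the
#' root seed), writes the cohort and landmark CSVs, and produces the
#' baseline/outcome-style summary with group tests.
#'
#' @param config A [read_run_config()] object or YAML path.
#' @param landmarks Also write a landmark CSV realizing the cohort's DD
#'   values.
#' @return List with `cohort`, `summary` and file paths, invisibly.
#' @export
cohort_report <- function(config = read_run_config(), landmarks = TRUE) {
  cfg <- if (inherits(config, "run_config")) config else
    read_run_config(config)
  prepare_output(cfg, if (is.character(config)) config else NULL)
  pars <- do.call(cohort_params, c(cfg$synthetic_raw, list(seed = cfg$seed)))
  cohort <- generate_cohort(pars)
  write_cohort_csv(cohort,
                   records_file = file.path(cfg$output_dir, "cohort.csv"),
                   dd_file = file.path(cfg$output_dir, "cohort_dd.csv"))
  lm_file <- NULL
  if (landmarks) {
    lm_file <- file.path(cfg$output_dir, "landmarks.csv")
    generate_landmark_cohort(cohort$dd, seed = cfg$seed, file = lm_file)
  }
  summ <- summarize_cohort(cohort$records)
  jsonlite::write_json(
    list(by_group = summ$by_group,
         tests = summ$tests[c("levene_p", "preferred")],
         anova_p = summ$tests$anova_cln$p,
         welch_p = summ$tests$welch_cln$p,
         chisq_sex_p = summ$tests$chisq_sex$p,
         n_total = summ$n_total),
    file.path(cfg$output_dir, "cohort_summary.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE, dataframe = "rows")
  log_msg(cfg, "cohort of ", summ$n_total, " patients summarized")
  invisible(list(cohort = cohort, summary = summ,
                 files = list(cohort = file.path(cfg$output_dir, "cohort.csv"),
                              landmarks = lm_file)))
}
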
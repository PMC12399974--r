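# CT landmark distances (DD1/DD2/DD3), stratification, and the
# deformation-versus-DD3 level-VII clearance rule.
#
# DD1: thyroid inferior pole -> innominate artery; DD2: thyroid inferior
# pole -> clavicular head; DD3 = DD1 - DD2 (clavicular head -> artery).
# All three are SIGNED projections onto the craniocaudal axis (caudal
# positive): DD3 is negative when the artery lies cranial to the clavicular
# head (structures already visible in the endoscopic field), which a
# Euclidean distance could not express.

#' A per-patient CT landmark set
#'
#' @param patient_id Identifier.
#' @param thyroid_inferior_pole,clavicular_head,innominate_artery 3D points,
#'   mm (image coordinates).
#' @param craniocaudal_axis Unit vector pointing caudally (normalized).
#' @return An object of class `landmark_set`.
#' @export
landmark_set <- function(patient_id, thyroid_inferior_pole, clavicular_head,
                         innominate_artery, craniocaudal_axis = c(0, 0, 1)) {
  pts <- rbind(thyroid_inferior_pole, clavicular_head, innominate_artery)
  if (!all(is.finite(pts))) stop("landmark points must be finite")
  na <- sqrt(sum(craniocaudal_axis^2))
  if (na == 0) stop("craniocaudal axis must be non-zero")
  structure(list(patient_id = patient_id,
                 thyroid_inferior_pole = as.numeric(thyroid_inferior_pole),
                 clavicular_head = as.numeric(clavicular_head),
                 innominate_artery = as.numeric(innominate_artery),
                 craniocaudal_axis = craniocaudal_axis / na),
            class = "landmark_set")
}

#' Compute DD1/DD2/DD3 from landmarks
#'
#' Signed craniocaudal projections (caudal positive) in cm;
#' `DD3 = DD1 - DD2` exactly.
#'
#' @param landmarks A [landmark_set()].
#' @return List of class `dd_measures` with `DD1`, `DD2`, `DD3` (cm).
#' @export
compute_dd <- function(landmarks) {
  stopifnot(inherits(landmarks, "landmark_set"))
  ax <- landmarks$craniocaudal_axis
  proj <- function(pt) sum((pt - landmarks$thyroid_inferior_pole) * ax) / 10
  dd1 <- proj(landmarks$innominate_artery)
  dd2 <- proj(landmarks$clavicular_head)
  structure(list(DD1 = dd1, DD2 = dd2, DD3 = dd1 - dd2,
                 patient_id = landmarks$patient_id),
            class = "dd_measures")
}

#' Assign the clavicle-to-artery stratum
#'
#' Strata by DD3 (equivalently tissue depth) in mm: `low` (< 5),
#' `middle` (5-13, both bounds inclusive), `large` (> 13). Values above
#' 20 mm are accepted but flagged via attribute `over_20mm` (the study's
#' deepest stratum was capped at 20 mm).
#'
#' @param dd3_or_thickness Depth(s), mm. Vectorized.
#' @return Factor with levels `low`, `middle`, `large`.
#' @export
assign_group <- function(dd3_or_thickness) {
  x <- as.numeric(dd3_or_thickness)
  if (any(!is.finite(x))) stop("inputs must be finite")
  g <- ifelse(x < 5, "low", ifelse(x <= 13, "middle", "large"))
  structure(factor(g, levels = c("low", "middle", "large")),
            over_20mm = x > 20)
}

#' Level-VII clearance verdict
#'
#' The study's decision rule: the level-VII compartment is deemed fully
#' clearable when the simulated tissue deformation reaches or exceeds DD3
#' (equality counts as cleared).
#'
#' @param deformation Simulated tissue deformation, cm.
#' @param dd3 Clavicle-to-artery distance, cm.
#' @param force Traction force the deformation was computed at, N.
#' @return Object of class `clearance_verdict` (vectorized data frame).
#' @export
clearance_verdict <- function(deformation, dd3, force) {
  stopifnot(all(is.finite(deformation)), all(is.finite(dd3)))
  out <- data.frame(cleared = deformation >= dd3, deformation = deformation,
                    dd3 = dd3, traction_force = force)
  class(out) <- c("clearance_verdict", "data.frame")
  out
}

#' Critical clavicle-to-artery distance
#'
#' The upper thickness bound (mm) of the deepest stratum whose clearance
#' verdict at the maximum traction force is "cleared". Strata upper bounds
#' are 5 / 13 / 20 mm; if no stratum clears, 0 is returned with attribute
#' `no_safe_stratum = TRUE`.
#'
#' @param deformation_table Data frame with `thickness_mm`, `force_N`,
#'   `deformation_cm` (e.g. from [force_sweep()]).
#' @param group_dd3 Numeric length-3 vector: mean DD3 (cm) of the low /
#'   middle / large strata.
#' @param max_force Force at which to evaluate, N.
#' @return Threshold in mm.
#' @export
critical_distance <- function(deformation_table, group_dd3, max_force = 2) {
  if (!nrow(deformation_table)) stop("empty deformation table")
  tab <- deformation_table[deformation_table$force_N == max_force, ]
  if (nrow(tab) < 3) stop("table does not cover all strata at max force")
  tab <- tab[order(tab$thickness_mm), ]
  upper <- c(5, 13, 20)
  cleared <- tab$deformation_cm[1:3] >= group_dd3
  if (!any(cleared)) return(structure(0, no_safe_stratum = TRUE))
  # deepest stratum cleared with all shallower strata cleared too
  k <- max(which(cumsum(!cleared) == 0))
  structure(upper[k], no_safe_stratum = FALSE)
}

#' Read a landmark CSV
#'
#' Schema: `patient_id,tip_x,tip_y,tip_z,clav_x,clav_y,clav_z,art_x,art_y,
#' art_z` in mm, header mandatory.
#'
#' @param file Path.
#' @param axis Craniocaudal axis (applied to all patients).
#' @return List of [landmark_set()]; malformed rows are collected in
#'   attribute `errors` (with line numbers) and skipped.
#' @export
read_landmarks <- function(file, axis = c(0, 0, 1)) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("patient_id", "tip_x", "tip_y", "tip_z", "clav_x", "clav_y",
            "clav_z", "art_x", "art_y", "art_z")
  if (!all(need %in% names(df)))
    stop("landmark CSV must have columns: ", paste(need, collapse = ","))
  sets <- list(); errs <- character(0)
  for (i in seq_len(nrow(df))) {
    r <- df[i, ]
    num <- suppressWarnings(as.numeric(r[need[-1]]))
    if (any(!is.finite(num))) {
      errs <- c(errs, sprintf("line %d: non-numeric coordinates", i + 1L))
      next
    }
    sets[[length(sets) + 1]] <- landmark_set(
      r$patient_id, num[1:3], num[4:6], num[7:9], axis)
  }
  structure(sets, errors = errs)
}

#' Write landmark sets as CSV
#'
#' @param landmarks List of [landmark_set()].
#' @param file Path.
#' @export
write_landmarks <- function(landmarks, file) {
  rows <- lapply(landmarks, function(l)
    data.frame(patient_id = l$patient_id,
               tip_x = l$thyroid_inferior_pole[1],
               tip_y = l$thyroid_inferior_pole[2],
               tip_z = l$thyroid_inferior_pole[3],
               clav_x = l$clavicular_head[1], clav_y = l$clavicular_head[2],
               clav_z = l$clavicular_head[3],
               art_x = l$innominate_artery[1], art_y = l$innominate_artery[2],
               art_z = l$innominate_artery[3]))
  utils::write.csv(do.call(rbind, rows), file, row.names = FALSE)
  invisible(file)
}

#' Classify a landmark cohort
#'
#' Computes DD measures, stratum and the clearance verdict at each study
#' force for every patient in a landmark CSV.
#'
#' @param landmark_file Path to a landmark CSV ([read_landmarks()] schema).
#' @param deformation_table Data frame `thickness_mm, force_N,
#'   deformation_cm` giving the per-stratum simulated deformation (rows for
#'   thicknesses 5/10/20 mm); defaults to the packaged study table.
#' @param forces Study forces, N.
#' @param axis Craniocaudal axis.
#' @return Data frame, one row per valid patient:
#'   `patient_id, dd1_cm, dd2_cm, dd3_cm, group, cleared_<force>N...`;
#'   parse errors in attribute `errors`.
#' @export
classify_cohort <- function(landmark_file,
                            deformation_table = study_deformation_table(),
                            forces = c(0.5, 1, 2), axis = c(0, 0, 1)) {
  sets <- read_landmarks(landmark_file, axis)
  out <- data.frame(patient_id = character(0), dd1_cm = numeric(0),
                    dd2_cm = numeric(0), dd3_cm = numeric(0),
                    group = character(0))
  for (f in forces) out[[sprintf("cleared_%gN", f)]] <- logical(0)
  for (l in sets) {
    dd <- compute_dd(l)
    grp <- assign_group(dd$DD3 * 10)
    th <- c(low = 5, middle = 10, large = 20)[as.character(grp)]
    row <- data.frame(patient_id = l$patient_id, dd1_cm = dd$DD1,
                      dd2_cm = dd$DD2, dd3_cm = dd$DD3,
                      group = as.character(grp))
    for (f in forces) {
      dt <- deformation_table[deformation_table$thickness_mm == th &
                                deformation_table$force_N == f, ]
      row[[sprintf("cleared_%gN", f)]] <- if (nrow(dt))
        dt$deformation_cm[1] >= dd$DD3 else NA
    }
    out <- rbind(out, row)
  }
  structure(out, errors = attr(sets, "errors"))
}

#' The study's reference deformation table
#'
#' Average tissue deformation (cm) by stratum-representative thickness at
#' the 1 N and 2 N traction forces, as reported for the reference
#' simulations; used as the default lookup when classifying patients without
#' re-running the solver (forces outside the table give NA verdicts).
#'
#' @return Data frame `thickness_mm, force_N, deformation_cm`.
#' @export
study_deformation_table <- function() {
  data.frame(
    thickness_mm = rep(c(5, 10, 20), each = 2),
    force_N = rep(c(1, 2), 3),
    deformation_cm = c(0.8, 1.8,
                       0.3, 0.96,
                       0.12, 0.47))
}
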
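# Synthetic cohort and landmark generation. The generator reproduces the
# statistical structure the analysis assumes: correlated truncated bivariate
# normal DD1/DD2 (DD3 = DD1 - DD2), strata from DD3, overdispersed
# negative-binomial lymph-node counts with binomial thinning for metastatic
# nodes, and recurrence confined to the configured strata.

#' Cohort generator parameters
#'
#' Defaults encode the study conditions: 178 patients; DD1 1.95 +- 0.7 cm,
#' DD2 1.42 +- 0.8 cm with correlation 0.571 (back-derived so that
#' Var(DD3) = 0.49, making all three printed SDs mutually consistent);
#' truncation to the printed ranges; per-stratum CLN counts 7.39 +- 3.35 /
#' 6.27 +- 2.98 / 5.12 +- 2.62; metastatic CLN 0.87 / 0.73 / 0.65 means;
#' recurrence preset `c(0, 0, 3)` (primary cohort; the external validation
#' series uses `c(0, 0, 7)`).
#'
#' @param n_patients Cohort size.
#' @param dd1_mean,dd1_sd,dd2_mean,dd2_sd DD distributions, cm.
#' @param dd1_dd2_correlation Correlation of DD1 and DD2.
#' @param dd1_range,dd2_range,dd3_range Truncation bounds, cm.
#' @param cln_mean,cln_sd Per-stratum total CLN count moments.
#' @param metastatic_mean Per-stratum metastatic CLN means.
#' @param recurrence_count Per-stratum recurrence counts.
#' @param female_fraction Per-stratum female fractions.
#' @param age_mean,age_sd Per-stratum age moments, years.
#' @param tumor_mean,tumor_sd Per-stratum largest-tumour diameter, cm.
#' @param multiple_lesion_fraction,total_thyroidectomy_fraction,
#'   hashimoto_fraction Per-stratum demographic fractions.
#' @param seed Integer seed; every draw flows from it.
#' @return An object of class `cohort_params`.
#' @export
cohort_params <- function(n_patients = 178,
                          dd1_mean = 1.95, dd1_sd = 0.7,
                          dd2_mean = 1.42, dd2_sd = 0.8,
                          dd1_dd2_correlation = 0.571,
                          dd1_range = c(0.038, 4.4),
                          dd2_range = c(0.05, 3.7),
                          dd3_range = c(-1.2, 2.1),
                          cln_mean = c(7.39, 6.27, 5.12),
                          cln_sd = c(3.35, 2.98, 2.62),
                          metastatic_mean = c(0.87, 0.73, 0.65),
                          recurrence_count = c(0, 0, 3),
                          female_fraction = c(0.9176, 0.8696, 0.875),
                          age_mean = c(35.34, 36.09, 38.13),
                          age_sd = c(8.87, 8.96, 7.83),
                          tumor_mean = c(0.89, 0.73, 0.88),
                          tumor_sd = c(0.39, 0.41, 0.52),
                          multiple_lesion_fraction = c(23, 20, 7) /
                            c(85, 69, 24),
                          total_thyroidectomy_fraction = c(9, 6, 3) /
                            c(85, 69, 24),
                          hashimoto_fraction = c(52, 42, 13) / c(85, 69, 24),
                          seed = 20250101L) {
  stopifnot(n_patients >= 1, dd1_sd > 0, dd2_sd > 0,
            abs(dd1_dd2_correlation) < 1,
            dd1_range[1] < dd1_range[2], dd2_range[1] < dd2_range[2],
            dd3_range[1] < dd3_range[2],
            all(cln_sd > 0), length(cln_mean) == 3)
  structure(as.list(environment()), class = "cohort_params")
}

#' Generate a synthetic patient cohort
#'
#' DD1/DD2 are drawn from the truncated correlated bivariate normal (joint
#' rejection on all three ranges), strata assigned from DD3 via
#' [assign_group()], total CLN counts from a moment-matched negative
#' binomial (Poisson fallback with a warning when sd^2 <= mean), metastatic
#' counts by binomial thinning (guaranteeing metastatic <= total), and
#' recurrence assigned only within the configured strata. Fully reproducible
#' from the seed.
#'
#' @param params A [cohort_params()].
#' @return List with `records` (patient data frame) and `dd`
#'   (per-patient DD1/DD2/DD3, cm).
#' @export
generate_cohort <- function(params = cohort_params()) {
  stopifnot(inherits(params, "cohort_params"))
  p <- params
  n <- p$n_patients
  lat <- calibrate_latent_dd(p)
  set.seed(p$seed)
  draw <- sample_truncated_dd(n, lat$mu, lat$sd, lat$rho, p)
  dd1 <- draw[, 1]; dd2 <- draw[, 2]
  dd3 <- dd1 - dd2
  stratum <- assign_group(dd3 * 10)
  gi <- as.integer(stratum)

  fallback <- FALSE
  draw_counts <- function(m, s, k) {
    if (s^2 > m) {
      stats::rnbinom(k, size = m^2 / (s^2 - m), mu = m)
    } else {
      fallback <<- TRUE
      stats::rpois(k, m)
    }
  }
  total_cln <- integer(n)
  for (g in 1:3) {
    idx <- which(gi == g)
    if (length(idx))
      total_cln[idx] <- draw_counts(p$cln_mean[g], p$cln_sd[g], length(idx))
  }
  if (fallback)
    warning("sd^2 <= mean for negative binomial; falling back to Poisson",
            call. = FALSE)
  thin_p <- pmin(1, p$metastatic_mean / p$cln_mean)[gi]
  metastatic_cln <- stats::rbinom(n, total_cln, thin_p)

  recurrence <- logical(n)
  for (g in 1:3) {
    idx <- which(gi == g)
    k <- min(p$recurrence_count[g], length(idx))
    if (k > 0) recurrence[sample(idx, k)] <- TRUE
  }

  records <- data.frame(
    patient_id = sprintf("P%04d", seq_len(n)),
    age = round(stats::rnorm(n, p$age_mean[gi], p$age_sd[gi]), 1),
    sex = ifelse(stats::runif(n) < p$female_fraction[gi], "female", "male"),
    lesion_count = ifelse(stats::runif(n) < p$multiple_lesion_fraction[gi],
                          "multiple", "single"),
    extent = ifelse(stats::runif(n) < p$total_thyroidectomy_fraction[gi],
                    "total+bilateral CND", "lobectomy+unilateral CND"),
    tumor_diameter = pmax(0.1, round(stats::rnorm(n, p$tumor_mean[gi],
                                                  p$tumor_sd[gi]), 2)),
    hashimoto = stats::runif(n) < p$hashimoto_fraction[gi],
    stratum = as.character(stratum),
    total_cln = total_cln,
    metastatic_cln = metastatic_cln,
    recurrence = recurrence,
    stringsAsFactors = FALSE)
  list(records = records,
       dd = data.frame(patient_id = records$patient_id,
                       DD1 = dd1, DD2 = dd2, DD3 = dd3))
}

# Joint rejection sampling of (DD1, DD2) from a bivariate normal truncated
# to the configured DD1/DD2/DD3 ranges.
sample_truncated_dd <- function(n, mu, sdv, rho, p) {
  sigma <- matrix(c(sdv[1]^2, rho * sdv[1] * sdv[2],
                    rho * sdv[1] * sdv[2], sdv[2]^2), 2, 2)
  out <- matrix(numeric(0), 0, 2)
  while (nrow(out) < n) {
    draw <- MASS::mvrnorm(max(2 * n, 256), mu, sigma)
    d3 <- draw[, 1] - draw[, 2]
    keep <- draw[, 1] >= p$dd1_range[1] & draw[, 1] <= p$dd1_range[2] &
            draw[, 2] >= p$dd2_range[1] & draw[, 2] <= p$dd2_range[2] &
            d3 >= p$dd3_range[1] & d3 <= p$dd3_range[2]
    out <- rbind(out, draw[keep, , drop = FALSE])
  }
  out[seq_len(n), , drop = FALSE]
}

# The configured moments describe the observable (truncated) distances, so
# the latent normal parameters are calibrated by a deterministic Monte-Carlo
# fixed point: shift means, rescale sds and nudge the correlation until the
# truncated sample reproduces the targets.
calibrate_latent_dd <- function(p, n_cal = 20000, iters = 6) {
  mu <- c(p$dd1_mean, p$dd2_mean)
  sdv <- c(p$dd1_sd, p$dd2_sd)
  rho <- p$dd1_dd2_correlation
  tm <- c(p$dd1_mean, p$dd2_mean)
  ts <- c(p$dd1_sd, p$dd2_sd)
  for (k in seq_len(iters)) {
    set.seed(p$seed + 1000L + k)
    s <- sample_truncated_dd(n_cal, mu, sdv, rho, p)
    mu <- mu + (tm - colMeans(s))
    sdv <- sdv * pmin(2, pmax(0.5, ts / apply(s, 2, stats::sd)))
    rho <- min(0.99, max(-0.99,
                         rho + (p$dd1_dd2_correlation - stats::cor(s[, 1],
                                                                   s[, 2]))))
  }
  list(mu = mu, sd = sdv, rho = rho)
}

#' Generate a landmark set realizing given DD measures
#'
#' Inverse of [compute_dd()]: builds three CT-style points whose signed
#' craniocaudal projections reproduce the requested DD values exactly;
#' jitter is added orthogonally to the axis only, so the projections are
#' unaffected.
#'
#' @param dd List/row with `DD1`, `DD2` (cm; `DD3` implied) and optionally
#'   `patient_id`.
#' @param seed Integer seed for the orthogonal jitter.
#' @param axis Craniocaudal axis.
#' @param jitter_mm Magnitude of the in-plane jitter, mm.
#' @return A [landmark_set()].
#' @export
generate_landmarks <- function(dd, seed = 1L, axis = c(0, 0, 1),
                               jitter_mm = 5) {
  set.seed(seed)
  ax <- axis / sqrt(sum(axis^2))
  # orthonormal in-plane basis
  ref <- if (abs(ax[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * ax) * ax; e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(ax[2] * e1[3] - ax[3] * e1[2],
          ax[3] * e1[1] - ax[1] * e1[3],
          ax[1] * e1[2] - ax[2] * e1[1])
  jit <- function() (stats::runif(1, -1, 1) * e1 +
                     stats::runif(1, -1, 1) * e2) * jitter_mm
  tip <- c(100, 100, 100) + jit()
  clav <- tip + ax * dd$DD2 * 10 + jit()
  art <- tip + ax * dd$DD1 * 10 + jit()
  landmark_set(if (!is.null(dd$patient_id)) dd$patient_id else "synthetic",
               tip, clav, art, ax)
}

#' Landmark sets for a whole DD cohort
#'
#' @param dd Data frame with `patient_id`, `DD1`, `DD2` (from
#'   [generate_cohort()]).
#' @param seed Base seed (per-patient seeds derived from it).
#' @param file Optional landmark CSV output path.
#' @return List of [landmark_set()].
#' @export
generate_landmark_cohort <- function(dd, seed = 1L, file = NULL) {
  sets <- lapply(seq_len(nrow(dd)), function(i)
    generate_landmarks(dd[i, ], seed = seed + i))
  if (!is.null(file)) write_landmarks(sets, file)
  sets
}

#' Geometry preset for a stratum
#'
#' Representative tissue thickness per stratum (5 / 10 / 20 mm for low /
#' middle / large) at the desk-scale fixture resolution (three element
#' layers through thin plates, 2.5 mm otherwise).
#'
#' @param stratum `"low"`, `"middle"` or `"large"` (or a `GroupLabel`
#'   factor level).
#' @return A [geometry_params()].
#' @export
geometry_fixture <- function(stratum) {
  th <- switch(as.character(stratum), low = 5, middle = 10, large = 20,
               stop("unknown stratum: ", stratum))
  geometry_params(tissue_thickness = th,
                  target_element_size = fixture_element_size(th))
}

#' Write a cohort as CSV
#'
#' @param cohort Result of [generate_cohort()].
#' @param records_file,dd_file Output paths (either may be NULL).
#' @export
write_cohort_csv <- function(cohort, records_file = NULL, dd_file = NULL) {
  if (!is.null(records_file))
    utils::write.csv(cohort$records, records_file, row.names = FALSE)
  if (!is.null(dd_file))
    utils::write.csv(cohort$dd, dd_file, row.names = FALSE)
  invisible(cohort)
}
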
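test_that("the generator is bitwise reproducible from its seed", {
  a <- generate_cohort(cohort_params(n_patients = 100, seed = 12))
  b <- generate_cohort(cohort_params(n_patients = 100, seed = 12))
  expect_identical(a, b)
  c3 <- generate_cohort(cohort_params(n_patients = 100, seed = 13))
  expect_false(identical(a$records$total_cln, c3$records$total_cln))
})

test_that("large-sample moments recover the calibration targets", {
  big <- cached("big_cohort",
                generate_cohort(cohort_params(n_patients = 10000, seed = 99)))
  dd <- big$dd
  n <- nrow(dd)
  # 3-SE recovery (truncation keeps the shifts well inside these bands)
  expect_lt(abs(mean(dd$DD1) - 1.95), 3 * 0.7 / sqrt(n) + 0.02)
  expect_lt(abs(mean(dd$DD2) - 1.42), 3 * 0.8 / sqrt(n) + 0.02)
  expect_lt(abs(sd(dd$DD3) - 0.7), 0.03)
  expect_lt(abs(mean(dd$DD3) - 0.53), 0.03)
  # per-stratum CLN means
  rec <- big$records
  for (g in c("low", "middle", "large")) {
    target <- c(low = 7.39, middle = 6.27, large = 5.12)[[g]]
    sdg <- c(low = 3.35, middle = 2.98, large = 2.62)[[g]]
    x <- rec$total_cln[rec$stratum == g]
    expect_lt(abs(mean(x) - target), 3 * sdg / sqrt(length(x)) + 0.05)
  }
})

test_that("stratum proportions follow the study split", {
  big <- cached("big_cohort",
                generate_cohort(cohort_params(n_patients = 10000, seed = 99)))
  prop <- table(big$records$stratum)[c("low", "middle", "large")] / 10000
  target <- c(85, 69, 24) / 178
  se <- sqrt(target * (1 - target) / 10000)
  expect_true(all(abs(prop - target) < 3 * se + 0.03))
})

test_that("structural constraints hold for every record", {
  co <- generate_cohort(cohort_params(n_patients = 2000, seed = 5))
  rec <- co$records
  expect_true(all(rec$metastatic_cln <= rec$total_cln))
  expect_true(all(rec$total_cln >= 0))
  expect_true(all(co$dd$DD3 >= -1.2 & co$dd$DD3 <= 2.1))
  expect_true(all(co$dd$DD1 >= 0.038 & co$dd$DD1 <= 4.4))
  # recurrence confined to the configured stratum
  expect_true(all(rec$stratum[rec$recurrence] == "large"))
  expect_equal(sum(rec$recurrence), 3)
  alt <- generate_cohort(cohort_params(n_patients = 2000, seed = 5,
                                       recurrence_count = c(0, 0, 7)))
  expect_equal(sum(alt$records$recurrence), 7)
})

test_that("Poisson fallback engages when overdispersion is infeasible", {
  expect_warning(
    generate_cohort(cohort_params(n_patients = 50, seed = 3,
                                  cln_mean = c(5, 5, 5),
                                  cln_sd = c(1, 1, 1))),
    "Poisson")
})

test_that("orthogonal jitter never leaks into the projections", {
  dd <- list(DD1 = 1.95, DD2 = 1.42, patient_id = "j")
  for (s in 1:5) {
    lm <- generate_landmarks(dd, seed = s, jitter_mm = 5)
    got <- compute_dd(lm)
    expect_equal(got$DD1, 1.95, tolerance = 1e-9)
    expect_equal(got$DD3, 0.53, tolerance = 1e-9)
  }
})

test_that("geometry fixtures map strata to the study thicknesses", {
  expect_equal(geometry_fixture("low")$tissue_thickness, 5)
  expect_equal(geometry_fixture("middle")$tissue_thickness, 10)
  expect_equal(geometry_fixture("large")$tissue_thickness, 20)
  expect_error(geometry_fixture("huge"), "stratum")
})
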
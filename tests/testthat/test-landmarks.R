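test_that("DD measures are signed axial projections", {
  # colinear points along the default axis
  lm <- landmark_set("p1", c(0, 0, 0), c(0, 0, 14.2), c(0, 0, 19.5))
  dd <- compute_dd(lm)
  expect_equal(dd$DD1, 1.95)
  expect_equal(dd$DD2, 1.42)
  expect_equal(dd$DD3, 0.53)
  # artery cranial to the clavicular head: negative DD3
  lm2 <- landmark_set("p2", c(0, 0, 0), c(0, 0, 20), c(0, 0, 12))
  expect_lt(compute_dd(lm2)$DD3, 0)
  # coincident landmarks
  lm3 <- landmark_set("p3", c(1, 2, 3), c(1, 2, 3), c(1, 2, 3))
  expect_equal(unlist(compute_dd(lm3)[c("DD1", "DD2", "DD3")]),
               c(DD1 = 0, DD2 = 0, DD3 = 0))
  expect_error(landmark_set("p", c(0, 0, 0), c(0, 0, 1), c(0, 0, 2),
                            craniocaudal_axis = c(0, 0, 0)), "axis")
  expect_error(landmark_set("p", c(0, 0, NA), c(0, 0, 1), c(0, 0, 2)),
               "finite")
})

test_that("DD3 identity holds for arbitrary landmark sets", {
  with_seed(11, {
    for (rep in 1:25) {
      ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
      lm <- landmark_set("x", rnorm(3, 0, 30), rnorm(3, 0, 30),
                         rnorm(3, 0, 30), ax)
      dd <- compute_dd(lm)
      expect_equal(dd$DD3, dd$DD1 - dd$DD2, tolerance = 1e-12)
    }
  })
})

test_that("stratum assignment partitions the depth axis", {
  expect_equal(as.character(assign_group(c(4, 8, 16))),
               c("low", "middle", "large"))
  expect_equal(as.character(assign_group(c(5, 13))), c("middle", "middle"))
  expect_equal(as.character(assign_group(-2)), "low")
  flag <- attr(assign_group(c(15, 25)), "over_20mm")
  expect_equal(flag, c(FALSE, TRUE))
  with_seed(3, {
    x <- runif(500, -20, 30)
    g <- assign_group(x)
    expect_false(any(is.na(g)))
    expect_equal(nlevels(g), 3)
  })
  expect_error(assign_group(NA), "finite")
})

test_that("clearance rule: deformation >= DD3, equality included", {
  # printed worked example: 2 N deformations vs group-mean DD3
  v <- clearance_verdict(c(1.8, 0.96, 0.47), c(0.01, 0.86, 1.63), 2)
  expect_equal(v$cleared, c(TRUE, TRUE, FALSE))
  expect_true(clearance_verdict(0, -0.5, 1)$cleared)   # negative DD3
  expect_true(clearance_verdict(0.8, 0.8, 1)$cleared)  # boundary convention
  # monotone in deformation, anti-monotone in dd3
  with_seed(5, {
    dd3 <- runif(20, -1, 2)
    d_lo <- clearance_verdict(0.3, dd3, 1)$cleared
    d_hi <- clearance_verdict(0.9, dd3, 1)$cleared
    expect_true(all(d_hi >= d_lo))
  })
})

test_that("critical distance reproduces the 13 mm threshold", {
  tab <- data.frame(thickness_mm = c(5, 10, 20), force_N = 2,
                    deformation_cm = c(1.8, 0.96, 0.47))
  expect_equal(as.numeric(critical_distance(tab, c(0.01, 0.86, 1.63), 2)), 13)
  # all strata cleared -> top of the deepest stratum
  tab2 <- tab; tab2$deformation_cm <- c(3, 3, 3)
  expect_equal(as.numeric(critical_distance(tab2, c(0.01, 0.86, 1.63), 2)), 20)
  # none cleared -> 0 with flag
  tab3 <- tab; tab3$deformation_cm <- c(0, 0, 0)
  cd <- critical_distance(tab3, c(0.5, 0.86, 1.63), 2)
  expect_equal(as.numeric(cd), 0)
  expect_true(attr(cd, "no_safe_stratum"))
  expect_error(critical_distance(tab[0, ], c(0, 0, 0), 2), "empty")
})

test_that("landmark CSV IO collects malformed rows and keeps valid ones", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("patient_id,tip_x,tip_y,tip_z,clav_x,clav_y,clav_z,art_x,art_y,art_z",
               "A,0,0,0,0,0,14.2,0,0,19.5",
               "B,0,0,0,bad,0,10,0,0,5",
               "C,0,0,0,0,0,5,0,0,2"), f)
  sets <- read_landmarks(f)
  expect_length(sets, 2)
  expect_length(attr(sets, "errors"), 1)
  expect_match(attr(sets, "errors"), "line 3")
})

test_that("cohort classification is a faithful batch driver", {
  # empty file -> empty report, no error
  f0 <- tempfile(fileext = ".csv")
  writeLines("patient_id,tip_x,tip_y,tip_z,clav_x,clav_y,clav_z,art_x,art_y,art_z",
             f0)
  expect_equal(nrow(classify_cohort(f0)), 0)
  # three patients spanning the strata, built by inverting compute_dd
  dds <- data.frame(patient_id = c("low", "middle", "large"),
                    DD1 = c(1.0, 2.0, 3.0), DD2 = c(0.9, 1.2, 1.2))
  f <- tempfile(fileext = ".csv")
  generate_landmark_cohort(dds, seed = 2, file = f)
  rep <- classify_cohort(f)
  expect_equal(rep$group, c("low", "middle", "large"))
  expect_equal(rep$dd3_cm, dds$DD1 - dds$DD2, tolerance = 1e-9)
  # verdicts at 2 N against the reference deformation table
  expect_equal(rep$cleared_2N, c(TRUE, TRUE, FALSE))
})

test_that("landmark generation inverts the measurement to 1e-9", {
  with_seed(9, {
    for (rep in 1:10) {
      dd <- list(DD1 = runif(1, -1, 4), DD2 = runif(1, 0, 3))
      lm <- generate_landmarks(dd, seed = rep, jitter_mm = 5)
      got <- compute_dd(lm)
      expect_equal(got$DD1, dd$DD1, tolerance = 1e-9)
      expect_equal(got$DD2, dd$DD2, tolerance = 1e-9)
    }
  })
})
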
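test_that("Welch t from summaries matches its closed form and edge cases", {
  a <- group_summary(30, 5, 1)
  expect_equal(welch_t_from_summary(a, a)$t, 0)
  expect_equal(welch_t_from_summary(a, a)$p, 1)
  w <- welch_t_from_summary(group_summary(85, 7.39, 3.35),
                            group_summary(24, 5.12, 2.62))
  expect_equal(w$t, 3.5109, tolerance = 1e-4)
  expect_equal(w$p, 0.001, tolerance = 0.1)
  z <- welch_t_from_summary(group_summary(5, 1, 0), group_summary(5, 2, 0))
  expect_true(z$degenerate)
  expect_error(welch_t_from_summary(group_summary(1, 0, 0), a), "n >= 2")
})

test_that("summary-based Welch equals raw-data Welch exactly", {
  # construct raw samples with exactly the requested moments
  exact_sample <- function(n, m, s) {
    x <- scale(rnorm(n))
    as.numeric(x * s + m)
  }
  with_seed(21, {
    for (rep in 1:5) {
      n1 <- sample(5:40, 1); n2 <- sample(5:40, 1)
      m1 <- rnorm(1); m2 <- rnorm(1); s1 <- runif(1, .5, 3); s2 <- runif(1, .5, 3)
      x <- exact_sample(n1, m1, s1); y <- exact_sample(n2, m2, s2)
      w <- welch_t_from_summary(group_summary(n1, mean(x), sd(x)),
                                group_summary(n2, mean(y), sd(y)))
      tt <- t.test(x, y)
      expect_equal(w$t, unname(tt$statistic), tolerance = 1e-10)
      expect_equal(w$df, unname(tt$parameter), tolerance = 1e-10)
      expect_equal(w$p, tt$p.value, tolerance = 1e-10)
    }
  })
})

test_that("two-group ANOVA obeys the F = t^2 identity", {
  with_seed(31, {
    x <- rnorm(12); y <- rnorm(15, 0.5)
    a <- one_way_anova(list(x, y))
    tt <- t.test(x, y, var.equal = TRUE)
    expect_equal(a$F, unname(tt$statistic)^2, tolerance = 1e-10)
    expect_equal(a$p, tt$p.value, tolerance = 1e-10)
    wa <- welch_anova(list(x, y))
    tw <- t.test(x, y)
    expect_equal(wa$F, unname(tw$statistic)^2, tolerance = 1e-10)
    expect_equal(wa$p, tw$p.value, tolerance = 1e-10)
  })
})

test_that("ANOVA has power against a one-SD shift", {
  with_seed(41, {
    rejections <- mean(replicate(200, {
      g <- list(rnorm(30), rnorm(30), rnorm(30, 1))
      one_way_anova(g)$p < 0.05
    }))
    expect_gt(rejections, 0.9)
  })
})

test_that("degenerate groups follow the stated conventions", {
  same <- list(rep(2, 5), rep(2, 6))
  expect_equal(one_way_anova(same)$p, 1)
  expect_equal(welch_anova(same)$p, 1)
  expect_warning(welch_anova(list(rep(1, 5), rnorm(5))), "zero variance")
  expect_error(one_way_anova(list(rnorm(5))), "groups")
  expect_error(one_way_anova(list(rnorm(5), 1)), "n >= 2")
})

test_that("chi-square matches the Pearson formula and a permutation oracle", {
  # independence: table proportional to the outer product of its margins
  ind <- outer(c(2, 3), c(1, 4)) * 5
  r0 <- chi_square_test(ind)
  expect_equal(r0$chisq, 0, tolerance = 1e-12)
  expect_equal(r0$p, 1)
  # study baseline: sex x stratum counts are comparable across strata
  tab <- matrix(c(7, 9, 3, 78, 60, 21), 2, 3, byrow = TRUE)
  r <- chi_square_test(tab)
  expect_equal(r$df, 2)
  expect_equal(r$chisq, chisq_stat_manual(tab), tolerance = 1e-12)
  expect_gt(r$p, 0.05)
  # permutation cross-check on a 2x2
  t22 <- matrix(c(12, 5, 7, 15), 2, 2)
  r22 <- chi_square_test(t22)
  pp <- chisq_perm_p(t22, n_draws = 1e5, seed = 4)
  se <- sqrt(pp * (1 - pp) / 1e5)
  expect_lt(abs(r22$p - pp), max(3 * se, 0.01))
  # invariance under row/column permutation
  perm <- tab[c(2, 1), c(3, 1, 2)]
  expect_equal(chi_square_test(perm)$chisq, r$chisq, tolerance = 1e-12)
  expect_error(chi_square_test(matrix(c(0, 0, 1, 2), 2)), "marginal")
  expect_error(chi_square_test(matrix(1:2, 2, 1)), "2x2")
})

test_that("Pearson correlation matches the printed force-stress triples", {
  expect_equal(pearson_r(1:5, 2 * (1:5))$r, 1)
  r10 <- pearson_r(c(0.5, 1, 2), c(2000, 4000, 7000))
  expect_equal(round(r10$r, 2), 1.00)
  expect_equal(r10$r, 0.9971, tolerance = 1e-4)
  r5 <- pearson_r(c(0.5, 1, 2), c(2500, 5000, 8200))
  expect_equal(round(r5$r, 2), 0.99)
  # affine invariance (sign-aware)
  with_seed(51, {
    x <- rnorm(10); y <- rnorm(10)
    base <- pearson_r(x, y)$r
    expect_equal(pearson_r(2 * x + 3, y)$r, base, tolerance = 1e-12)
    expect_equal(pearson_r(-x, y)$r, -base, tolerance = 1e-12)
  })
  expect_error(pearson_r(1:3, rep(1, 3)), "variance")
  expect_error(pearson_r(1:3, 1:4), "length")
})

test_that("cohort summaries recompute their own percentages and flags", {
  co <- with_seed(61, generate_cohort(cohort_params(n_patients = 178,
                                                    seed = 61)))
  s <- summarize_cohort(co$records)
  expect_equal(s$n_total, 178)
  for (i in seq_len(nrow(s$by_group))) {
    g <- s$by_group[i, ]
    expect_equal(g$female_pct, 100 * g$female / g$n, tolerance = 1e-12)
  }
  expect_true(s$tests$preferred %in% c("anova", "welch"))
  expect_equal(sum(s$by_group$n), 178)
  # single-patient cohort: values echoed, SD flagged undefined
  one <- co$records[1, ]
  s1 <- summarize_cohort(one)
  expect_equal(s1$by_group$n[s1$by_group$stratum == one$stratum], 1)
  expect_true(s1$tests$skipped)
  expect_match(s1$by_group$tumor_diameter[s1$by_group$stratum == one$stratum],
               "sd undefined")
  expect_error(summarize_cohort(co$records[0, ]), "empty")
})
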
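# Group-comparison statistics for the clinical cohort: Welch t from summary
# statistics, one-way and Welch ANOVA, Pearson chi-square, Pearson
# correlation, and Table-style cohort summaries.

#' Group summary statistics
#'
#' @param n Group size.
#' @param mean Group mean.
#' @param sd Group standard deviation (>= 0).
#' @return An object of class `group_summary`.
#' @export
group_summary <- function(n, mean, sd) {
  if (n < 1 || sd < 0) stop("need n >= 1 and sd >= 0")
  structure(list(n = n, mean = mean, sd = sd), class = "group_summary")
}

#' Welch two-sample t test from summary statistics
#'
#' Welch statistic with Satterthwaite degrees of freedom, computed directly
#' from (n, mean, sd) pairs; identical to `t.test(x, y)` on raw data with
#' those summaries.
#'
#' @param a,b [group_summary()] objects (each n >= 2).
#' @return List with `t`, `df`, `p` (two-sided). When both sds are zero:
#'   equal means give p = 1 by convention; unequal means set the
#'   `degenerate` flag with p = 0.
#' @export
welch_t_from_summary <- function(a, b) {
  stopifnot(inherits(a, "group_summary"), inherits(b, "group_summary"))
  if (a$n < 2 || b$n < 2) stop("both groups need n >= 2")
  va <- a$sd^2 / a$n; vb <- b$sd^2 / b$n
  if (va + vb == 0) {
    if (a$mean == b$mean)
      return(list(t = 0, df = a$n + b$n - 2, p = 1, degenerate = FALSE))
    return(list(t = Inf, df = a$n + b$n - 2, p = 0, degenerate = TRUE))
  }
  t <- (a$mean - b$mean) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (a$n - 1) + vb^2 / (b$n - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df), degenerate = FALSE)
}

#' One-way (classical) ANOVA
#'
#' Classical equal-variance F test across groups (wraps
#' `stats::oneway.test(var.equal = TRUE)`).
#'
#' @param groups List of numeric vectors (>= 2 groups, each n >= 2).
#' @return List with `F`, `df1`, `df2`, `p`.
#' @export
one_way_anova <- function(groups) {
  check_groups(groups)
  if (all_identical(groups)) return(list(F = 0, df1 = length(groups) - 1,
                                         df2 = sum(lengths(groups)) -
                                           length(groups), p = 1))
  dat <- stack_groups(groups)
  ft <- stats::oneway.test(value ~ group, data = dat, var.equal = TRUE)
  list(F = unname(ft$statistic), df1 = unname(ft$parameter[1]),
       df2 = unname(ft$parameter[2]), p = unname(ft$p.value))
}

#' Welch heteroscedastic ANOVA
#'
#' Welch's F* with adjusted denominator degrees of freedom (wraps
#' `stats::oneway.test(var.equal = FALSE)`); groups with zero variance are
#' guarded by the all-identical convention.
#'
#' @param groups List of numeric vectors (>= 2 groups, each n >= 2).
#' @return List with `F`, `df1`, `df2`, `p`.
#' @export
welch_anova <- function(groups) {
  check_groups(groups)
  if (all_identical(groups)) return(list(F = 0, df1 = length(groups) - 1,
                                         df2 = Inf, p = 1))
  if (any(vapply(groups, stats::var, numeric(1)) == 0))
    warning("a group has zero variance; Welch ANOVA is unstable")
  dat <- stack_groups(groups)
  ft <- stats::oneway.test(value ~ group, data = dat, var.equal = FALSE)
  list(F = unname(ft$statistic), df1 = unname(ft$parameter[1]),
       df2 = unname(ft$parameter[2]), p = unname(ft$p.value))
}

check_groups <- function(groups) {
  if (!is.list(groups) || length(groups) < 2) stop("need >= 2 groups")
  if (any(lengths(groups) < 2)) stop("each group needs n >= 2")
  invisible(TRUE)
}

all_identical <- function(groups) {
  v <- unlist(groups)
  all(v == v[1])
}

stack_groups <- function(groups) {
  data.frame(value = unlist(groups),
             group = factor(rep(seq_along(groups), lengths(groups))))
}

#' Pearson chi-square test of independence
#'
#' Without continuity correction by default (switchable), df = (r-1)(c-1)
#' (wraps `stats::chisq.test`).
#'
#' @param contingency Matrix of non-negative counts (at least 2x2).
#' @param correct Apply Yates continuity correction (2x2 only).
#' @return List with `chisq`, `df`, `p`.
#' @export
chi_square_test <- function(contingency, correct = FALSE) {
  m <- as.matrix(contingency)
  if (nrow(m) < 2 || ncol(m) < 2) stop("need at least a 2x2 table")
  if (any(m < 0) || any(m != round(m))) stop("counts must be non-negative integers")
  rs <- rowSums(m); cs <- colSums(m)
  if (any(rs == 0)) stop("zero marginal in row ", which(rs == 0)[1])
  if (any(cs == 0)) stop("zero marginal in column ", which(cs == 0)[1])
  ct <- suppressWarnings(stats::chisq.test(m, correct = correct))
  list(chisq = unname(ct$statistic), df = unname(ct$parameter),
       p = unname(ct$p.value))
}

#' Pearson correlation with t-based p-value
#'
#' @param x,y Numeric vectors, equal length >= 3, non-zero variance.
#' @return List with `r` and two-sided `p`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3)
    stop("need equal lengths >= 3")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("zero variance in input")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = unname(ct$p.value))
}

#' Cohort summary in the style of the clinical baseline/outcome tables
#'
#' Per-stratum n, demographic counts with percentages, mean +- SD of tumour
#' diameter and central-lymph-node (CLN) counts, and recurrence counts, plus
#' the between-stratum tests (classical and Welch ANOVA for CLN counts,
#' chi-square for sex); the Welch result is preferred when Levene's test
#' (median-centred) indicates heteroscedasticity.
#'
#' @param records Cohort data frame (as from [generate_cohort()]).
#' @return List with `by_group` (data frame), `tests` (list), and `n_total`.
#' @export
summarize_cohort <- function(records) {
  if (!nrow(records)) stop("empty cohort")
  records$stratum <- factor(records$stratum,
                            levels = c("low", "middle", "large"))
  groups <- split(records, records$stratum, drop = FALSE)
  msd <- function(x) if (length(x) >= 2)
    sprintf("%.2f ± %.2f", mean(x), stats::sd(x)) else
      sprintf("%.2f (sd undefined)", if (length(x)) mean(x) else NA)
  by_group <- do.call(rbind, lapply(names(groups), function(g) {
    d <- groups[[g]]
    nf <- sum(d$sex == "female")
    data.frame(
      stratum = g, n = nrow(d),
      age_mean = if (nrow(d)) mean(d$age) else NA_real_,
      age_sd = if (nrow(d) >= 2) stats::sd(d$age) else NA_real_,
      female = nf,
      female_pct = if (nrow(d)) 100 * nf / nrow(d) else NA_real_,
      tumor_diameter = msd(d$tumor_diameter),
      total_cln_mean = if (nrow(d)) mean(d$total_cln) else NA_real_,
      total_cln_sd = if (nrow(d) >= 2) stats::sd(d$total_cln) else NA_real_,
      metastatic_cln_mean = if (nrow(d)) mean(d$metastatic_cln) else NA_real_,
      recurrence = sum(d$recurrence))
  }))
  nonempty <- vapply(groups, nrow, integer(1)) >= 2
  tests <- list(skipped = !all(nonempty))
  if (all(nonempty)) {
    cln <- lapply(groups, `[[`, "total_cln")
    tests$anova_cln <- one_way_anova(cln)
    tests$welch_cln <- welch_anova(cln)
    tests$levene_p <- levene_p(cln)
    tests$preferred <- if (tests$levene_p < 0.05) "welch" else "anova"
    sexes <- table(records$sex, records$stratum)
    tests$chisq_sex <- tryCatch(chi_square_test(sexes),
                                error = function(e) NULL)
  }
  list(by_group = by_group, tests = tests, n_total = nrow(records))
}

# Brown-Forsythe variant of Levene's test (median-centred), used only to
# pick between classical and Welch ANOVA.
levene_p <- function(groups) {
  z <- lapply(groups, function(x) abs(x - stats::median(x)))
  one_way_anova(z)$p
}
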
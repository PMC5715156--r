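test_that("sire-pool expectations apportion the cohort by sire origin", {
  e <- expected_f1_counts(34, 5, 21)
  expect_equal(unname(round(e, 2)), c(6.54, 27.46))
  expect_equal(unname(expected_f1_counts(10, 0, 21)), c(0, 10))
  expect_equal(unname(expected_f1_counts(26, 5, 21)), c(5, 21))
  expect_error(expected_f1_counts(10, 0, 0), "empty")
  # counts always sum to the cohort size
  set.seed(3)
  for (i in 1:10) {
    n <- sample(10:60, 1)
    e <- expected_f1_counts(n, sample(0:9, 1), sample(1:30, 1))
    expect_equal(sum(e), n)
  }
})

test_that("random-mating expectations for the following cohort", {
  e <- expected_next_cohort_hybrids(47, 13, 32)
  expect_equal(round(e[["exp_hybrid"]], 2), 23.23)
  expect_equal(unname(expected_next_cohort_hybrids(30, 7, 0)), c(30, 0))
  expect_equal(unname(expected_next_cohort_hybrids(100, 1, 1)), c(75, 25))
  # sex-specific mode: 21/29 non-hybrid females, 11/16 non-hybrid males
  e2 <- expected_next_cohort_hybrids(47, NA, NA, q_female = 21 / 29,
                                     q_male = 11 / 16)
  expect_equal(round(e2[["exp_hybrid"]], 2), 23.6)
  expect_error(expected_next_cohort_hybrids(47, 13, 32, q_female = 0.5),
               "both")
  expect_error(expected_next_cohort_hybrids(47, 0, 0), "empty")
})

test_that("relative fitness is the observed/expected double ratio", {
  expect_equal(round(relative_fitness(13, 21, 6.54, 27.46), 2), 2.60)
  expect_equal(round(relative_fitness(29, 18, 23.23, 23.77), 2), 1.65)
  expect_equal(relative_fitness(10, 20, 10, 20), 1)
  expect_warning(w <- relative_fitness(5, 0, 2, 3), "infinite")
  expect_equal(w, Inf)
  # scale invariance in all four arguments
  set.seed(5)
  for (i in 1:10) {
    x <- runif(4, 1, 30); c0 <- runif(1, 0.1, 10)
    expect_equal(relative_fitness(x[1] * c0, x[2] * c0, x[3] * c0, x[4] * c0),
                 relative_fitness(x[1], x[2], x[3], x[4]))
  }
})

test_that("the bootstrap CI converges to the exact resampling oracle", {
  d <- rf_resampling_distribution(13, 21, 6.54, 27.46)
  expect_equal(sum(d$prob), 1)
  # oracle values at the printed resample counts
  expect_equal(round(d$w[d$h == 8], 2), 1.29)
  expect_equal(round(d$w[d$h == 18], 2), 4.72)
  # exact closest-tail-mass bounds of the enumerated distribution
  below <- cumsum(d$prob) - d$prob          # P(W < w(h))
  above <- 1 - cumsum(d$prob)               # P(W > w(h))
  exact_lo <- d$w[which.min(abs(below - 0.025))]
  exact_hi <- d$w[which.min(abs(above - 0.025))]
  expect_equal(c(exact_lo, exact_hi), c(d$w[d$h == 8], d$w[d$h == 18]))
  ci <- bootstrap_rf_ci(13, 21, 6.54, 27.46, B = 1e5, seed = 17)
  expect_equal(ci$ci_low, exact_lo, tolerance = 0.02)
  expect_equal(ci$ci_high, exact_hi, tolerance = 0.02)
})

test_that("bootstrap degeneracy and small-B warnings are flagged", {
  ci <- bootstrap_rf_ci(0, 12, 2, 10, B = 200, seed = 1)
  expect_true(ci$degenerate)
  expect_equal(ci$ci_low, 0)
  expect_warning(bootstrap_rf_ci(5, 5, 5, 5, B = 50, seed = 1), "unstable")
  # CI brackets the point estimate
  w <- relative_fitness(13, 21, 6.54, 27.46)
  ci <- bootstrap_rf_ci(13, 21, 6.54, 27.46, B = 1000, seed = 2)
  expect_true(ci$ci_low <= w && w <= ci$ci_high)
})

test_that("chi-squared goodness of fit reproduces its closed form", {
  g <- chi2_gof(c(13, 21), c(6.54, 27.46))
  expect_equal(g$statistic, 7.90, tolerance = 0.001)
  expect_equal(g$p, 0.005, tolerance = 0.05)
  g2 <- chi2_gof(c(29, 18), c(23.23, 23.77))
  expect_equal(g2$statistic, 2.83, tolerance = 0.005)
  expect_equal(g2$p, 0.092, tolerance = 0.01)
  g0 <- chi2_gof(c(10, 20), c(10, 20))
  expect_equal(g0$statistic, 0)
  expect_equal(g0$p, 1)
})

test_that("one-tailed Fisher matches enumeration and stats::fisher.test", {
  expect_equal(fisher_exact_one_tailed(8, 0, 13, 8), 0.0474, tolerance = 1e-3)
  expect_equal(fisher_exact_one_tailed(4, 4, 0, 16), 0.0066, tolerance = 1e-2)
  # observed cell at its minimum in the tested direction -> p = 1
  expect_equal(fisher_exact_one_tailed(0, 5, 5, 5, "greater"), 1)
  # brute-force enumeration and the base-R implementation agree
  set.seed(23)
  for (i in 1:25) {
    cells <- as.integer(sample(0:15, 4, replace = TRUE))
    if (sum(cells) == 0) next
    a <- cells[1]; b <- cells[2]; c <- cells[3]; d <- cells[4]
    p_pkg <- fisher_exact_one_tailed(a, b, c, d, "greater")
    expect_equal(p_pkg, fisher_brute(a, b, c, d, "greater"), tolerance = 1e-12)
    p_base <- stats::fisher.test(matrix(cells, 2, byrow = TRUE),
                                 alternative = "greater")$p.value
    expect_equal(p_pkg, p_base, tolerance = 1e-9)
    p_less <- fisher_exact_one_tailed(a, b, c, d, "less")
    expect_equal(p_less,
                 stats::fisher.test(matrix(cells, 2, byrow = TRUE),
                                    alternative = "less")$p.value,
                 tolerance = 1e-9)
  }
})

test_that("the exact binomial upper tail behaves at its limits", {
  expect_equal(binomial_exact_upper(0, 10, 0.3), 1)
  expect_equal(binomial_exact_upper(10, 10, 0.5), 0.5^10)
  p <- binomial_exact_upper(13, 34, 5 / 26)
  expect_true(p > 0.001 && p < 0.02)
  expect_equal(p, sum(dbinom(13:34, 34, 5 / 26)))
})

test_that("cohort fitness rows assemble all components coherently", {
  cf <- cohort_fitness(2012, 13, 21, 6.54, 27.46, B = 1000, seed = 4)
  expect_s3_class(cf, "cohort_fitness")
  expect_equal(round(cf$relative_fitness, 2), 2.60)
  expect_true(cf$ci_low <= cf$relative_fitness &&
                cf$relative_fitness <= cf$ci_high)
  expect_equal(cf$exp_hybrid + cf$exp_nonhybrid,
               cf$obs_hybrid + cf$obs_nonhybrid, tolerance = 1e-9)
  expect_lt(cf$p_chi2, 0.01)
})

test_that("longevity counts inclusive calendar years per ancestry class", {
  records <- data.frame(
    id = c("a", "b", "c", "d"),
    sex = "F",
    year_first_adult = c(2012L, 2012L, 2012L, 2012L),
    pouch_young = 4L,
    last_seen_year = c(2012L, 2015L, 2012L, 2013L))
  calls <- data.frame(id = c("a", "b", "c", "d"),
                      class = c("F1", "F1", "resident", "resident"))
  s <- longevity_summary(records, calls, census_year = 2015)
  expect_equal(s$longevity$mean_longevity[s$longevity$class == "hybrid"], 2.5)
  expect_equal(s$longevity$mean_longevity[s$longevity$class == "nonhybrid"],
               1.5)
  expect_equal(s$survival_table["hybrid", "alive"], 1)
  expect_equal(s$survival_table["nonhybrid", "alive"], 0)
  expect_error(longevity_summary(records, calls, census_year = 2000),
               "precedes")
  # all animals last seen in their first year -> mean longevity 1 per class
  records$last_seen_year <- records$year_first_adult
  s1 <- longevity_summary(records, calls, census_year = 2012)
  expect_true(all(s1$longevity$mean_longevity == 1))
})

test_that("class-dependent simulated survival is recovered in the ordering", {
  set.seed(31)
  n <- 300
  cls <- sample(c("F1", "resident"), n, TRUE)
  surv_p <- ifelse(cls == "F1", 0.7, 0.3)
  extra <- rgeom(n, prob = 1 - surv_p)
  records <- data.frame(id = paste0("i", 1:n), sex = "F",
                        year_first_adult = 2012L, pouch_young = 4L,
                        last_seen_year = 2012L + pmin(extra, 3L))
  calls <- data.frame(id = records$id, class = cls)
  s <- longevity_summary(records, calls, census_year = 2015)
  lng <- s$longevity
  expect_gt(lng$mean_longevity[lng$class == "hybrid"],
            lng$mean_longevity[lng$class == "nonhybrid"])
  expect_lt(s$p_survival, 0.05)
})
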
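test_that("the MoCA cutoff classifies scores below 26 as impaired", {
  expect_identical(as.character(classify_moca(25L)), "CI")
  expect_identical(as.character(classify_moca(26L)), "CN")
  expect_identical(as.character(classify_moca(30L)), "CN")
  expect_identical(as.character(classify_moca(0L)), "CI")
  expect_error(classify_moca(31L), "\\[0, 30\\]")
})

test_that("KS normality gating separates normal from exponential samples", {
  set.seed(40)
  expect_true(ks_normality(rnorm(500))$is_normal)
  expect_false(ks_normality(rexp(500))$is_normal)
  const <- ks_normality(rep(3, 10))
  expect_false(const$is_normal)
  expect_true(const$constant)
  expect_error(ks_normality(1:3), "at least 5")
})

test_that("pooled t-test agrees between raw-data and summary entry points", {
  set.seed(41)
  x <- rnorm(20, 1); y <- rnorm(15)
  raw <- student_t(x, y)
  summ <- student_t_summary(mean(x), sd(x), 20, mean(y), sd(y), 15)
  expect_equal(raw$statistic, summ$statistic, tolerance = 1e-10)
  expect_equal(raw$p_value, summ$p_value, tolerance = 1e-10)
  expect_equal(student_t(x, x)$statistic, 0)
  # independent direct-formula oracle
  sp2 <- ((19) * var(x) + (14) * var(y)) / 33
  t_hand <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / 20 + 1 / 15))
  expect_equal(raw$statistic, t_hand, tolerance = 1e-12)
  expect_error(student_t(rep(1, 5), rep(2, 5)), "zero variance")
})

test_that("one-way ANOVA matches its summary reconstruction and t^2 identity", {
  set.seed(42)
  g1 <- rnorm(12, 0); g2 <- rnorm(14, 0.5); g3 <- rnorm(10, 1)
  raw <- one_way_anova(list(g1, g2, g3))
  summ <- one_way_anova_summary(list(c(mean(g1), sd(g1), 12),
                                     c(mean(g2), sd(g2), 14),
                                     c(mean(g3), sd(g3), 10)))
  expect_equal(raw$statistic, summ$statistic, tolerance = 1e-10)
  expect_equal(raw$p_value, summ$p_value, tolerance = 1e-10)
  # two groups: F = t^2
  f2 <- one_way_anova(list(g1, g2))
  t2 <- student_t(g1, g2)
  expect_equal(f2$statistic, t2$statistic^2, tolerance = 1e-10)
  expect_error(one_way_anova(list(g1)), "2 groups")
  expect_error(one_way_anova(list(rep(1, 5), rep(2, 5))), "zero")
})

test_that("Mann-Whitney U handles extremes and matches exact enumeration", {
  sep <- mann_whitney_u(1:4, 11:14)
  expect_identical(sep$u, 0)
  expect_lt(sep$statistic, 0)

  sym <- mann_whitney_u(c(1, 3, 5, 7), c(2, 4, 6, 8))
  expect_equal(sym$u, 4 * 4 / 2 - 2)  # near the null midpoint
  expect_lt(abs(sym$statistic), 1)

  # exact p equals wilcox.test's exact enumeration for small tie-free data
  set.seed(43)
  for (rep_i in 1:10) {
    x <- sample(100, 5L); y <- sample(200:300, 4L)
    mine <- mann_whitney_u(x, y)
    ref <- wilcox.test(x, y, exact = TRUE)
    expect_true(mine$exact)
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-12)
  }
})

test_that("Kruskal-Wallis wraps the tie-corrected H with optional exact p", {
  expect_lt(kruskal_wallis(list(c(1, 2, 3), c(1, 2, 3)))$statistic, 0.01)
  # consistent direction with the rank-sum test for two groups
  set.seed(44)
  x <- rnorm(8); y <- rnorm(8, 2)
  kw <- kruskal_wallis(list(x, y))
  mw <- mann_whitney_u(x, y)
  expect_lt(kw$p_value, 0.05)
  expect_lt(mw$p_value, 0.05)
  # exact permutation p from complete enumeration
  x2 <- c(1.2, 3.4, 0.5); y2 <- c(5.6, 7.8, 6.1)
  ex <- kruskal_wallis(list(x2, y2), exact = TRUE)
  h_ref <- suppressWarnings(kruskal.test(c(x2, y2),
                                         factor(rep(1:2, each = 3)))$statistic)
  perms <- thalamod:::all_permutations(6L)
  h_all <- apply(perms, 1L, function(pp) {
    suppressWarnings(kruskal.test(c(x2, y2)[pp],
                                  factor(rep(1:2, each = 3)))$statistic)
  })
  expect_equal(ex$p_value, mean(h_all >= h_ref - 1e-9), tolerance = 1e-12)
})

test_that("chi-square equals the (O-E)^2/E expansion without correction", {
  tab <- rbind(male = c(6, 8, 16), female = c(12, 27, 21))
  res <- chi_square(tab)
  # independent oracle: stats::chisq.test without continuity correction
  ref <- chisq.test(tab, correct = FALSE)
  expect_equal(res$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(res$p_value, ref$p.value, tolerance = 1e-12)
  expect_identical(res$df, 2)

  # a table equal to its expected counts gives exactly zero
  perfect <- outer(c(10, 20), c(3, 7)) / 10
  expect_equal(chi_square(perfect)$statistic, 0, tolerance = 1e-12)

  set.seed(45)
  for (rep_i in 1:10) {
    t2 <- matrix(sample(1:30, 4L), 2L)
    expect_equal(chi_square(t2)$statistic,
                 unname(chisq.test(t2, correct = FALSE)$statistic),
                 tolerance = 1e-12)
  }
  expect_error(chi_square(rbind(c(0, 0), c(1, 2))), "zero margin")
})

test_that("Bonferroni correction is the capped product and monotone in m", {
  expect_equal(bonferroni(0.01, m = 7), 0.07)
  expect_equal(bonferroni(0.001, m = 21), 0.021)
  expect_equal(bonferroni(0.4, m = 5), 1)
  expect_equal(bonferroni(c(0.3), m = 1), 0.3)
  ps <- bonferroni(c(0.01, 0.02))
  expect_equal(ps, c(0.02, 0.04))
  for (m in 1:5) {
    expect_gte(bonferroni(0.03, m = m + 1), bonferroni(0.03, m = m))
  }
  res <- bonferroni(list(student_t(rnorm(10), rnorm(10))), family_id = "demo",
                    m = 4)
  expect_equal(res[[1]]$corrected_p, min(1, res[[1]]$p_value * 4))
  expect_identical(res[[1]]$family_id, "demo")
})

test_that("metric-MoCA correlation is exact for linear data and calibrated under the null", {
  moca <- c(18, 20, 21, 23, 24, 25, 22, 19, 17, 16)
  res <- metric_moca_correlation(2 * moca + 3, moca)
  expect_equal(res$estimate, 1, tolerance = 1e-10)
  expect_error(metric_moca_correlation(rep(1, 10), moca), "constant")

  set.seed(46)
  hits <- mean(vapply(1:1000, function(i) {
    metric_moca_correlation(rnorm(18), rnorm(18))$p_value < 0.05
  }, logical(1L)))
  expect_gt(hits, 0.03)
  expect_lt(hits, 0.07)
})

test_that("the demographic battery covers every variable and comparison", {
  spec <- tiny_spec(n_hc = 12L, n_cn = 12L, n_ci = 12L, n_timepoints = 60L,
                    n_parcels = 14L, seed = 47L)
  cohort <- generate_cohort(spec)
  report <- run_table1(cohort$phenotypes)
  expect_true(all(c("age", "sex", "education", "moca", "onset_age",
                    "duration", "seizure_freq") %in% report$variable))
  expect_true(all(report$p_value >= 0 & report$p_value <= 1))
  expect_true(any(report$comparison == "TLE-CI vs TLE-CN vs HC"))
  expect_true(any(report$comparison == "TLE vs HC"))
  expect_true(any(report$comparison == "TLE-CI vs TLE-CN"))
  expect_error(run_table1(cohort$phenotypes[, -3]), "lacks column")
})

test_that("permuting group labels destroys the MoCA group effect", {
  spec <- tiny_spec(n_hc = 30L, n_cn = 30L, n_ci = 20L, n_timepoints = 60L,
                    n_parcels = 14L, seed = 48L)
  ph <- generate_cohort(spec)$phenotypes
  observed <- one_way_anova(split(ph$moca, ph$group))$statistic
  crit <- qf(0.95, 2, nrow(ph) - 3)
  expect_gt(observed, crit)
  set.seed(49)
  below <- mean(vapply(1:200, function(i) {
    g <- sample(ph$group)
    one_way_anova(split(ph$moca, g))$statistic < crit
  }, logical(1L)))
  expect_gte(below, 0.95)
})
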
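test_that("interobserver correlation handles identity, anticorrelation and errors", {
  tab <- makeCohortTable(c("a", "b", "c"), c(25, 45, 65), c(1.2, 1.5, 1.3),
                         c(1.2, 1.5, 1.3))
  expect_equal(interobserverCorrelation(tab)$r, 1)

  anti <- makeCohortTable(c("a", "b"), c(25, 45), c(1, 2), c(2, 1))
  expect_equal(interobserverCorrelation(anti)$r, -1)

  holes <- makeCohortTable(c("a", "b"), c(25, 45), c(1, NA), c(2, 1))
  expect_error(interobserverCorrelation(holes), "subject\\(s\\): b")
})

test_that("Pearson r matches the explicit sum-formula oracle", {
  set.seed(21)
  for (i in 1:10) {
    n <- sample(10:40, 1)
    a <- rnorm(n, 1.5, 0.2)
    b <- a + rnorm(n, 0, 0.1)
    tab <- makeCohortTable(sprintf("s%d", 1:n), sample(10:89, n, TRUE), a, b)
    expect_equal(interobserverCorrelation(tab)$r, pearsonOracle(a, b),
                 tolerance = 1e-12)
  }
})

test_that("the Fisher-z CI brackets r and the ICC extension is sane", {
  set.seed(8)
  a <- rnorm(40, 1.5, 0.15); b <- a + rnorm(40, 0, 0.07)
  tab <- makeCohortTable(sprintf("s%d", 1:40), sample(10:89, 40, TRUE), a, b)
  res <- interobserverCorrelation(tab)
  expect_true(res$ci[1] < res$r && res$r < res$ci[2])
  expect_true(res$icc21 <= 1 && res$icc21 > 0)
})

test_that("linearFit reproduces collinear and flat degenerate cases", {
  col3 <- makeCohortTable(c("a", "b", "c"), c(11, 12, 13), c(1, 2, 3), c(1, 2, 3))
  f <- linearFit(col3)
  expect_equal(f@r, 1, tolerance = 1e-12)
  expect_equal(unname(f@coefficients["age"]), 1, tolerance = 1e-12)

  flat <- makeCohortTable(c("a", "b", "c"), c(11, 12, 13), c(2, 2, 2), c(2, 2, 2))
  f2 <- linearFit(flat)
  expect_equal(unname(f2@coefficients["age"]), 0, tolerance = 1e-12)
  expect_equal(f2@r, 0)

  expect_error(linearFit(col3[1:2, ]), "at least 3")
})

test_that("OLS coefficients match the normal-equations oracle", {
  tab <- generateCohort(defaultCohortSpec(), seed = 31)
  f <- linearFit(tab)
  oracle <- olsOracle(tab$age, tab$index, degree = 1)
  expect_equal(unname(f@coefficients), unname(oracle), tolerance = 1e-10)
  expect_equal(f@r, pearsonOracle(tab$age, tab$index), tolerance = 1e-12)

  q <- quadraticFit(tab)
  oracle2 <- olsOracle(tab$age, tab$index, degree = 2)
  expect_equal(unname(q@coefficients), unname(oracle2), tolerance = 1e-8)
})

test_that("the over-40 subgroup filter is strictly exclusive", {
  tab <- makeCohortTable(sprintf("s%d", 1:6), c(39, 40, 41, 50, 60, 70),
                         c(1.6, 1.6, 1.5, 1.4, 1.3, 1.2),
                         c(1.6, 1.6, 1.5, 1.4, 1.3, 1.2))
  f <- linearFit(tab, minAge = 40)
  expect_identical(f@n, 4L) # ages 41, 50, 60, 70; age 40 excluded
})

test_that("quadraticFit recovers an exact parabola and its vertex", {
  ages <- c(20, 30, 45, 60, 80)
  y <- -(ages - 45)^2 / 1000 + 1.8
  tab <- makeCohortTable(sprintf("s%d", 1:5), ages, y, y)
  q <- quadraticFit(tab)
  expect_equal(q@R, 1, tolerance = 1e-9)
  expect_equal(q@vertexAge, 45, tolerance = 1e-8)
})

test_that("on collinear data the quadratic fit collapses to the linear one", {
  ages <- c(15, 25, 35, 45, 55)
  y <- 2 - 0.01 * ages
  tab <- makeCohortTable(sprintf("s%d", 1:5), ages, y, y)
  q <- quadraticFit(tab)
  l <- linearFit(tab)
  expect_equal(unname(q@coefficients["age2"]), 0, tolerance = 1e-10)
  expect_equal(q@R, abs(l@r), tolerance = 1e-9)

  same <- makeCohortTable(sprintf("s%d", 1:4), rep(40, 4), 1:4, 1:4)
  expect_error(quadraticFit(same), "degenerate")
})

test_that("quadratic R is never below |linear r| (nested models)", {
  set.seed(77)
  for (i in 1:15) {
    n <- sample(8:60, 1)
    tab <- makeCohortTable(sprintf("s%d", 1:n), sample(10:89, n, TRUE),
                           rnorm(n, 1.5, 0.2), rnorm(n, 1.5, 0.2))
    expect_gte(quadraticFit(tab)@R + 1e-12, abs(linearFit(tab)@r))
  }
})

test_that("decade ANOVA matches the between/within sum-of-squares oracle", {
  tab <- tinyCohort(list(c(1.2, 1.4, 1.3), c(1.6, 1.8, 1.5), c(1.1, 1.0, 1.3)))
  res <- decadeAnova(tab)
  expect_equal(res@fStatistic, anovaFOracle(tab$index, tab$decade),
               tolerance = 1e-12)
  expect_identical(nrow(res@pairwise), 3L)
  expect_equal(sum(res@groups$n), nrow(tab))
})

test_that("zero within-group variance yields a maximal F and significant pair", {
  tab <- tinyCohort(list(c(1, 1), c(2, 2)))
  res <- decadeAnova(tab)
  expect_identical(res@fStatistic, Inf)
  expect_identical(res@pValue, 0)
  expect_true(all(res@pairwise$significant))
})

test_that("the Tukey significant set is invariant under group relabeling", {
  set.seed(5)
  vals <- list(rnorm(8, 1.2, 0.1), rnorm(8, 1.6, 0.1), rnorm(8, 1.25, 0.1))
  tab <- tinyCohort(vals)
  tabRev <- tinyCohort(rev(vals)) # same groups, opposite decade labels
  s1 <- decadeAnova(tab)@pairwise
  s2 <- decadeAnova(tabRev)@pairwise
  # map: vals[[1]] sits in decade 10s of tab but 30s of tabRev, etc.
  relabel <- c("10s" = "30s", "20s" = "20s", "30s" = "10s")
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  flags1 <- setNames(s1$significant, key(relabel[s1$group1], relabel[s1$group2]))
  flags2 <- setNames(s2$significant, key(s2$group1, s2$group2))
  expect_identical(flags1[names(flags2)], flags2)
  expect_error(decadeAnova(tinyCohort(list(c(1, 2)))), "insufficient groups")
})

test_that("boxplot summaries use type-7 quantiles and the 1.5 IQR rule", {
  tab <- tinyCohort(list(1:9, c(1, 1.1, 1.2, 9)))
  res <- decadeAnova(tab)
  g1 <- res@groups[res@groups$decade == "10s", ]
  expect_equal(g1$median, 5)
  expect_equal(g1$q1, 3)
  expect_equal(g1$q3, 7)
  expect_identical(g1$n_outliers, 0L)
  g2 <- res@groups[res@groups$decade == "20s", ]
  expect_identical(g2$n_outliers, 1L) # the 9 among 1, 1.1, 1.2
  expect_equal(res@outliers$value, 9)
})

test_that("plot data serializes the computed regression curves exactly", {
  tab <- generateCohort(defaultCohortSpec(), seed = 19)
  stats <- cohortStatistics(tab)
  out <- plotCohort(tab, stats$linear, stats$subgroup, stats$quadratic,
                    stats$anova)
  bands <- out$plotData$bands
  # oracle: re-fit with lm/predict directly in the test
  fit <- lm(index ~ age, data = tab)
  grid <- data.frame(age = seq(min(tab$age), max(tab$age), length.out = 101))
  p <- predict(fit, newdata = grid, interval = "confidence")
  expect_equal(bands$linear$fit, unname(p[, "fit"]), tolerance = 1e-10)
  expect_equal(bands$linear$lwr, unname(p[, "lwr"]), tolerance = 1e-10)
  expect_equal(bands$linear$upr, unname(p[, "upr"]), tolerance = 1e-10)
  # determinism: a second call serializes identically
  out2 <- plotCohort(tab, stats$linear, stats$subgroup, stats$quadratic,
                     stats$anova)
  expect_identical(out$plotData$bands, out2$plotData$bands)
})

test_that("an unavailable subgroup fit is omitted with a notice", {
  young <- makeCohortTable(sprintf("s%d", 1:5), c(15, 18, 22, 25, 30),
                           seq(1.3, 1.5, length.out = 5),
                           seq(1.3, 1.5, length.out = 5))
  expect_message(stats <- cohortStatistics(young, minAge = 40),
                 "subgroup fit skipped")
  expect_null(stats$subgroup)
  expect_message(plotCohort(young, stats$linear, NULL, stats$quadratic),
                 "omitting")
})
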
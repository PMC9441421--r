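test_that("tensorSignal follows the monoexponential model", {
  expect_equal(tensorSignal(c(1.0, 0.5, 0.5), "x", 1000, 1000),
               1000 * exp(-1), tolerance = 1e-12)
  expect_equal(tensorSignal(c(1.0, 0.5, 0.5), "y", 1000, 0), 1000)
  expect_equal(tensorSignal(c(3.0, 3.0, 3.0), "z", 800, 1000),
               800 * exp(-3), tolerance = 1e-12)
})

test_that("phantom ground-truth indices follow the closed-form tensor ratio", {
  expect_equal(phantomTruthIndex(defaultPhantomSpec()), 3.0)
  expect_equal(phantomTruthIndex(defaultPhantomSpec("low_perivascular")), 2.0)
  expect_equal(phantomTruthIndex(defaultPhantomSpec("realistic")), 1.5)
  expect_equal(phantomTruthIndex(defaultPhantomSpec("isotropic")), 1.0)
  # invariant to grid resolution
  expect_equal(phantomTruthIndex(defaultPhantomSpec(dims = c(96L, 96L, 48L))),
               3.0)
})

test_that("noiseless phantoms reproduce tensorSignal exactly", {
  spec <- defaultPhantomSpec(sigma = 0)
  ph <- generatePhantom(spec)
  m <- phantomRegionMask(spec, "proj_R")
  sx <- signalVolume(ph$study, "x")[m]
  expect_equal(unique(sx), tensorSignal(c(1.2, 0.4, 1.4), "x", 1000, 1000),
               tolerance = 1e-12)
  expect_true(all(signalVolume(ph$study, "b0") == 1000))
})

test_that("phantom generation is seed-deterministic", {
  spec <- defaultPhantomSpec(sigma = 50)
  a <- generatePhantom(spec, seed = 123)
  b <- generatePhantom(spec, seed = 123)
  c <- generatePhantom(spec, seed = 124)
  expect_identical(signalVolume(a$study, "x"), signalVolume(b$study, "x"))
  expect_identical(signalVolume(a$study, "b0"), signalVolume(b$study, "b0"))
  expect_false(identical(signalVolume(a$study, "x"), signalVolume(c$study, "x")))
})

test_that("invalid phantom specs are rejected", {
  spec <- defaultPhantomSpec()
  bad <- spec
  bad@regions$proj_L$box[1, ] <- c(20, 30) # collides with ventricle at 27
  expect_error(validObject(bad), "overlap")
  aniso <- spec
  aniso@regions$ventricle$D <- c(3, 3, 2)
  expect_error(validObject(aniso), "isotropic")
  flip <- spec
  flip@regions$proj_L$D <- c(1.2, 1.4, 0.4) # Dz not maximal
  expect_error(validObject(flip), "Dz maximal")
})

test_that("Rician noise at high SNR matches the Rice-mean approximation", {
  spec <- defaultPhantomSpec(sigma = 50)
  ph <- generatePhantom(spec, seed = 42)
  s0 <- signalVolume(ph$study, "b0") # true signal 1000 everywhere
  n <- length(s0)
  approxMean <- 1000 + 50^2 / (2 * 1000)
  se <- 50 / sqrt(n)
  expect_lt(abs(mean(s0) - approxMean), 3 * se)
})

test_that("pipeline estimate converges to the ground truth as noise shrinks", {
  errs <- vapply(c(50, 10, 2), function(sg) {
    ph <- generatePhantom(defaultPhantomSpec(sigma = sg), seed = 6)
    abs(indexValue(measureSubject(ph$study, defaultRoiSet(), "A")) - 3.0)
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[3], 0.02)
})

test_that("the cohort generator honors the decade design", {
  tab <- generateCohort(defaultCohortSpec(), seed = 7)
  expect_identical(nrow(tab), 128L)
  expect_identical(unname(c(table(tab$decade))), c(24L, 21L, 14L, 15L, 19L, 14L, 15L, 6L))
  expect_true(all(tab$age >= 10 & tab$age <= 89))
  # determinism
  expect_identical(tab, generateCohort(defaultCohortSpec(), seed = 7))
})

test_that("a noise-free cohort reproduces the generative parabola exactly", {
  spec <- defaultCohortSpec(subjectSD = 0, observerSD = 0)
  tab <- generateCohort(spec, seed = 3)
  q <- quadraticFit(tab)
  expect_equal(q@R, 1, tolerance = 1e-9)
  expect_equal(q@vertexAge, 45, tolerance = 1e-6)
})

test_that("interobserver correlation matches the variance-attenuation closed form", {
  # large-n design (counts x 30) so Monte-Carlo error is small
  spec <- defaultCohortSpec(counts = c(24L, 21L, 14L, 15L, 19L, 14L, 15L, 6L) * 30L)
  tab <- generateCohort(spec, seed = 11)
  emp <- interobserverCorrelation(tab)$r
  # closed form: r = var(true subject index) / (var(true) + var(observer));
  # the covariance of the two observers estimates var(true)
  vTrue <- cov(tab$index_obs_a, tab$index_obs_b)
  pred <- vTrue / (vTrue + 0.048^2)
  expect_equal(emp, pred, tolerance = 0.02)
  expect_gt(emp, 0.8) # calibrated near the reported agreement
  expect_lt(emp, 0.9)
})

test_that("with zero curvature the fitted quadratic coefficient centers on zero", {
  coefs <- vapply(1:40, function(s) {
    tab <- generateCohort(defaultCohortSpec(curvature = 0), seed = s)
    unname(quadraticFit(tab)@coefficients["age2"])
  }, numeric(1))
  se <- sd(coefs) / sqrt(length(coefs))
  expect_lt(abs(mean(coefs)), 3 * se)
})
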
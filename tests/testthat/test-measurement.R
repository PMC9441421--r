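test_that("alpsIndex implements the ratio-of-means formula", {
  expect_equal(alpsIndex(1.0, 1.0, 1.0, 1.0), 1.0)
  expect_equal(alpsIndex(1.2, 1.0, 0.8, 0.6), 1.1 / 0.7, tolerance = 1e-15)
  # closed-form phantom tensors
  expect_equal(alpsIndex(1.2, 1.2, 0.4, 0.4), 3.0)
  expect_error(alpsIndex(1, 1, -2, 1), "degenerate denominator")
  expect_error(alpsIndex(1, NA, 1, 1), "finite")
})

test_that("alpsIndex is invariant under common positive scaling", {
  set.seed(3)
  for (i in 1:20) {
    v <- runif(4, 0.3, 2)
    s <- runif(1, 0.1, 10)
    expect_equal(alpsIndex(v[1], v[2], v[3], v[4]),
                 alpsIndex(s * v[1], s * v[2], s * v[3], s * v[4]),
                 tolerance = 1e-12)
  }
})

test_that("measureRois averages valid voxels inside inclusive circles", {
  spec <- defaultPhantomSpec()
  maps <- computeADC(generatePhantom(spec)$study)

  # radius 0: single-voxel region inside proj_L (D = 1.2, 0.4, 1.4)
  regs <- data.frame(label = c("L_proj", "R_proj", "L_assoc", "R_assoc"),
                     row = c(21, 44, 11, 54), col = 32, radius = 0)
  tab <- measureRois(maps, RoiSet(17L, regs))
  lp <- tab[tab$label == "L_proj", ]
  expect_identical(lp$n_voxels, 1L)
  expect_equal(c(lp$mean_x, lp$mean_y, lp$mean_z), c(1.2, 0.4, 1.4),
               tolerance = 1e-9)

  # radius 3 fully inside the noiseless block: exact tensor diagonal
  tab3 <- measureRois(maps, defaultRoiSet())
  la <- tab3[tab3$label == "L_assoc", ]
  expect_equal(c(la$mean_x, la$mean_y, la$mean_z), c(1.2, 1.4, 0.4),
               tolerance = 1e-9)
  # inclusive boundary: radius 3 disc has 29 voxels
  expect_identical(la$n_voxels, 29L)
})

test_that("a straddling ROI equals the voxel-count-weighted tensor average", {
  spec <- defaultPhantomSpec()
  maps <- computeADC(generatePhantom(spec)$study)
  # disc centered on the proj_L / background boundary at row 24/25
  regs <- data.frame(label = c("L_proj", "R_proj", "L_assoc", "R_assoc"),
                     row = c(24, 44, 11, 54), col = 32, radius = c(3, 0, 0, 0))
  tab <- measureRois(maps, RoiSet(17L, regs))
  # brute-force oracle: enumerate disc voxels, look up each voxel's region
  mem <- expand.grid(row = 21:27, col = 29:35)
  mem <- mem[(mem$row - 24)^2 + (mem$col - 32)^2 <= 9, ]
  # proj_L box ends at row 24; ventricle starts at row 27; between is background
  Dx <- ifelse(mem$row <= 24, 1.2, ifelse(mem$row >= 27, 3.0, 0.8))
  Dy <- ifelse(mem$row <= 24, 0.4, ifelse(mem$row >= 27, 3.0, 0.8))
  expected_x <- mean(Dx)
  expected_y <- mean(Dy)
  got <- tab[tab$label == "L_proj", ]
  expect_equal(got$mean_x, expected_x, tolerance = 1e-9)
  expect_equal(got$mean_y, expected_y, tolerance = 1e-9)
})

test_that("measureRois errors name the offending ROI", {
  spec <- defaultPhantomSpec()
  maps <- computeADC(generatePhantom(spec)$study)
  oob <- data.frame(label = c("L_proj", "R_proj", "L_assoc", "R_assoc"),
                    row = c(2, 44, 11, 54), col = 32, radius = c(3, 3, 3, 3))
  oob$row[1] <- 2
  expect_error(measureRois(maps, RoiSet(17L, oob)), "'L_proj'")
})

test_that("bilateral pooling averages hemispheres; symmetric phantoms agree per side", {
  ph <- generatePhantom(defaultPhantomSpec())
  res <- measureSubject(ph$study, defaultRoiSet(), "A", perHemisphere = TRUE)
  expect_equal(res$left, res$right, tolerance = 1e-12)
  expect_equal(indexValue(res$measurement), res$left, tolerance = 1e-12)
})

test_that("identical ROI sets give identical measurements across observers", {
  ph <- generatePhantom(defaultPhantomSpec(sigma = 40), seed = 9)
  mA <- measureSubject(ph$study, defaultRoiSet(), "A")
  mB <- measureSubject(ph$study, defaultRoiSet(), "B")
  expect_identical(indexValue(mA), indexValue(mB))
  expect_identical(roiMeans(mA), roiMeans(mB))
})

test_that("stage errors are reported with the stage named", {
  g <- array(1000, c(4, 4, 2))
  bad <- DiffusionStudy(g, g, g, g, bValue = 0)
  expect_error(measureSubject(bad, defaultRoiSet(), "A"), "\\[stage adc\\]")
})

test_that("combineObservers averages indices per subject", {
  mk <- function(id, ob, idx) {
    # build via means that reproduce the requested index exactly
    new("AlpsMeasurement", adcxProj = idx, adcxAssoc = idx,
        adcyProj = 1, adczAssoc = 1,
        alpsIndex = alpsIndex(idx, idx, 1, 1), subjectID = id, observerID = ob)
  }
  two <- combineObservers(list(mk("s1", "A", 1.4), mk("s1", "B", 1.6)))
  expect_equal(two$index, 1.5)
  one <- combineObservers(list(mk("s2", "A", 1.37)))
  expect_equal(one$index, 1.37)
  three <- combineObservers(list(mk("s3", "A", 1.2), mk("s3", "B", 1.3),
                                 mk("s3", "C", 1.6)))
  expect_equal(three$index, mean(c(1.2, 1.3, 1.6)), tolerance = 1e-15)
  expect_identical(three$n_observers, 3L)
})

test_that("the stored index is recomputable from the stored means", {
  ph <- generatePhantom(defaultPhantomSpec(sigma = 25), seed = 2)
  m <- measureSubject(ph$study, defaultRoiSet(), "A")
  v <- roiMeans(m)
  expect_identical(indexValue(m),
                   ((v[["adcx_proj"]] + v[["adcx_assoc"]]) / 2) /
                     ((v[["adcy_proj"]] + v[["adcz_assoc"]]) / 2))
  # validity enforces it
  expect_error(new("AlpsMeasurement", adcxProj = 1, adcxAssoc = 1,
                   adcyProj = 1, adczAssoc = 1, alpsIndex = 2,
                   subjectID = "s", observerID = "A"),
               "recomputable")
})
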
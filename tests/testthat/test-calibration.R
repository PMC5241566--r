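test_that("FOV projection selects the expected planar band", {
  pl <- planarImage(matrix(1, 10, 20), spacing = c(4, 4), origin = c(0, 0))
  ## full coverage
  expect_true(all(projectFov(pl, c(0, 80))))
  ## exactly half of the axial extent
  half <- projectFov(pl, c(0, 40))
  expect_equal(sum(half), 10 * 10)
  expect_true(all(half[, 1:10]) && !any(half[, 11:20]))
  ## known box: pixel centres 2, 6, 10, ... mm; centres in [10, 30]
  ## are columns 3..8
  box <- projectFov(pl, c(10, 30))
  expect_equal(which(box[1, ]), 3:8)
  expect_error(projectFov(pl, c(200, 300)), "overlap")
})

test_that("FAF is the in-FOV count fraction and is scale invariant", {
  m <- matrix(0, 4, 10); m[, 1:5] <- 2
  pl <- planarImage(m, spacing = c(4, 4))
  region <- projectFov(pl, c(0, 20))
  expect_equal(computeFaf(pl, region), 1.0)
  m2 <- matrix(1, 4, 10)
  pl2 <- planarImage(m2, spacing = c(4, 4))
  expect_equal(computeFaf(pl2, region), 0.5)
  pl3 <- planarImage(m2 * 137, spacing = c(4, 4))
  expect_equal(computeFaf(pl3, region), 0.5)
  expect_error(computeFaf(planarImage(m2 * 0, spacing = c(4, 4)), region),
               "zero total")
})

test_that("calibration factor follows the decay-corrected count ratio", {
  expect_equal(computeCalibrationFactor(1e6, 100, 0, faf = 1)@calibFactor, 1e4)
  expect_equal(computeCalibrationFactor(1e6, 100, 0, faf = 0.5)@calibFactor,
               2e4)
  lam <- log(2) / 67.3
  cf <- computeCalibrationFactor(1e6, 185, 1, lam, faf = 0.8)
  expect_equal(cf@calibFactor, 1e6 / (185 * exp(-lam * 1) * 0.8))
  expect_error(computeCalibrationFactor(1e6, 185, 1, lam, faf = 0), "faf")
  expect_error(computeCalibrationFactor(1e6, -5, 1, lam, faf = 0.5),
               "positive")
})

test_that("counts convert to activity and %IA/kg", {
  img <- voxelImage(array(300, c(3, 3, 3)), 4.18, unit = "counts")
  act <- countsToActivity(img, 3e4)
  expect_equal(voxelValues(act), array(0.01, c(3, 3, 3)))
  expect_equal(valueUnit(act), "MBq")
  expect_equal(toPercentIAPerKg(1.85, 185, 0.1), 10)
  expect_equal(toPercentIAPerKg(0, 185, 0.1), 0)
  expect_error(toPercentIAPerKg(1, 185, 0), "mass")
})

test_that("activity -> counts -> activity round trips exactly without noise", {
  study <- smallStudy(seed = 7, noise = FALSE, psfFwhmMm = 0)
  cal <- calibrateStudy(study)
  ## the recovered calibration factor is the generator's
  expect_equal(cal$calibration@calibFactor, study@meta$calibFactorTrue,
               tolerance = 1e-10)
  expect_equal(cal$calibration@faf, study@meta$fafTrue, tolerance = 1e-10)
  ## total image activity at 1 h equals A_inj e^(-lambda t) FAF
  lam <- log(2) / 67.3
  expect_equal(sum(voxelValues(cal$study@spect[[1]])),
               study@injectedActivityMBq * exp(-lam * study@times[1]) *
                 cal$calibration@faf,
               tolerance = 1e-10)
})

test_that("liver activity is recovered from a noisy rendered study", {
  study <- smallStudy(seed = 13, noise = TRUE, psfFwhmMm = 0)
  cal <- calibrateStudy(study)
  act <- sum(voxelValues(cal$study@spect[[1]])[maskArray(study@masks$liver)])
  spec <- smallPhantomSpec()
  k <- spec$kinetics[spec$kinetics$region == "liver", ]
  lam <- log(2) / 67.3
  truth <- k$fraction * 185 * (exp(-k$lambda_b) - exp(-k$lambda_u)) *
    exp(-lam)
  expect_equal(act, truth, tolerance = 0.05)  # Poisson-level agreement
})
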
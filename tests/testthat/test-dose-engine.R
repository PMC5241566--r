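test_that("the bundled beta spectrum has the expected moments", {
  sp <- loadY90Spectrum()
  expect_equal(meanEnergy(sp), 933.7, tolerance = 0.01)
  expect_equal(endpointEnergy(sp), 2280.1)
  ## a uniform spectrum on [0, 100] keV has mean 50
  u <- betaSpectrum(seq(0, 100, by = 1), rep(1, 101))
  expect_equal(meanEnergy(u), 50, tolerance = 1e-9)
})

test_that("energy sampling follows the tabulated distribution", {
  sp <- loadY90Spectrum()
  set.seed(100)
  n <- 1e5
  e <- sampleEnergy(sp, n)
  expect_true(all(e >= 0 & e <= endpointEnergy(sp)))
  ## CLT bound on the mean (3 standard errors)
  m2 <- sum(diff(sp@energy) * (head(sp@density * sp@energy^2, -1) +
                               tail(sp@density * sp@energy^2, -1)) / 2)
  se <- sqrt((m2 - meanEnergy(sp)^2) / n)
  expect_lt(abs(mean(e) - meanEnergy(sp)), 3 * se)
  ## empirical vs tabulated CDF: KS-style sup bound at n = 1e5
  cdfP <- cumsum(c(0, diff(sp@energy) * (head(sp@density, -1) +
                                         tail(sp@density, -1)) / 2))
  tabCdf <- approxfun(sp@energy, cdfP / max(cdfP))
  dks <- max(abs(ecdf(e)(sp@energy) - tabCdf(sp@energy)))
  expect_lt(dks, 1.95 / sqrt(n))  # ~ alpha = 0.001 KS bound
  ## an (effectively) single-bin spectrum concentrates at that energy
  delta <- betaSpectrum(c(499.9, 500, 500.1), c(0, 1, 0))
  expect_true(all(abs(sampleEnergy(delta, 100) - 500) <= 0.1))
})

test_that("water stopping power reproduces reference CSDA ranges", {
  rt <- csdaRangeTable()
  rangeAt <- approxfun(rt$energy_kev, rt$range_mm)
  ## reference CSDA ranges in water (g/cm2 -> mm at unit density)
  expect_equal(rangeAt(100), 0.01431 * 10, tolerance = 0.01)
  expect_equal(rangeAt(1000), 0.4367 * 10, tolerance = 0.01)
  expect_equal(rangeAt(2280), 1.125 * 10, tolerance = 0.015)
})

test_that("transport conserves energy and is deterministic and linear in TIA", {
  w <- waterCube(n = 15, hot = c(8, 8, 8))
  cfg <- transportConfig(nHistories = 2e4, seed = 11, nBatches = 4)
  d1 <- simulateDose(w$tia, w$density, cfg = cfg)
  expect_equal(d1@emittedKeV, d1@depositedKeV + d1@escapedKeV,
               tolerance = 1e-12)
  ## same seed, same config: bitwise identical
  d2 <- simulateDose(w$tia, w$density, cfg = cfg)
  expect_identical(doseValues(d1), doseValues(d2))
  ## scaling TIA scales dose exactly (same seed)
  w3 <- w; w3$tia@values <- w$tia@values * 3.5
  d3 <- simulateDose(w3$tia, w$density, cfg = cfg)
  expect_equal(doseValues(d3), 3.5 * doseValues(d1), tolerance = 1e-12)
  ## zero TIA -> zero dose
  z <- simulateDose(voxelImage(array(0, c(4, 4, 4)), 4.18, unit = "MBq.h"),
                    voxelImage(array(1, c(4, 4, 4)), 4.18, unit = "g/cc"))
  expect_true(all(doseValues(z) == 0))
})

test_that("local deposition dose follows the unit-conversion closed form", {
  sp <- loadY90Spectrum()
  w <- waterCube(n = 5, hot = c(3, 3, 3))
  ld <- localDepositionDose(w$tia, w$density, sp)
  massKg <- 4.18^3 / 1e6
  expected <- 3.6e9 * meanEnergy(sp) * 1.602176634e-16 / massKg * 100
  expect_equal(doseValues(ld)[3, 3, 3], expected, tolerance = 1e-12)
  expect_equal(sum(doseValues(ld) > 0), 1)
  ## halving density doubles dose
  half <- voxelImage(array(0.5, c(5, 5, 5)), 4.18, unit = "g/cc")
  ld2 <- localDepositionDose(w$tia, half, sp)
  expect_equal(doseValues(ld2)[3, 3, 3], 2 * expected, tolerance = 1e-12)
})

test_that("transport matches local deposition in a uniform cube interior", {
  n <- 19
  tia <- voxelImage(array(1e-3, c(n, n, n)), 4.18, unit = "MBq.h")
  dens <- voxelImage(array(1, c(n, n, n)), 4.18, unit = "g/cc")
  core <- array(FALSE, c(n, n, n)); core[7:13, 7:13, 7:13] <- TRUE
  coreMask <- voiMask("core", core, reference = tia)
  d <- simulateDose(tia, dens, cfg = transportConfig(nHistories = 2e5,
                                                     seed = 19),
                    tallyMask = coreMask)
  ld <- localDepositionDose(tia, dens)
  tally <- attr(d, "tally")
  expect_equal(tally$meanDoseCGy, voiMeanDose(d, coreMask, dens),
               tolerance = 1e-6)
  expect_lt(abs(tally$meanDoseCGy - voiMeanDose(ld, coreMask, dens)),
            3 * tally$seDoseCGy + 1e-9)
})

test_that("VOI mean dose is the mass-weighted mean", {
  d <- c(4, 4, 4)
  dens <- voxelImage(array(1, d), 4.18, unit = "g/cc")
  uni <- voxelImage(array(2.5, d), 4.18, unit = "cGy")
  mask <- voiMask("all", array(TRUE, d), reference = dens)
  expect_equal(voiMeanDose(uni, mask, dens), 2.5)
  ## two equal-mass voxels with doses 0 and 2 average to 1
  dv <- array(0, d); dv[1, 1, 1] <- 0; dv[2, 1, 1] <- 2
  m2 <- array(FALSE, d); m2[1:2, 1, 1] <- TRUE
  expect_equal(voiMeanDose(voxelImage(dv, 4.18, unit = "cGy"),
                           voiMask("pair", m2, reference = dens), dens), 1)
  ## heterogeneous density: brute-force energy / mass ratio
  set.seed(40)
  rho <- array(runif(prod(d), 0.2, 2), d)
  dose <- array(runif(prod(d)), d)
  m3 <- array(runif(prod(d)) < 0.5, d); m3[1] <- TRUE
  brute <- sum(dose[m3] * rho[m3]) / sum(rho[m3])
  expect_equal(voiMeanDose(voxelImage(dose, 4.18, unit = "cGy"),
                           voiMask("het", m3, spacing = 4.18),
                           voxelImage(rho, 4.18, unit = "g/cc")), brute)
})

test_that("statistical uncertainty is zero without randomness and shrinks with histories", {
  w <- waterCube(n = 9, tiaValue = 1e-3)
  ld <- localDepositionDose(w$tia, w$density)
  expect_equal(uncertaintyCheck(ld)$maxRelUncertainty, 0)
  u1 <- uncertaintyCheck(simulateDose(w$tia, w$density,
                                      cfg = transportConfig(5e3, seed = 1)))
  u2 <- uncertaintyCheck(simulateDose(w$tia, w$density,
                                      cfg = transportConfig(8e4, seed = 1)))
  expect_true(is.finite(u1$maxRelUncertainty))
  expect_lt(u2$maxRelUncertainty, u1$maxRelUncertainty)
})
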
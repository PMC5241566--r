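test_that("the default phantom builds with all regions present and disjoint", {
  ph <- buildPhantom(defaultPhantomSpec(), buildCt = FALSE)
  lab <- voxelValues(ph$spectLabels)
  ## disjointness is enforced during rasterisation; every region non-empty
  for (i in seq_along(ph$regionNames))
    expect_gt(sum(lab == i), 0, label = ph$regionNames[i])
  expect_length(ph$regionNames, 1 + 8 + 8)
  ## determinism: the phantom is a pure function of its spec
  ph2 <- buildPhantom(defaultPhantomSpec(), buildCt = FALSE)
  expect_identical(lab, voxelValues(ph2$spectLabels))
  ## overlapping organs are rejected
  bad <- defaultPhantomSpec()
  bad$organs$cx[4] <- 0  # liver onto the midline, hits marrow/heart region
  expect_error(buildPhantom(bad, buildCt = FALSE), "overlap")
})

test_that("a water-only phantom has mass = volume", {
  spec <- smallPhantomSpec()
  spec$huBody <- 0
  spec$organs$hu <- 0
  spec$lesions$hu <- 0
  ph <- buildPhantom(spec, buildCt = FALSE)
  body <- voxelValues(ph$spectLabels) > 0
  ct <- ph$spectCt
  mask <- voiMask("body", body, reference = ct)
  m <- voiMass(ct, mask)
  expect_equal(m$mass_g, m$volume_cc)  # 1 g/cc
})

test_that("true activity obeys the kinetic model and mass balance", {
  spec <- smallPhantomSpec()
  ph <- buildPhantom(spec, buildCt = FALSE)
  lam <- log(2) / 67.3
  ## zero activity at injection time
  expect_equal(sum(voxelValues(trueActivity(ph, 0, 185))), 185)
  ## (at t = 0 the explicit regions hold nothing; all in the remainder)
  a0 <- trueActivity(ph, 0, 185)
  lab <- voxelValues(ph$spectLabels)
  liverCode <- match("liver", ph$regionNames)
  expect_equal(sum(voxelValues(a0)[lab == liverCode]), 0)
  ## whole-body activity is injected activity under physical decay alone
  for (t in c(1, 24, 144))
    expect_equal(sum(voxelValues(trueActivity(ph, t, 185))),
                 185 * exp(-lam * t), tolerance = 1e-12)
  ## region activity matches the closed form
  k <- spec$kinetics[spec$kinetics$region == "liver", ]
  for (t in c(5, 48)) {
    truth <- k$fraction * 185 * (exp(-k$lambda_b * t) - exp(-k$lambda_u * t)) *
      exp(-lam * t)
    expect_equal(sum(voxelValues(trueActivity(ph, t, 185))[lab == liverCode]),
                 truth, tolerance = 1e-12)
  }
})

test_that("ground-truth TIA matches fine-grid quadrature of the kinetic model", {
  spec <- smallPhantomSpec()
  ph <- buildPhantom(spec, buildCt = FALSE)
  gt <- groundTruth(ph, 185)
  cst <- decayConstants()
  k <- spec$kinetics[spec$kinetics$region == "liver", ]
  tt <- seq(0, 5000, by = 0.05)
  shape <- exp(-k$lambda_b * tt) - exp(-k$lambda_u * tt)
  for (nuc in c("imaging", "therapy")) {
    lam <- if (nuc == "imaging") cst$lambdaImaging else cst$lambdaTherapy
    quad <- k$fraction * 185 *
      sum(diff(tt) * (head(shape * exp(-lam * tt), -1) +
                      tail(shape * exp(-lam * tt), -1)) / 2)
    col <- paste0("tia_", nuc, "_mbq_h")
    expect_equal(gt[[col]][gt$region == "liver"], quad, tolerance = 1e-6)
  }
  ## faster therapy decay means smaller substituted TIA
  expect_true(all(gt$tia_therapy_mbq_h < gt$tia_imaging_mbq_h))
  ## equilibrium dose is linear in TIA
  expect_equal(gt$dose_eq_cgy_per_mbq / gt$tia_therapy_mbq_h * gt$mass_kg,
               rep((gt$dose_eq_cgy_per_mbq / gt$tia_therapy_mbq_h *
                    gt$mass_kg)[1], nrow(gt)),
               tolerance = 1e-9)
})

test_that("SPECT rendering round trips in the noise-free, blur-free case", {
  spec <- smallPhantomSpec()
  ph <- buildPhantom(spec, buildCt = FALSE)
  act <- trueActivity(ph, 5, 185)
  full <- renderSpect(act, 3e4, psfFwhmMm = 0, fovRange = c(-Inf, Inf),
                      noise = FALSE)
  expect_equal(voxelValues(full) / 3e4, voxelValues(act), tolerance = 1e-12)
  ## Poisson totals stay within 3 SE of the noise-free total
  set.seed(12)
  noisy <- renderSpect(act, 3e4, psfFwhmMm = 0, fovRange = c(-Inf, Inf),
                       noise = TRUE)
  tot <- sum(voxelValues(full))
  expect_lt(abs(sum(voxelValues(noisy)) - tot), 3 * sqrt(tot))
  ## FOV cropping keeps the generator-known activity fraction
  crop <- renderSpect(act, 3e4, psfFwhmMm = 0, fovRange = spec$fovRange,
                      noise = FALSE)
  cz <- voxelCenters(act)[[3]]
  inFov <- cz >= spec$fovRange[1] & cz <= spec$fovRange[2]
  expect_equal(sum(voxelValues(crop)) / sum(voxelValues(full)),
               sum(voxelValues(act)[, , inFov]) / sum(voxelValues(act)),
               tolerance = 1e-12)
  ## blur preserves total counts away from the border
  blurred <- renderSpect(act, 3e4, psfFwhmMm = 8, fovRange = c(-Inf, Inf),
                         noise = FALSE)
  expect_equal(sum(voxelValues(blurred)), sum(voxelValues(full)),
               tolerance = 0.02)
})

test_that("planar projection conserves counts and supports FAF recovery", {
  ## uniform cube projects to a uniform rectangle
  act <- voxelImage(array(1, c(6, 5, 8)), 4, unit = "MBq")
  pl <- renderPlanar(act, 10, noise = FALSE)
  expect_true(all(pl@values == pl@values[1, 1]))
  expect_equal(sum(pl@values), sum(voxelValues(act)) * 10)
  ## a known 70/30 in/out-of-FOV split is recovered by computeFaf
  d <- c(10, 10, 20)
  v <- array(1, d)  # uniform along z: fraction = covered z extent
  act2 <- voxelImage(v, 4, unit = "MBq")  # z extent 0..80 mm
  pl2 <- renderPlanar(act2, 2000, noise = FALSE)
  faf <- computeFaf(pl2, projectFov(pl2, c(0, 0.7 * 80)))
  expect_equal(faf, 0.7, tolerance = 1e-12)
  set.seed(3)
  pl3 <- renderPlanar(act2, 2000, noise = TRUE)
  fafN <- computeFaf(pl3, projectFov(pl3, c(0, 0.7 * 80)))
  expect_equal(fafN, 0.7, tolerance = 0.01)
})

test_that("studies are reproducible from the seed", {
  s1 <- smallStudy(seed = 77, noise = TRUE, psfFwhmMm = 6)
  s2 <- smallStudy(seed = 77, noise = TRUE, psfFwhmMm = 6)
  expect_identical(voxelValues(s1@spect[[4]]), voxelValues(s2@spect[[4]]))
  expect_identical(s1@planar@values, s2@planar@values)
  s3 <- smallStudy(seed = 78, noise = TRUE, psfFwhmMm = 6)
  expect_false(identical(voxelValues(s1@spect[[4]]),
                         voxelValues(s3@spect[[4]])))
})

test_that("lesion constraints are enforced", {
  spec <- smallPhantomSpec()
  spec$lesions$diameter <- 8
  expect_error(do.call(phantomSpec, spec[setdiff(names(spec), "hotspot")]),
               "diameter")
})
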
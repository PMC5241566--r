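test_that("identity deformation leaves images unchanged", {
  img <- randomImage(seed = 11)
  idf <- identityField(img)
  expect_equal(voxelValues(applyDeformation(img, idf, "nearest")),
               voxelValues(img))
  expect_equal(voxelValues(applyDeformation(img, idf, "linear")),
               voxelValues(img), tolerance = 1e-6)
})

test_that("a one-voxel translation displaces a hot voxel by one voxel", {
  d <- c(8, 8, 8); sp <- c(2, 2, 2)
  v <- array(0, d); v[4, 5, 3] <- 1
  img <- voxelImage(v, sp)
  ## pull-back warp: sampling at x + spacing along axis 1 shifts content
  ## to one voxel lower index
  disp <- array(0, c(d, 3)); disp[, , , 1] <- sp[1]
  fld <- deformationField(disp, sp)
  for (interp in c("nearest", "linear")) {
    out <- voxelValues(applyDeformation(img, fld, interp))
    expected <- array(0, d); expected[3, 5, 3] <- 1
    expect_equal(out, expected, tolerance = 1e-12, info = interp)
  }
})

test_that("uniform images are invariant under smooth fields in the interior", {
  d <- c(10, 10, 10)
  img <- voxelImage(array(3.7, d), c(2, 2, 2))
  set.seed(4)
  disp <- array(stats::runif(prod(d) * 3, -1.5, 1.5), c(d, 3))
  out <- voxelValues(applyDeformation(img, deformationField(disp, c(2, 2, 2))))
  expect_equal(out[3:8, 3:8, 3:8], array(3.7, c(6, 6, 6)), tolerance = 1e-9)
})

test_that("deformation requires a matching grid", {
  img <- randomImage()
  bad <- deformationField(array(0, c(dim(img), 3)),
                          spacing = voxelSpacing(img) * 2)
  expect_error(applyDeformation(img, bad), "grid mismatch")
})

test_that("CT averaging is the voxelwise mean and reduces noise ~ 1/sqrt(6)", {
  img <- randomImage(seed = 2, unit = "HU")
  expect_equal(voxelValues(averageCts(rep(list(img), 6))), voxelValues(img))
  a <- voxelImage(array(0, c(4, 4, 4)), unit = "HU")
  b <- voxelImage(array(2, c(4, 4, 4)), unit = "HU")
  expect_equal(voxelValues(averageCts(list(a, b))), array(1, c(4, 4, 4)))
  ## six noisy replicates of one phantom
  set.seed(9)
  d <- c(12, 12, 12)
  truth <- array(100, d)
  reps <- lapply(1:6, function(i)
    voxelImage(truth + array(rnorm(prod(d), sd = 10), d), unit = "HU"))
  av <- averageCts(reps)
  sdOne <- sd(voxelValues(reps[[1]]) - truth)
  sdAv <- sd(voxelValues(av) - truth)
  expect_equal(sdAv / sdOne, 1 / sqrt(6), tolerance = 0.15)
  expect_error(averageCts(list()), "at least one")
})

test_that("HU to density mapping is anchored, interpolated and monotone", {
  expect_equal(huToDensity(0), 1.000)
  expect_equal(huToDensity(-1000), 0.00121)
  ## 60 HU sits between the 40 and 300 HU anchors
  m <- defaultDensityModel()
  expected <- 1.050 + (60 - 40) / (300 - 40) * (1.180 - 1.050)
  expect_equal(huToDensity(60), expected)
  ## clamped at the ends, monotone over the whole domain
  expect_equal(huToDensity(-2000), huToDensity(-1000))
  hu <- seq(-1200, 3200, by = 7)
  expect_true(all(diff(huToDensity(hu)) >= 0))
  expect_error(huToDensity(NaN), "non-finite")
})

test_that("VOI mass integrates density over the mask", {
  ## 1000 voxels of water at the CT spacing: voxel volume 1.19 mm^3
  sp <- c(0.976562, 0.976562, 1.25)
  ct <- voxelImage(array(0, c(10, 10, 10)), sp, unit = "HU")
  mask <- voiMask("cube", array(TRUE, c(10, 10, 10)), reference = ct)
  m <- voiMass(ct, mask)
  expect_equal(m$volume_cc, 1000 * prod(sp) / 1000)
  expect_equal(m$mass_g, 1000 * prod(sp) / 1000)  # water, 1 g/cc
  ## air mass ~ 0
  air <- voxelImage(array(-1000, c(10, 10, 10)), sp, unit = "HU")
  expect_lt(voiMass(air, mask)$mass_g, 0.01 * m$mass_g)
  ## mixed densities match a brute-force per-voxel sum
  set.seed(3)
  huv <- array(stats::runif(1000, -900, 1200), c(10, 10, 10))
  ct2 <- voxelImage(huv, sp, unit = "HU")
  sel <- array(stats::runif(1000) < 0.4, c(10, 10, 10))
  mask2 <- voiMask("blob", sel, reference = ct2)
  brute <- sum(huToDensity(huv[sel])) * prod(sp) / 1000
  expect_equal(voiMass(ct2, mask2)$mass_g, brute)
  ## additive over disjoint masks
  selB <- !sel
  maskB <- voiMask("rest", selB, reference = ct2)
  expect_equal(voiMass(ct2, mask2)$mass_g + voiMass(ct2, maskB)$mass_g,
               sum(huToDensity(huv)) * prod(sp) / 1000)
  expect_error(voiMass(ct2, voiMask("empty", array(FALSE, c(10, 10, 10)),
                                    reference = ct2)), "empty")
})
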
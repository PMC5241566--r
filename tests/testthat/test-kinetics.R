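test_that("VOI curves sum activity and use the population SD", {
  img1 <- voxelImage(array(c(1, 1, 0, 0, 0, 0, 0, 0), c(2, 2, 2)), 4)
  img1@unit <- "MBq"
  img2 <- voxelImage(array(c(0, 2, 0, 0, 0, 0, 0, 0), c(2, 2, 2)), 4)
  img2@unit <- "MBq"
  mask <- voiMask("pair", array(c(TRUE, TRUE, rep(FALSE, 6)), c(2, 2, 2)),
                  reference = img1)
  st <- studySeries(times = c(1, 5), spect = list(img1, img2),
                    masks = list(pair = mask), injectedActivityMBq = 100)
  cv <- voiActivityCurve(st, mask)
  expect_equal(curveActivities(cv), c(2, 2))
  expect_equal(curveSds(cv), c(0, 1))  # population SD of (1,1) and (0,2)
  ## random values match a brute-force sum / SD
  set.seed(6)
  v <- array(stats::runif(8), c(2, 2, 2))
  img3 <- voxelImage(v, 4, unit = "MBq")
  m3 <- array(stats::runif(8) < 0.6, c(2, 2, 2)); m3[1] <- TRUE
  mask3 <- voiMask("rand", m3, reference = img3)
  st3 <- studySeries(times = 1, spect = list(img3), masks = list(),
                     injectedActivityMBq = 1)
  cv3 <- voiActivityCurve(st3, mask3)
  expect_equal(curveActivities(cv3), sum(v[m3]))
  expect_equal(curveSds(cv3), sqrt(mean(v[m3]^2) - mean(v[m3])^2))
})

test_that("tail point selection implements the window and artificial-point rules", {
  t <- c(1, 5, 24, 48, 72, 144)
  ## max early, monotone decrease: last three, no artificial point
  s1 <- selectTailPoints(kineticCurve(t, c(5, 8, 6, 4, 3, 2)))
  expect_equal(s1$indices, 4:6)
  expect_false(s1$artificial)
  ## max at the 4th of 6 points: only the last two
  s2 <- selectTailPoints(kineticCurve(t, c(3, 5, 6, 8, 7, 5)))
  expect_equal(s2$indices, 5:6)
  expect_false(s2$artificial)
  ## activity rising into the last point: artificial point at t_last + 60 h
  ## with half the maximum
  expect_message(
    s3 <- selectTailPoints(kineticCurve(t, c(3, 5, 4, 3, 4, 6))),
    "artificial")
  expect_true(s3$artificial)
  expect_equal(max(s3$times), 144 + 60)
  expect_equal(s3$activities[length(s3$activities)], 3)  # half of max (6)
  expect_error(selectTailPoints(kineticCurve(c(1, 5), c(2, 1))), "at least 3")
})

test_that("two-point tail fits use the closed form", {
  t <- c(72, 144)
  f <- fitMonoexpTail(t, 5 * exp(-0.01 * t))
  expect_equal(f@lambda, 0.01, tolerance = 1e-12)
  expect_equal(f@a0, 5, tolerance = 1e-12)
  ## non-decaying pair falls back to the physical constant, flagged
  g <- fitMonoexpTail(t, c(1, 2))
  expect_true(g@degenerate)
  expect_equal(g@lambda, log(2) / 67.3)
})

test_that("three-point fits recover exact exponentials and match a grid-search oracle", {
  t <- c(48, 72, 144)
  f <- fitMonoexpTail(t, 7 * exp(-0.02 * t))
  expect_equal(f@lambda, 0.02, tolerance = 1e-8)
  expect_equal(f@a0, 7, tolerance = 1e-6)
  ## noisy weighted fit vs dense 2-parameter grid search
  set.seed(17)
  a <- 7 * exp(-0.02 * t) * (1 + rnorm(3, sd = 0.05))
  sds <- c(0.3, 0.2, 0.1)
  fit <- fitMonoexpTail(t, a, sds)
  w <- 1 / pmax(sds, 1e-6 * max(a)); w <- w / max(w)
  lamGrid <- seq(0.005, 0.05, by = 1e-4)
  a0Grid <- seq(3, 12, by = 0.01)
  sse <- outer(a0Grid, lamGrid, function(a0, l)
    w[1] * (a[1] - a0 * exp(-l * t[1]))^2 +
    w[2] * (a[2] - a0 * exp(-l * t[2]))^2 +
    w[3] * (a[3] - a0 * exp(-l * t[3]))^2)
  best <- arrayInd(which.min(sse), dim(sse))
  expect_equal(fit@lambda, lamGrid[best[2]], tolerance = 2e-4 / 0.02)
  expect_equal(fit@a0, a0Grid[best[1]], tolerance = 0.02 / 7 * 2)
})

test_that("TIA integration = trapezoid from zero plus analytic tail", {
  t <- c(1, 5, 24, 48, 72, 144)
  ## all-zero curve integrates to zero
  expect_equal(integrateTia(kineticCurve(t, rep(0, 6)),
                            new("TailFit", a0 = 0, lambda = 0.01,
                                nPointsUsed = 2L, artificialPoint = FALSE,
                                degenerate = FALSE, weights = 1)), 0)
  ## pure exponential: within the trapezoid bias bound (5%) of A0/lambda
  lam <- log(2) / 67.3
  cv <- kineticCurve(t, 10 * exp(-lam * t))
  fit <- fitTail(cv)
  expect_equal(integrateTia(cv, fit), 10 / lam, tolerance = 0.05)
  ## triangle curve with zero tail equals fine-grid quadrature
  t2 <- c(10, 20, 30)
  a2 <- c(5, 10, 0)
  cv2 <- kineticCurve(t2, a2)
  fit2 <- new("TailFit", a0 = 1e-12, lambda = 1, nPointsUsed = 2L,
              artificialPoint = FALSE, degenerate = FALSE, weights = 1)
  tt <- seq(0, 30, by = 1e-3)
  aa <- approx(c(0, t2), c(0, a2), xout = tt)$y
  quad <- sum(diff(tt) * (head(aa, -1) + tail(aa, -1)) / 2)
  expect_equal(integrateTia(cv2, fit2), quad, tolerance = 1e-6)
})

test_that("TIA is linear in the activity scale", {
  t <- c(1, 5, 24, 48, 72, 144)
  set.seed(23)
  for (i in 1:5) {
    a <- cumsum(runif(6, 0, 2))[6:1] # decreasing positive curve
    cv <- kineticCurve(t, a)
    k <- runif(1, 0.1, 30)
    cvk <- kineticCurve(t, k * a)
    expect_equal(integrateTia(cvk, fitTail(cvk)),
                 k * integrateTia(cv, fitTail(cv)), tolerance = 1e-8)
  }
})

test_that("decay substitution re-decays the biological curve", {
  t <- c(1, 5, 24, 48, 72, 144)
  cst <- decayConstants()
  ## equal half-lives: identity
  same <- decayConstants(67.3, 67.3)
  cv <- kineticCurve(t, 10 * exp(-0.02 * t))
  expect_equal(curveActivities(substituteDecay(cv, same)),
               curveActivities(cv))
  ## pure imaging-radionuclide physical decay becomes pure therapy decay
  cvIn <- kineticCurve(t, 10 * exp(-cst$lambdaImaging * t))
  out <- substituteDecay(cvIn, cst)
  expect_equal(curveActivities(out), 10 * exp(-cst$lambdaTherapy * t),
               tolerance = 1e-12)
  ## bi-exponential: substituted TIA equals quadrature of the analytically
  ## substituted curve
  lu <- 0.3; lb <- 0.01
  bio <- function(tt) 4 * (exp(-lb * tt) - exp(-lu * tt))
  cvB <- kineticCurve(t, bio(t) * exp(-cst$lambdaImaging * t))
  sub <- substituteDecay(cvB, cst)
  expect_equal(curveActivities(sub), bio(t) * exp(-cst$lambdaTherapy * t),
               tolerance = 1e-12)
  fit <- fitTail(sub, lambdaFallback = cst$lambdaTherapy)
  tia <- integrateTia(sub, fit)
  tt <- seq(0, 2000, by = 0.01)
  quad <- sum(diff(tt) * (head(bio(tt) * exp(-cst$lambdaTherapy * tt), -1) +
                          tail(bio(tt) * exp(-cst$lambdaTherapy * tt), -1)) / 2)
  expect_equal(tia, quad, tolerance = 0.05)  # trapezoid bias bound
})

test_that("effective half-life inverts the decay constant", {
  expect_equal(effectiveHalfLife(log(2) / 67.3), 67.3)
  expect_equal(effectiveHalfLife(0.0693147), 10, tolerance = 1e-4)
  ## biological 100 h on top of In-111 physical: 1/T = 1/100 + 1/67.3
  t <- c(24, 48, 72, 144)
  lam <- log(2) / 100 + log(2) / 67.3
  f <- fitMonoexpTail(t, 3 * exp(-lam * t))
  expect_equal(1 / effectiveHalfLife(f), 1 / 100 + 1 / 67.3,
               tolerance = 1e-8)
  expect_error(effectiveHalfLife(-0.1), "positive")
})

test_that("peak curves locate and track a stable hot spot", {
  expect_equal(peakKernelRadius(1), (3000 / (4 * pi))^(1/3), tolerance = 1e-12)
  ## homogeneous activity: peak curve equals the mask mean curve
  img <- voxelImage(array(2, c(12, 12, 12)), 4.18, unit = "MBq")
  mask <- voiMask("blob", array(TRUE, c(12, 12, 12)), reference = img)
  st <- studySeries(times = c(1, 5, 24), spect = list(img, img, img),
                    masks = list(blob = mask), injectedActivityMBq = 1)
  pk <- peakCurve(st, mask)
  expect_equal(curveActivities(pk$curve), rep(2, 3))
  ## single hot sphere: centre recovered within one voxel at every time
  d <- c(16, 16, 16); sp <- c(4, 4, 4)
  ctr <- c(34, 30, 38)  # mm
  cx <- lapply(1:3, function(a) (seq_len(16) - 0.5) * 4)
  dist2 <- outer(outer((cx[[1]] - ctr[1])^2, (cx[[2]] - ctr[2])^2, `+`),
                 (cx[[3]] - ctr[3])^2, `+`)
  hot <- array(0, d); hot[dist2 <= 10^2] <- 5
  frames <- lapply(c(1, 0.8, 0.5), function(s)
    voxelImage(hot * s, sp, unit = "MBq"))
  maskAll <- voiMask("les", array(TRUE, d), spacing = sp)
  st2 <- studySeries(times = c(1, 24, 72), spect = frames,
                     masks = list(), injectedActivityMBq = 1)
  pk2 <- peakCurve(st2, maskAll)
  expect_true(all(abs(pk2$center - ctr) <= 4))
  expect_lt(pk2$centerSdMm, 1e-9)  # identical argmax at all times
  ## a mask smaller than the peak sphere falls back with a warning
  tiny <- array(FALSE, d); tiny[8, 8, 8] <- TRUE
  expect_warning(peakCurve(st2, voiMask("tiny", tiny, spacing = sp)),
                 "smaller")
})

test_that("peak centre stays stable under noise (SD of argmax positions ~ 5 mm)", {
  spec <- smallPhantomSpec()
  spec$hotspot <- list(region = "liver", gainFrac = 3, sigmaMm = 10)
  study <- synthesizeStudy(spec, seed = 27, noise = TRUE, psfFwhmMm = 8)
  cal <- calibrateStudy(study)
  pk <- peakCurve(cal$study, cal$study@masks$liver)
  expect_lt(pk$centerSdMm, 8)
})
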
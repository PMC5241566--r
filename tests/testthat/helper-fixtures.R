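# Fixtures shared across test files; everything is generated in code.

# compact two-organ + one-lesion phantom for fast end-to-end runs
smallPhantomSpec <- function() {
  phantomSpec(
    bodySemiAxes = c(60, 50, 80),
    organs = data.frame(
      name = c("liver", "heart"),
      cx = c(18, 0), cy = c(5, 0), cz = c(-25, 28),
      rx = c(22, 15), ry = c(18, 15), rz = c(16, 15),
      hu = c(50, 45)),
    lesions = data.frame(name = "lesion_1", cx = -20, cy = -10, cz = 5,
                         diameter = 12, hu = 30),
    kinetics = data.frame(
      region = c("liver", "heart", "lesion_1"),
      lambda_u = c(0.2, 3.0, 0.065),
      lambda_b = c(0.0045, 0.012, 0.004),
      fraction = c(0.25, 0.08, 0.004)),
    fovRange = c(-60, 60))
}

smallStudy <- function(seed = 5, noise = FALSE, psfFwhmMm = 0, ...) {
  synthesizeStudy(smallPhantomSpec(), seed = seed, noise = noise,
                  psfFwhmMm = psfFwhmMm, ...)
}

randomImage <- function(d = c(6, 7, 8), spacing = c(2, 2, 2.5), seed = 1,
                        unit = "arb") {
  set.seed(seed)
  voxelImage(array(stats::runif(prod(d)), d), spacing, unit = unit)
}

# uniform water cube with a single hot voxel or uniform TIA
waterCube <- function(n = 25, spacing = 4.18, tiaValue = 0, hot = NULL) {
  tia <- array(tiaValue, c(n, n, n))
  if (!is.null(hot)) tia[hot[1], hot[2], hot[3]] <- 1
  list(tia = voxelImage(tia, spacing, unit = "MBq.h"),
       density = voxelImage(array(1, c(n, n, n)), spacing, unit = "g/cc"))
}
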
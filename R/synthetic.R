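## Synthetic study generator.
##
## Produces complete studies with known ground truth: an ellipsoidal
## torso phantom with organs (liver, spleen, heart/mediastinal blood
## pool, kidneys, L2-L4 vertebral bone marrow, lungs) and spherical lung
## lesions; region-constant bi-phasic uptake-washout kinetics modulated
## by the imaging radionuclide's physical decay; SPECT-like count images
## (system blur, limited axial FOV, Poisson counting noise) and a
## whole-body planar projection. Regionwise kinetics are piecewise
## constant so TIA, effective half-life and equilibrium dose have closed
## forms.

#' Phantom and kinetics specification
#'
#' @param bodySemiAxes torso ellipsoid semi-axes, mm (x, y, z).
#' @param organs data.frame: name, cx, cy, cz (centre mm), rx, ry, rz
#'   (semi-axes mm), hu, and optionally quantify (logical; FALSE marks a
#'   region that shapes anatomy, kinetics and density but is not a
#'   quantified VOI -- the lungs, which only host lesions).
#' @param lesions data.frame: name, cx, cy, cz, diameter (mm, >= 10), hu.
#'   At most 25 lesions.
#' @param kinetics data.frame: region (matching organ/lesion names),
#'   lambda_u (uptake rate 1/h), lambda_b (biological clearance 1/h),
#'   fraction (amplitude as a fraction of the injected activity). Region
#'   activity is
#'   A_r(t) = fraction * A_inj * (exp(-lambda_b t) - exp(-lambda_u t)) *
#'   exp(-lambda_phys t). The body remainder is the mass-balance
#'   complement: whatever the explicit regions do not hold stays in the
#'   circulating remainder, so the whole-body activity is always the
#'   injected activity under physical decay alone (the tracer is not
#'   excreted, matching acquisition before urination at the calibration
#'   time point).
#' @param ctSpacing,spectSpacing grid spacings, mm.
#' @param fovRange axial SPECT field-of-view extent, mm.
#' @param huBody soft-tissue background HU inside the body.
#' @param hotspot optional list(region, gainFrac, sigmaMm): multiply that
#'   region's concentration by a Gaussian bump (total preserved), for
#'   peak-localisation tests.
#' @return a \code{PhantomSpec} (validated list).
#' @export
phantomSpec <- function(bodySemiAxes, organs, lesions, kinetics,
                        ctSpacing = c(0.976562, 0.976562, 1.25),
                        spectSpacing = c(4.18, 4.18, 4.18),
                        fovRange, huBody = 20, hotspot = NULL) {
  stopifnot(length(bodySemiAxes) == 3L, all(bodySemiAxes > 0),
            length(fovRange) == 2L, fovRange[1] < fovRange[2])
  if (nrow(lesions) > 25L) stop("at most 25 lesions")
  if (nrow(lesions) && any(lesions$diameter < 10))
    stop("lesions must have diameter >= 10 mm")
  if (is.null(organs$quantify)) organs$quantify <- TRUE
  need <- c(organs$name, lesions$name)
  if (!all(need %in% kinetics$region))
    stop("kinetics must cover every organ and lesion")
  if ("remainder" %in% kinetics$region)
    stop("the body remainder is implicit (mass-balance complement); do not specify kinetics for it")
  if (any(kinetics$lambda_u <= kinetics$lambda_b))
    stop("uptake rate must exceed clearance rate for every region")
  if (sum(kinetics$fraction) > 1)
    stop("kinetic amplitude fractions exceed the injected activity")
  structure(list(bodySemiAxes = bodySemiAxes, organs = organs,
                 lesions = lesions, kinetics = kinetics,
                 ctSpacing = ctSpacing, spectSpacing = spectSpacing,
                 fovRange = fovRange, huBody = huBody, hotspot = hotspot),
            class = "PhantomSpec")
}

#' Default phantom: a torso with six organs, lungs and eight lung lesions
#'
#' Geometry is a compact adult-torso ellipsoid (semi-axes 95 x 70 x 160
#' mm); the axial FOV covers the organs but not the caudal end of the
#' body, so a known fraction of activity stays outside the SPECT FOV.
#' Kinetics emulate antibody biodistribution: liver uptake peaking
#' between 1 and 24 h, fast blood-pool clearance from the heart, lesions
#' peaking around 24-48 h, and a slowly clearing body remainder.
#'
#' @return a \code{PhantomSpec}.
#' @export
defaultPhantomSpec <- function() {
  organs <- data.frame(
    name = c("lung_right", "lung_left", "heart", "liver", "spleen",
             "kidney_right", "kidney_left", "marrow_L2L4"),
    cx = c( 48, -48,  0, 40, -55,  35, -35,   0),
    cy = c( -5,  -5,  0,  0,   5, -40, -40, -40),
    cz = c( 65,  65, 80, -25, -25, -70, -70, -50),
    rx = c( 26,  26, 20, 45,  25,  15,  15,  14),
    ry = c( 34,  34, 30, 40,  30,  12,  12,  12),
    rz = c( 52,  52, 35, 35,  30,  26,  26,  35),
    hu = c(-700, -700, 45, 50, 45, 40, 40, 700),
    quantify = c(FALSE, FALSE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE))
  lesions <- data.frame(
    name = paste0("lesion_", 1:8),
    cx = c( 48,  54,  38,  44, -48, -54, -38, -44),
    cy = c( -8,   5, -15,  10,  -8,   5, -15,  12),
    cz = c( 95,  50,  65,  30,  95,  50,  65,  28),
    diameter = c(12, 16, 20, 24, 14, 18, 22, 28),
    hu = rep(30, 8))
  kinetics <- data.frame(
    region = c(organs$name, lesions$name),
    lambda_u = c(2.0, 2.0, 3.0, 0.20, 1.2, 1.5, 1.5, 1.0,
                 rep(0.065, 8)),
    lambda_b = c(0.010, 0.010, 0.012, 0.0045, 0.007, 0.009, 0.009, 0.008,
                 c(0.004, 0.003, 0.005, 0.006, 0.004, 0.005, 0.003, 0.004)),
    fraction = c(0.020, 0.020, 0.080, 0.250, 0.030, 0.020, 0.020, 0.040,
                 c(0.0042, 0.0022, 0.0018, 0.00175, 0.00165, 0.0020,
                   0.0007, 0.0006)))
  phantomSpec(bodySemiAxes = c(95, 70, 160), organs = organs,
              lesions = lesions, kinetics = kinetics,
              fovRange = c(-110, 150))
}

## ellipsoid membership over a bounding-box subgrid; returns linear indices
.ellipsoidIdx <- function(cx, cy, cz, rx, ry, rz, centers, d) {
  ix <- which(abs(centers[[1]] - cx) <= rx)
  iy <- which(abs(centers[[2]] - cy) <= ry)
  iz <- which(abs(centers[[3]] - cz) <= rz)
  if (!length(ix) || !length(iy) || !length(iz)) return(integer(0))
  qx <- ((centers[[1]][ix] - cx) / rx)^2
  qy <- ((centers[[2]][iy] - cy) / ry)^2
  qz <- ((centers[[3]][iz] - cz) / rz)^2
  q <- outer(outer(qx, qy, `+`), qz, `+`)
  sub <- which(q <= 1)
  if (!length(sub)) return(integer(0))
  a <- arrayInd(sub, c(length(ix), length(iy), length(iz)))
  (iz[a[, 3]] - 1) * d[1] * d[2] + (iy[a[, 2]] - 1) * d[1] + ix[a[, 1]]
}

## label volume on a grid; labels: 0 outside body, 1 body remainder,
## then organs, then lesions (lesions overwrite lungs)
.labelVolume <- function(spec, spacing) {
  b <- spec$bodySemiAxes
  d <- pmax(ceiling(2 * b / spacing), 1)
  origin <- -d * spacing / 2
  centers <- lapply(1:3, function(a) origin[a] + (seq_len(d[a]) - 0.5) * spacing[a])
  lab <- integer(prod(d))
  bodyIdx <- .ellipsoidIdx(0, 0, 0, b[1], b[2], b[3], centers, d)
  lab[bodyIdx] <- 1L
  names <- c("remainder", spec$organs$name, spec$lesions$name)
  lungCodes <- 1L + which(spec$organs$name %in% c("lung_right", "lung_left"))
  for (r in seq_len(nrow(spec$organs))) {
    o <- spec$organs[r, ]
    idx <- .ellipsoidIdx(o$cx, o$cy, o$cz, o$rx, o$ry, o$rz, centers, d)
    clash <- lab[idx] > 1L
    if (any(clash))
      stop(sprintf("organ '%s' overlaps '%s'", o$name,
                   names[lab[idx][which(clash)[1]]]))
    if (!all(lab[idx] == 1L))
      stop(sprintf("organ '%s' extends outside the body", o$name))
    lab[idx] <- 1L + r
  }
  nOrg <- nrow(spec$organs)
  for (r in seq_len(nrow(spec$lesions))) {
    l <- spec$lesions[r, ]
    rad <- l$diameter / 2
    idx <- .ellipsoidIdx(l$cx, l$cy, l$cz, rad, rad, rad, centers, d)
    if (any(!lab[idx] %in% c(1L, lungCodes)))
      stop(sprintf("lesion '%s' overlaps an organ other than lung", l$name))
    if (any(lab[idx] == 0L))
      stop(sprintf("lesion '%s' extends outside the body", l$name))
    lab[idx] <- 1L + nOrg + r
  }
  list(labels = array(lab, d), spacing = spacing, origin = origin,
       names = names)
}

#' Build the phantom CT and region labels
#'
#' @param spec a \code{PhantomSpec}.
#' @param buildCt if TRUE (default) also rasterise the full-resolution CT
#'   and its label volume at the CT grid.
#' @return list with \code{spectLabels} (full-body label
#'   \linkS4class{VoxelImage} at SPECT spacing), \code{regionNames}
#'   (label value i + 1 corresponds to \code{regionNames[i + 1]}; 0 is
#'   outside the body), and, when \code{buildCt}, \code{ct} (HU
#'   \linkS4class{VoxelImage} at CT spacing) and \code{ctLabels}.
#' @export
buildPhantom <- function(spec, buildCt = TRUE) {
  sl <- .labelVolume(spec, spec$spectSpacing)
  out <- list(
    spec = spec,
    spectLabels = voxelImage(sl$labels + 0, sl$spacing, sl$origin, "arb"),
    regionNames = sl$names)
  if (buildCt) {
    cl <- .labelVolume(spec, spec$ctSpacing)
    out$ctLabels <- voxelImage(cl$labels + 0, cl$spacing, cl$origin, "arb")
    out$ct <- voxelImage(.labelsToHu(cl$labels, spec), cl$spacing,
                         cl$origin, "HU")
  }
  out$spectCt <- voxelImage(.labelsToHu(sl$labels, spec), sl$spacing,
                            sl$origin, "HU")
  out
}

.labelsToHu <- function(labels, spec) {
  huByCode <- c(-1000, spec$huBody, spec$organs$hu, spec$lesions$hu)
  array(huByCode[labels + 1L], dim(labels))
}

#' Extract VOI masks from a phantom label image
#'
#' @param labelImage label \linkS4class{VoxelImage} from
#'   \code{\link{buildPhantom}} (or a cropped version of it).
#' @param regionNames the phantom's region name vector.
#' @param which region names wanted (default all organs and lesions,
#'   not the remainder).
#' @return named list of \linkS4class{VOIMask}.
#' @export
phantomMasks <- function(labelImage, regionNames,
                         which = setdiff(regionNames, "remainder")) {
  codes <- match(which, regionNames)
  out <- lapply(seq_along(which), function(i) {
    voiMask(which[i], labelImage@values == codes[i], reference = labelImage)
  })
  names(out) <- which
  out
}

#' Regionwise true activity image at time t
#'
#' Region-constant activity concentration from the bi-phasic kinetic
#' model, modulated by physical decay; closed-form ground truth is
#' available for its time integral.
#'
#' @param phantom from \code{\link{buildPhantom}}.
#' @param t time, h post injection.
#' @param injectedActivityMBq injected activity.
#' @param lambdaPhys physical decay constant, 1/h (In-111 default).
#' @return \linkS4class{VoxelImage} in MBq per voxel on the full-body
#'   SPECT-spacing grid.
#' @export
trueActivity <- function(phantom, t, injectedActivityMBq,
                         lambdaPhys = log(2) / 67.3) {
  stopifnot(t >= 0)
  spec <- phantom$spec
  lab <- phantom$spectLabels@values
  kin <- spec$kinetics
  concByCode <- numeric(length(phantom$regionNames) + 1L)  # MBq per voxel
  totalMBq <- injectedActivityMBq * exp(-lambdaPhys * t)
  explicit <- 0
  for (i in seq_along(phantom$regionNames)) {
    rn <- phantom$regionNames[i]
    k <- kin[kin$region == rn, ]
    if (!nrow(k)) next
    nvox <- sum(lab == i)
    if (nvox == 0) next
    A <- k$fraction * injectedActivityMBq *
      (exp(-k$lambda_b * t) - exp(-k$lambda_u * t)) * exp(-lambdaPhys * t)
    explicit <- explicit + A
    concByCode[i + 1L] <- A / nvox
  }
  ## circulating remainder: mass-balance complement
  remCode <- match("remainder", phantom$regionNames)
  nRem <- sum(lab == remCode)
  concByCode[remCode + 1L] <- max(totalMBq - explicit, 0) / nRem
  act <- array(concByCode[lab + 1L], dim(lab))
  hs <- spec$hotspot
  if (!is.null(hs)) {
    code <- match(hs$region, phantom$regionNames)
    sel <- which(lab == code)
    if (length(sel)) {
      ctr <- .regionCentroid(phantom$spectLabels, sel)
      cx <- voxelCenters(phantom$spectLabels)
      ijk <- arrayInd(sel, dim(lab))
      d2 <- (cx[[1]][ijk[, 1]] - ctr[1])^2 + (cx[[2]][ijk[, 2]] - ctr[2])^2 +
            (cx[[3]][ijk[, 3]] - ctr[3])^2
      g <- 1 + hs$gainFrac * exp(-d2 / (2 * hs$sigmaMm^2))
      act[sel] <- act[sel] * g * (sum(act[sel]) / sum(act[sel] * g))
    }
  }
  voxelImage(act, phantom$spectLabels@spacing, phantom$spectLabels@origin,
             "MBq")
}

.regionCentroid <- function(labelImage, sel) {
  ijk <- arrayInd(sel, dim(labelImage@values))
  labelImage@origin + (colMeans(ijk) - 0.5) * labelImage@spacing
}

## separable Gaussian blur, zero-padded
.gaussBlur3d <- function(arr, spacing, fwhmMm) {
  if (fwhmMm <= 0) return(arr)
  sigma <- fwhmMm / (2 * sqrt(2 * log(2)))
  d <- dim(arr)
  for (ax in 1:3) {
    sv <- sigma / spacing[ax]
    hw <- max(1L, ceiling(3 * sv))
    kern <- exp(-((-hw):hw)^2 / (2 * sv^2))
    kern <- kern / sum(kern)
    acc <- array(0, d)
    for (o in (-hw):hw) {
      w <- kern[o + hw + 1L]
      src <- max(1, 1 - o):min(d[ax], d[ax] - o)
      dst <- src + o
      if (ax == 1) acc[dst, , ] <- acc[dst, , ] + w * arr[src, , ]
      else if (ax == 2) acc[, dst, ] <- acc[, dst, ] + w * arr[, src, ]
      else acc[, , dst] <- acc[, , dst] + w * arr[, , src]
    }
    arr <- acc
  }
  arr
}

## crop a full-body SPECT-grid image to the axial FOV
.cropToFov <- function(image, fovRange) {
  cz <- voxelCenters(image)[[3]]
  keep <- which(cz >= fovRange[1] & cz <= fovRange[2])
  if (!length(keep)) stop("FOV does not intersect the image")
  newOrigin <- image@origin
  newOrigin[3] <- image@origin[3] + (keep[1] - 1) * image@spacing[3]
  voxelImage(image@values[, , keep, drop = FALSE], image@spacing, newOrigin,
             image@unit)
}

#' Render a SPECT-like count image
#'
#' Gaussian system blur, multiplication by the calibration factor, crop
#' to the axial FOV, optional Poisson counting noise. With blur off,
#' noise off and a full FOV, counts / cf recovers the activity exactly.
#'
#' @param activity \linkS4class{VoxelImage} in MBq (full-body grid).
#' @param calibFactor counts per MBq.
#' @param psfFwhmMm system resolution as Gaussian FWHM, mm.
#' @param fovRange axial FOV, mm.
#' @param noise Poisson noise on/off (uses R's RNG stream).
#' @return \linkS4class{VoxelImage} in counts on the FOV-cropped grid.
#' @export
renderSpect <- function(activity, calibFactor, psfFwhmMm = 10,
                        fovRange = c(-Inf, Inf), noise = TRUE) {
  stopifnot(all(activity@values >= 0), calibFactor > 0)
  v <- .gaussBlur3d(activity@values, activity@spacing, psfFwhmMm)
  img <- voxelImage(v * calibFactor, activity@spacing, activity@origin,
                    "counts")
  img <- .cropToFov(img, fovRange)
  if (noise)
    img@values <- array(as.numeric(stats::rpois(length(img@values),
                                                img@values)),
                        dim(img@values))
  img
}

#' Render a whole-body planar projection
#'
#' Sum projection of the full-body activity along the anteroposterior
#' axis (y), scaled to counts; optional Poisson noise. Total planar
#' counts equal total volumetric counts in the noise-free case.
#'
#' @param activity \linkS4class{VoxelImage} in MBq (full-body grid).
#' @param calibFactor planar counts per MBq.
#' @param noise Poisson on/off.
#' @return \linkS4class{PlanarImage}; rows run along x, columns along the
#'   body (z) axis.
#' @export
renderPlanar <- function(activity, calibFactor = 50, noise = TRUE) {
  stopifnot(all(activity@values >= 0), calibFactor > 0)
  proj <- apply(activity@values, c(1, 3), sum) * calibFactor
  if (noise)
    proj <- matrix(as.numeric(stats::rpois(length(proj), proj)),
                   nrow(proj), ncol(proj))
  planarImage(proj, activity@spacing[c(1, 3)], activity@origin[c(1, 3)],
              axialAxis = 2L)
}

#' Closed-form ground truth for a phantom
#'
#' Per region: time-integrated activity for the imaging radionuclide and
#' with the therapy radionuclide's decay substituted
#' (TIA = K [1/(lambda_b + lambda_phys) - 1/(lambda_u + lambda_phys)]),
#' the effective tail half-life ln 2 / (lambda_b + lambda_phys), and the
#' equilibrium (local-deposition) absorbed dose per injected MBq.
#'
#' @param phantom from \code{\link{buildPhantom}}.
#' @param injectedActivityMBq injected activity.
#' @param constants decay constants of the theranostic pair.
#' @param spectrum beta spectrum used for the equilibrium dose.
#' @param model density model for region mass.
#' @return data.frame keyed by region.
#' @export
groundTruth <- function(phantom, injectedActivityMBq,
                        constants = decayConstants(),
                        spectrum = loadY90Spectrum(),
                        model = defaultDensityModel()) {
  spec <- phantom$spec
  kin <- spec$kinetics
  lab <- phantom$spectLabels@values
  vcc <- prod(phantom$spectLabels@spacing) / 1000
  huByCode <- c(-1000, spec$huBody, spec$organs$hu, spec$lesions$hu)
  doseEq <- function(tiaY, massKg) {
    if (massKg <= 0) return(NA_real_)
    (tiaY / injectedActivityMBq) * .DECAYS_PER_MBQ_H * spectrum@meanEnergy *
      .JOULE_PER_KEV / massKg * 100
  }
  rows <- lapply(seq_len(nrow(kin)), function(r) {
    k <- kin[r, ]
    code <- match(k$region, phantom$regionNames)
    nvox <- sum(lab == code)
    K <- k$fraction * injectedActivityMBq
    tiaOf <- function(lp) K * (1 / (k$lambda_b + lp) - 1 / (k$lambda_u + lp))
    massKg <- nvox * vcc * huToDensity(huByCode[code + 1L], model) / 1000
    data.frame(region = k$region, n_voxels = nvox,
               volume_cc = nvox * vcc, mass_kg = massKg,
               tia_imaging_mbq_h = tiaOf(constants$lambdaImaging),
               tia_therapy_mbq_h = tiaOf(constants$lambdaTherapy),
               t_eff_h = log(2) / (k$lambda_b + constants$lambdaImaging),
               dose_eq_cgy_per_mbq = doseEq(tiaOf(constants$lambdaTherapy),
                                            massKg))
  })
  out <- do.call(rbind, rows)
  ## circulating remainder: complement of the explicit regions
  remCode <- match("remainder", phantom$regionNames)
  nRem <- sum(lab == remCode)
  remTia <- function(lp) injectedActivityMBq / lp - sum(vapply(
    seq_len(nrow(kin)), function(r) {
      k <- kin[r, ]
      k$fraction * injectedActivityMBq *
        (1 / (k$lambda_b + lp) - 1 / (k$lambda_u + lp))
    }, 0))
  remMassKg <- nRem * vcc * huToDensity(spec$huBody, model) / 1000
  remY <- remTia(constants$lambdaTherapy)
  rbind(out, data.frame(
    region = "remainder", n_voxels = nRem, volume_cc = nRem * vcc,
    mass_kg = remMassKg,
    tia_imaging_mbq_h = remTia(constants$lambdaImaging),
    tia_therapy_mbq_h = remY,
    t_eff_h = log(2) / constants$lambdaImaging,
    dose_eq_cgy_per_mbq = doseEq(remY, remMassKg)))
}

#' Synthesize a complete study
#'
#' Builds the phantom, renders the six SPECT frames and the 1 h planar
#' image, assembles VOI masks on the FOV grid and attaches the analytic
#' ground truth. All randomness flows from \code{seed}.
#'
#' @param spec a \code{PhantomSpec} (default \code{defaultPhantomSpec()}).
#' @param seed RNG seed; identical seeds give identical studies.
#' @param times acquisition times, h (default 1, 5, 24, 48, 72, 144).
#' @param injectedActivityMBq injected activity (default 185 MBq).
#' @param calibFactor true SPECT counts per MBq (default 3e4).
#' @param planarCalibFactor planar counts per MBq (default 50).
#' @param psfFwhmMm system blur FWHM (default 10 mm; 0 disables).
#' @param noise Poisson counting noise on/off.
#' @param timeJitterH uniform jitter half-width added to the nominal
#'   times (robustness experiments; default 0).
#' @param lambdaPhys imaging radionuclide decay constant.
#' @return A \linkS4class{StudySeries} (SPECT frames in counts) whose
#'   \code{meta} carries the ground truth (\code{groundTruth} data.frame,
#'   true FAF, true calibration factor, seed).
#' @export
synthesizeStudy <- function(spec = defaultPhantomSpec(), seed = 1L,
                            times = c(1, 5, 24, 48, 72, 144),
                            injectedActivityMBq = 185,
                            calibFactor = 3e4, planarCalibFactor = 50,
                            psfFwhmMm = 10, noise = TRUE, timeJitterH = 0,
                            lambdaPhys = log(2) / 67.3) {
  set.seed(seed)
  if (timeJitterH > 0)
    times <- sort(times + stats::runif(length(times), -timeJitterH,
                                       timeJitterH))
  phantom <- buildPhantom(spec, buildCt = FALSE)
  spect <- vector("list", length(times))
  planar <- NULL
  fafTrue <- NA_real_
  for (i in seq_along(times)) {
    act <- trueActivity(phantom, times[i], injectedActivityMBq, lambdaPhys)
    spect[[i]] <- renderSpect(act, calibFactor, psfFwhmMm, spec$fovRange,
                              noise)
    if (i == 1L) {
      planar <- renderPlanar(act, planarCalibFactor, noise)
      cz <- voxelCenters(act)[[3]]
      inFov <- cz >= spec$fovRange[1] & cz <= spec$fovRange[2]
      fafTrue <- sum(act@values[, , inFov]) / sum(act@values)
    }
  }
  fovLabels <- .cropToFov(phantom$spectLabels, spec$fovRange)
  quantified <- c(spec$organs$name[spec$organs$quantify], spec$lesions$name)
  masks <- phantomMasks(fovLabels, phantom$regionNames, quantified)
  ctFov <- .cropToFov(phantom$spectCt, spec$fovRange)
  gt <- groundTruth(phantom, injectedActivityMBq)
  studySeries(times = times, spect = spect, ct = ctFov, planar = planar,
              masks = masks, injectedActivityMBq = injectedActivityMBq,
              fovRange = spec$fovRange,
              meta = list(groundTruth = gt, fafTrue = fafTrue,
                          calibFactorTrue = calibFactor, seed = seed,
                          psfFwhmMm = psfFwhmMm, noise = noise,
                          regionNames = phantom$regionNames,
                          lambdaPhys = lambdaPhys))
}
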
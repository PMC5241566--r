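## Central S4 data model.
##
## Coordinate convention used everywhere in the package: images are
## axis-aligned, voxel (i, j, k) (1-based) has its centre at
## origin + (index - 0.5) * spacing, in mm.

.VALID_UNITS <- c("counts", "HU", "MBq", "MBq.h", "cGy", "g/cc", "%IA/kg", "arb")

#' VoxelImage: a 3D scalar grid with physical geometry
#'
#' The workhorse container of the package. Depending on the pipeline stage
#' the voxel values are SPECT counts, CT Hounsfield units, activity (MBq),
#' time-integrated activity (MBq h) or absorbed dose (cGy).
#'
#' @slot values 3D numeric array.
#' @slot spacing voxel size in mm per axis (length 3, strictly positive).
#' @slot origin position (mm) of the grid corner; the centre of voxel
#'   (1,1,1) is at \code{origin + 0.5 * spacing}.
#' @slot unit one of \code{"counts", "HU", "MBq", "MBq.h", "cGy", "g/cc",
#'   "\%IA/kg", "arb"}.
#'
#' @export
setClass("VoxelImage",
  representation(values = "array", spacing = "numeric",
                 origin = "numeric", unit = "character"))

setValidity("VoxelImage", function(object) {
  msg <- NULL
  if (length(dim(object@values)) != 3L)
    msg <- c(msg, "'values' must be a 3D array")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    msg <- c(msg, "'spacing' must be 3 strictly positive finite values (mm)")
  if (length(object@origin) != 3L || any(!is.finite(object@origin)))
    msg <- c(msg, "'origin' must be 3 finite values (mm)")
  if (anyNA(object@values) || any(is.infinite(object@values)))
    msg <- c(msg, "voxel values must be finite")
  if (length(object@unit) != 1L || !object@unit %in% .VALID_UNITS)
    msg <- c(msg, sprintf("'unit' must be one of: %s",
                          paste(.VALID_UNITS, collapse = ", ")))
  if (is.null(msg)) TRUE else msg
})

#' Construct a VoxelImage
#'
#' @param values 3D numeric array.
#' @param spacing voxel size in mm (length 3 or scalar, recycled).
#' @param origin grid corner in mm (length 3 or scalar, recycled).
#' @param unit value unit tag.
#' @return A \linkS4class{VoxelImage}.
#' @examples
#' img <- voxelImage(array(0, c(4, 4, 4)), spacing = 4.18, unit = "MBq")
#' voxelVolumeCc(img)
#' @export
voxelImage <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                       unit = "arb") {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (length(origin) == 1L) origin <- rep(origin, 3L)
  storage.mode(values) <- "double"
  new("VoxelImage", values = values, spacing = as.numeric(spacing),
      origin = as.numeric(origin), unit = unit)
}

#' VOIMask: a binary volume of interest on a reference grid
#'
#' @slot name VOI label (e.g. "liver").
#' @slot mask logical 3D array.
#' @slot spacing,origin grid geometry, must match the reference image.
#' @export
setClass("VOIMask",
  representation(name = "character", mask = "array",
                 spacing = "numeric", origin = "numeric"))

setValidity("VOIMask", function(object) {
  msg <- NULL
  if (length(dim(object@mask)) != 3L || !is.logical(object@mask))
    msg <- c(msg, "'mask' must be a logical 3D array")
  if (length(object@name) != 1L || !nzchar(object@name))
    msg <- c(msg, "'name' must be a non-empty string")
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    msg <- c(msg, "'spacing' must be 3 positive values")
  if (is.null(msg)) TRUE else msg
})

#' Construct a VOIMask
#' @param name VOI label.
#' @param mask logical 3D array (or coercible).
#' @param spacing,origin grid geometry in mm; alternatively pass
#'   \code{reference}, a \linkS4class{VoxelImage} whose grid is copied.
#' @param reference optional reference image supplying the grid.
#' @return A \linkS4class{VOIMask}.
#' @export
voiMask <- function(name, mask, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                    reference = NULL) {
  if (!is.null(reference)) {
    stopifnot(is(reference, "VoxelImage"))
    spacing <- reference@spacing
    origin <- reference@origin
  }
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (length(origin) == 1L) origin <- rep(origin, 3L)
  m <- array(as.logical(mask), dim = dim(mask))
  new("VOIMask", name = name, mask = m, spacing = as.numeric(spacing),
      origin = as.numeric(origin))
}

#' DeformationField: per-voxel displacement vectors
#'
#' Displacements are in mm, stored as a 4D array (nx, ny, nz, 3) on the
#' same grid convention as \linkS4class{VoxelImage}. Applying the identity
#' field leaves an image unchanged.
#'
#' @slot displacement 4D numeric array, last dimension of extent 3.
#' @slot spacing,origin grid geometry in mm.
#' @export
setClass("DeformationField",
  representation(displacement = "array", spacing = "numeric",
                 origin = "numeric"))

setValidity("DeformationField", function(object) {
  d <- dim(object@displacement)
  msg <- NULL
  if (length(d) != 4L || d[4L] != 3L)
    msg <- c(msg, "'displacement' must be a (nx, ny, nz, 3) array")
  if (anyNA(object@displacement) || any(is.infinite(object@displacement)))
    msg <- c(msg, "displacements must be finite")
  if (is.null(msg)) TRUE else msg
})

#' Construct a DeformationField
#' @param displacement (nx, ny, nz, 3) array of mm displacements.
#' @param spacing,origin grid geometry in mm.
#' @return A \linkS4class{DeformationField}.
#' @export
deformationField <- function(displacement, spacing = c(1, 1, 1),
                             origin = c(0, 0, 0)) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (length(origin) == 1L) origin <- rep(origin, 3L)
  new("DeformationField", displacement = displacement,
      spacing = as.numeric(spacing), origin = as.numeric(origin))
}

#' Identity deformation field on the grid of an image
#' @param image reference \linkS4class{VoxelImage}.
#' @return A \linkS4class{DeformationField} of all-zero displacements.
#' @export
identityField <- function(image) {
  d <- dim(image@values)
  deformationField(array(0, c(d, 3L)), image@spacing, image@origin)
}

#' DensityModel: piecewise-linear HU to mass-density mapping
#'
#' A density-only simplification of the stoichiometric (Schneider-type)
#' CT calibration: Hounsfield units are mapped to mass density (g/cc) by
#' linear interpolation between anchor points, clamped at the table ends.
#' Elemental composition is not modelled because the transport engine
#' only consumes density.
#'
#' @slot hu anchor HU values, strictly increasing.
#' @slot density anchor densities in g/cc, non-decreasing.
#' @export
setClass("DensityModel",
  representation(hu = "numeric", density = "numeric"))

setValidity("DensityModel", function(object) {
  msg <- NULL
  if (length(object@hu) < 2L || length(object@hu) != length(object@density))
    msg <- c(msg, "need >= 2 matching (hu, density) anchors")
  if (is.unsorted(object@hu, strictly = TRUE))
    msg <- c(msg, "'hu' anchors must be strictly increasing")
  if (is.unsorted(object@density))
    msg <- c(msg, "'density' must be monotone non-decreasing")
  if (any(object@density < 0))
    msg <- c(msg, "densities must be non-negative")
  if (is.null(msg)) TRUE else msg
})

#' Construct a DensityModel
#' @param hu anchor HU values (strictly increasing).
#' @param density anchor densities (g/cc, non-decreasing).
#' @return A \linkS4class{DensityModel}.
#' @export
densityModel <- function(hu, density) {
  new("DensityModel", hu = as.numeric(hu), density = as.numeric(density))
}

#' Default HU-to-density anchors
#'
#' Anchors at air, lung, adipose, water, muscle and bone. By definition of
#' the Hounsfield scale, 0 HU maps to exactly 1.000 g/cc and -1000 HU to
#' the density of air.
#' @return A \linkS4class{DensityModel}.
#' @export
defaultDensityModel <- function() {
  densityModel(
    hu      = c(-1000,  -700,  -98,     0,    40,   300,   700,  1500,  3000),
    density = c(0.00121, 0.30, 0.93, 1.000, 1.050, 1.180, 1.420, 1.850, 2.700))
}

#' PlanarImage: a 2D whole-body projection in counts
#'
#' @slot values 2D count matrix; non-negative.
#' @slot spacing pixel size in mm (length 2).
#' @slot origin corner position in mm (length 2).
#' @slot axialAxis which matrix dimension (1 or 2) runs along the body
#'   (cranio-caudal) axis.
#' @export
setClass("PlanarImage",
  representation(values = "matrix", spacing = "numeric",
                 origin = "numeric", axialAxis = "integer"))

setValidity("PlanarImage", function(object) {
  msg <- NULL
  if (any(!is.finite(object@values)) || any(object@values < 0))
    msg <- c(msg, "planar counts must be finite and non-negative")
  if (length(object@spacing) != 2L || any(object@spacing <= 0))
    msg <- c(msg, "'spacing' must be 2 positive values")
  if (!object@axialAxis %in% c(1L, 2L))
    msg <- c(msg, "'axialAxis' must be 1 or 2")
  if (is.null(msg)) TRUE else msg
})

#' Construct a PlanarImage
#' @param values 2D count matrix.
#' @param spacing pixel size mm (length 2).
#' @param origin corner mm (length 2).
#' @param axialAxis matrix dimension along the body axis (default 2).
#' @return A \linkS4class{PlanarImage}.
#' @export
planarImage <- function(values, spacing = c(1, 1), origin = c(0, 0),
                        axialAxis = 2L) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 2L)
  if (length(origin) == 1L) origin <- rep(origin, 2L)
  new("PlanarImage", values = as.matrix(values), spacing = as.numeric(spacing),
      origin = as.numeric(origin), axialAxis = as.integer(axialAxis))
}

#' CalibrationResult: planar FAF and SPECT calibration factor
#'
#' @slot faf fraction of whole-body activity inside the SPECT field of
#'   view, in (0, 1].
#' @slot calibFactor counts per MBq for the fixed-duration acquisition.
#' @slot decayCorrectedActivityMBq total-body activity at the calibration
#'   acquisition (injected activity decay-corrected to t_acq).
#' @slot tAcqH calibration acquisition time, h post injection.
#' @export
setClass("CalibrationResult",
  representation(faf = "numeric", calibFactor = "numeric",
                 decayCorrectedActivityMBq = "numeric", tAcqH = "numeric"))

setValidity("CalibrationResult", function(object) {
  msg <- NULL
  if (object@faf <= 0 || object@faf > 1)
    msg <- c(msg, "'faf' must be in (0, 1]")
  if (object@calibFactor <= 0)
    msg <- c(msg, "'calibFactor' must be positive")
  if (is.null(msg)) TRUE else msg
})

#' KineticCurve: activity versus time for one VOI, peak region or voxel
#'
#' @slot times h post injection, strictly increasing.
#' @slot activities activity at each time (MBq or \%IA/kg).
#' @slot sds voxel-level dispersion of activity within the VOI at each
#'   time (population SD), used as fit weights.
#' @slot unit activity unit.
#' @slot label VOI / voxel identifier.
#' @export
setClass("KineticCurve",
  representation(times = "numeric", activities = "numeric",
                 sds = "numeric", unit = "character", label = "character"))

setValidity("KineticCurve", function(object) {
  msg <- NULL
  n <- length(object@times)
  if (length(object@activities) != n || length(object@sds) != n)
    msg <- c(msg, "times, activities and sds must have equal length")
  if (n >= 2L && is.unsorted(object@times, strictly = TRUE))
    msg <- c(msg, "'times' must be strictly increasing")
  if (any(object@activities < 0))
    msg <- c(msg, "activities must be non-negative")
  if (is.null(msg)) TRUE else msg
})

#' Construct a KineticCurve
#' @param times h post injection (strictly increasing).
#' @param activities activities at \code{times}.
#' @param sds within-VOI SDs (defaults to 0).
#' @param unit activity unit tag.
#' @param label identifier.
#' @return A \linkS4class{KineticCurve}.
#' @export
kineticCurve <- function(times, activities, sds = rep(0, length(times)),
                         unit = "MBq", label = "") {
  new("KineticCurve", times = as.numeric(times),
      activities = as.numeric(activities), sds = as.numeric(sds),
      unit = unit, label = label)
}

#' TailFit: fitted mono-exponential washout tail
#'
#' Parameters of A0 * exp(-lambda * t) fitted to the terminal part of a
#' kinetic curve.
#'
#' @slot a0 amplitude, same unit as the fitted curve.
#' @slot lambda effective decay constant, 1/h; positive on success.
#' @slot nPointsUsed 2 or 3 measured points (+ possibly one artificial).
#' @slot artificialPoint TRUE if an artificial late point was appended to
#'   force a decreasing tail.
#' @slot degenerate TRUE if the fit fell back to the physical decay
#'   constant because the tail did not decay.
#' @slot weights fit weights actually used.
#' @export
setClass("TailFit",
  representation(a0 = "numeric", lambda = "numeric", nPointsUsed = "integer",
                 artificialPoint = "logical", degenerate = "logical",
                 weights = "numeric"))

setValidity("TailFit", function(object) {
  msg <- NULL
  if (!object@degenerate && (object@lambda <= 0 || object@a0 < 0))
    msg <- c(msg, "a successful fit requires lambda > 0 and a0 >= 0")
  if (is.null(msg)) TRUE else msg
})

#' DecayConstants: physical half-lives of the theranostic pair
#'
#' In-111 (imaging surrogate) physical half-life 67.3 h; Y-90 (therapy)
#' 64.05 h from standard nuclear data.
#'
#' @param halfLifeImagingH imaging radionuclide half-life, h.
#' @param halfLifeTherapyH therapy radionuclide half-life, h.
#' @return list with half-lives and decay constants (1/h).
#' @examples
#' dc <- decayConstants()
#' dc$lambdaImaging  # ln 2 / 67.3
#' @export
decayConstants <- function(halfLifeImagingH = 67.3, halfLifeTherapyH = 64.05) {
  stopifnot(halfLifeImagingH > 0, halfLifeTherapyH > 0)
  list(halfLifeImaging = halfLifeImagingH,
       halfLifeTherapy = halfLifeTherapyH,
       lambdaImaging = log(2) / halfLifeImagingH,
       lambdaTherapy = log(2) / halfLifeTherapyH)
}

#' BetaSpectrum: tabulated beta-particle emission spectrum
#'
#' @slot energy energy grid, keV, strictly increasing.
#' @slot density probability density per keV; trapezoidal integral 1.
#' @slot meanEnergy intensity-weighted mean energy, keV.
#' @slot endpoint maximum (endpoint) energy, keV.
#' @export
setClass("BetaSpectrum",
  representation(energy = "numeric", density = "numeric",
                 meanEnergy = "numeric", endpoint = "numeric"))

setValidity("BetaSpectrum", function(object) {
  msg <- NULL
  if (length(object@energy) < 2L ||
      length(object@energy) != length(object@density))
    msg <- c(msg, "energy and density must be matching vectors")
  if (is.unsorted(object@energy, strictly = TRUE))
    msg <- c(msg, "'energy' must be strictly increasing")
  if (any(object@density < 0))
    msg <- c(msg, "densities must be non-negative")
  tot <- sum(diff(object@energy) *
             (utils::head(object@density, -1) + utils::tail(object@density, -1)) / 2)
  if (abs(tot - 1) > 1e-6)
    msg <- c(msg, "spectrum must be normalised (trapezoidal integral 1)")
  if (is.null(msg)) TRUE else msg
})

#' Construct a BetaSpectrum from an energy/density tabulation
#'
#' The tabulation is renormalised so its trapezoidal integral is 1; the
#' mean and endpoint are derived from the table.
#' @param energy energy grid, keV.
#' @param density probability density per keV (any positive scale).
#' @return A \linkS4class{BetaSpectrum}.
#' @export
betaSpectrum <- function(energy, density) {
  o <- order(energy)
  energy <- as.numeric(energy[o]); density <- as.numeric(density[o])
  if (any(density < 0)) stop("spectrum densities must be non-negative")
  tot <- sum(diff(energy) * (utils::head(density, -1) + utils::tail(density, -1)) / 2)
  if (tot <= 0) stop("spectrum integrates to zero")
  density <- density / tot
  ## trapezoid-consistent first moment
  m1 <- sum(diff(energy) * (utils::head(density * energy, -1) +
                            utils::tail(density * energy, -1)) / 2)
  new("BetaSpectrum", energy = energy, density = density,
      meanEnergy = m1, endpoint = energy[length(energy)])
}

#' TransportConfig: settings for the beta transport engine
#'
#' @param nHistories number of simulated decays (>= 1).
#' @param seed RNG seed recorded in the output.
#' @param mode "csda_straight_line" (default) or "local_deposition".
#' @param stepMm geometric step length, mm.
#' @param densityFloor minimum density (g/cc) used for range scaling, so
#'   electron ranges stay finite in air.
#' @param nBatches history batches used for the statistical uncertainty.
#' @return An object of class \code{TransportConfig} (a validated list).
#' @export
transportConfig <- function(nHistories = 1e6, seed = 1L,
                            mode = c("csda_straight_line", "local_deposition"),
                            stepMm = 1.0, densityFloor = 0.001,
                            nBatches = 10L) {
  mode <- match.arg(mode)
  stopifnot(nHistories >= 1, stepMm > 0, densityFloor > 0, nBatches >= 2)
  structure(list(nHistories = as.numeric(nHistories), seed = as.integer(seed),
                 mode = mode, stepMm = stepMm, densityFloor = densityFloor,
                 nBatches = as.integer(nBatches)),
            class = "TransportConfig")
}

#' DoseImage: absorbed dose map with statistical uncertainty
#'
#' @slot dose \linkS4class{VoxelImage} of absorbed dose, cGy per injected
#'   MBq.
#' @slot relUncertainty array of relative batch standard errors (fraction),
#'   NA where dose is zero.
#' @slot nHistories,nBatches,seed simulation bookkeeping.
#' @slot mode transport mode used.
#' @slot emittedKeV,depositedKeV,escapedKeV energy ledger of the run (keV
#'   per simulated history set, before disintegration scaling).
#' @export
setClass("DoseImage",
  representation(dose = "VoxelImage", relUncertainty = "array",
                 nHistories = "numeric", nBatches = "integer",
                 seed = "integer", mode = "character",
                 emittedKeV = "numeric", depositedKeV = "numeric",
                 escapedKeV = "numeric"))

setValidity("DoseImage", function(object) {
  msg <- NULL
  if (any(object@dose@values < 0))
    msg <- c(msg, "dose must be non-negative")
  if (!identical(dim(object@relUncertainty), dim(object@dose@values)))
    msg <- c(msg, "uncertainty grid must match the dose grid")
  if (is.null(msg)) TRUE else msg
})

#' StudySeries: one patient-like study (time series + metadata)
#'
#' The unit of pipeline input: calibrated or raw SPECT frames at each
#' acquisition time, the (averaged) CT, the whole-body planar image used
#' for the FAF, the VOI masks, and injection metadata.
#'
#' @slot times acquisition times, h post injection, strictly increasing.
#' @slot spect list of \linkS4class{VoxelImage} (counts or MBq), one per
#'   time, all on a common grid.
#' @slot ct \linkS4class{VoxelImage} in HU on the SPECT grid (avCT
#'   resampled to SPECT resolution), or NULL.
#' @slot planar \linkS4class{PlanarImage} at the first time point, or NULL.
#' @slot masks named list of \linkS4class{VOIMask} on the SPECT grid.
#' @slot injectedActivityMBq injected activity.
#' @slot fovRange axial extent (mm, length 2) of the SPECT field of view.
#' @slot meta free-form metadata list (generator ground truth, seeds, ...).
#' @export
setClass("StudySeries",
  representation(times = "numeric", spect = "list", ct = "ANY",
                 planar = "ANY", masks = "list",
                 injectedActivityMBq = "numeric", fovRange = "numeric",
                 meta = "list"))

setValidity("StudySeries", function(object) {
  msg <- NULL
  if (length(object@spect) != length(object@times))
    msg <- c(msg, "one SPECT frame per time point required")
  if (length(object@times) >= 2L && is.unsorted(object@times, strictly = TRUE))
    msg <- c(msg, "'times' must be strictly increasing")
  if (object@injectedActivityMBq <= 0)
    msg <- c(msg, "'injectedActivityMBq' must be positive")
  if (length(object@spect) >= 2L) {
    g1 <- object@spect[[1L]]
    ok <- vapply(object@spect, function(im) isTRUE(sameGrid(im, g1)), logical(1))
    if (!all(ok)) msg <- c(msg, "all SPECT frames must share one grid")
  }
  if (is.null(msg)) TRUE else msg
})

#' Construct a StudySeries
#' @param times acquisition times (h).
#' @param spect list of SPECT \linkS4class{VoxelImage}s.
#' @param ct CT \linkS4class{VoxelImage} (HU) or NULL.
#' @param planar \linkS4class{PlanarImage} or NULL.
#' @param masks named list of \linkS4class{VOIMask}.
#' @param injectedActivityMBq injected activity, MBq.
#' @param fovRange axial FOV extent, mm (length 2).
#' @param meta metadata list.
#' @return A \linkS4class{StudySeries}.
#' @export
studySeries <- function(times, spect, ct = NULL, planar = NULL,
                        masks = list(), injectedActivityMBq,
                        fovRange = c(-Inf, Inf), meta = list()) {
  new("StudySeries", times = as.numeric(times), spect = spect, ct = ct,
      planar = planar, masks = masks,
      injectedActivityMBq = injectedActivityMBq,
      fovRange = as.numeric(fovRange), meta = meta)
}

#' GradeResult: automated lesion grade
#'
#' Grade 0 to IV from the lesion-to-mediastinum and lesion-to-liver ratio
#' of the chosen uptake/dose metric.
#'
#' @slot lesionId lesion identifier.
#' @slot metric name of the metric graded on.
#' @slot ratioMediastinum lesion / mediastinal blood pool ratio.
#' @slot ratioLiver lesion / liver ratio.
#' @slot grade one of "0", "I", "II", "III", "IV".
#' @slot boundaryBand TRUE when the lesion falls in the 80--120\%-of-liver
#'   band above the mediastinal threshold, which the scale leaves
#'   unassigned and this implementation maps to grade III.
#' @export
setClass("GradeResult",
  representation(lesionId = "character", metric = "character",
                 ratioMediastinum = "numeric", ratioLiver = "numeric",
                 grade = "character", boundaryBand = "logical"))

setValidity("GradeResult", function(object) {
  if (!object@grade %in% c("0", "I", "II", "III", "IV"))
    "grade must be one of 0, I, II, III, IV" else TRUE
})
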
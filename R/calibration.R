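## Patient-specific SPECT calibration.
##
## The camera is not assumed to have an absolute calibration: the counts
## of the 1 h SPECT are tied to the known injected activity, decay
## corrected to the acquisition time (the 1 h images predate any
## urination), after accounting for the fraction of total-body activity
## that the limited axial SPECT field of view actually sees (FAF,
## estimated from the whole-body planar image).

#' Project the SPECT field of view onto a planar image
#'
#' Returns the logical band of planar pixels whose centres fall inside
#' the axial extent of the SPECT FOV. FOV boundaries are rounded to the
#' nearest pixel (a pixel belongs to the band iff its centre is inside).
#'
#' @param planar a \linkS4class{PlanarImage}.
#' @param fovRange length-2 numeric, axial FOV extent in mm.
#' @return logical matrix of the same shape as the planar image.
#' @export
projectFov <- function(planar, fovRange) {
  stopifnot(length(fovRange) == 2L, fovRange[1] < fovRange[2])
  ax <- planar@axialAxis
  n <- dim(planar@values)[ax]
  centers <- planar@origin[ax] + (seq_len(n) - 0.5) * planar@spacing[ax]
  inband <- centers >= fovRange[1] & centers <= fovRange[2]
  if (!any(inband)) stop("SPECT FOV does not overlap the planar axial extent")
  region <- matrix(FALSE, nrow(planar@values), ncol(planar@values))
  if (ax == 1L) region[inband, ] <- TRUE else region[, inband] <- TRUE
  region
}

#' Fraction of activity in the field of view (FAF)
#'
#' Counts inside the projected FOV region divided by the total counts of
#' the whole-body planar image. Invariant to global rescaling of the
#' planar image.
#'
#' @param planar a \linkS4class{PlanarImage}.
#' @param region logical matrix from \code{\link{projectFov}} (or a
#'   length-2 FOV range, projected internally).
#' @return the FAF, in [0, 1].
#' @export
computeFaf <- function(planar, region) {
  if (is.numeric(region) && length(region) == 2L)
    region <- projectFov(planar, region)
  stopifnot(identical(dim(region), dim(planar@values)))
  tot <- sum(planar@values)
  if (tot <= 0) stop("planar image has zero total counts")
  sum(planar@values[region]) / tot
}

#' Patient-specific SPECT calibration factor
#'
#' cf = C / (A_inj * exp(-lambda * t_acq) * FAF): total counts of the
#' calibration SPECT divided by the decay-corrected injected activity
#' weighted by the fraction of activity inside the FOV. Units are counts
#' per MBq for the fixed-duration acquisition (divide by the acquisition
#' duration in seconds for cps/MBq).
#'
#' @param totalSpectCounts total counts of the calibration SPECT frame.
#' @param injectedActivityMBq injected activity, MBq.
#' @param tAcqH acquisition time, h post injection.
#' @param lambdaPhys physical decay constant of the imaging radionuclide,
#'   1/h (default In-111, ln 2 / 67.3).
#' @param faf fraction of activity in the FOV, in (0, 1].
#' @return A \linkS4class{CalibrationResult}.
#' @examples
#' computeCalibrationFactor(1e6, 100, 0, faf = 1)  # 1e4 counts/MBq
#' @export
computeCalibrationFactor <- function(totalSpectCounts, injectedActivityMBq,
                                     tAcqH,
                                     lambdaPhys = log(2) / 67.3, faf) {
  if (faf <= 0 || faf > 1) stop("'faf' must be in (0, 1]")
  if (injectedActivityMBq <= 0) stop("injected activity must be positive")
  if (totalSpectCounts <= 0) stop("total SPECT counts must be positive")
  aDecay <- injectedActivityMBq * exp(-lambdaPhys * tAcqH)
  new("CalibrationResult",
      faf = faf,
      calibFactor = totalSpectCounts / (aDecay * faf),
      decayCorrectedActivityMBq = aDecay,
      tAcqH = as.numeric(tAcqH))
}

#' Convert a SPECT count image to absolute activity
#'
#' @param spect \linkS4class{VoxelImage} in counts.
#' @param cf calibration factor (counts/MBq) or a
#'   \linkS4class{CalibrationResult}.
#' @return \linkS4class{VoxelImage} in MBq per voxel.
#' @export
countsToActivity <- function(spect, cf) {
  if (is(cf, "CalibrationResult")) cf <- cf@calibFactor
  if (cf <= 0) stop("calibration factor must be positive")
  .likeImage(spect, spect@values / cf, unit = "MBq")
}

#' Express activity as percent injected activity per kilogram
#'
#' @param activityMBq activity in a VOI (scalar or vector), MBq.
#' @param injectedActivityMBq injected activity, MBq.
#' @param massKg VOI mass, kg (> 0).
#' @return \%IA/kg.
#' @examples
#' toPercentIAPerKg(1.85, 185, 0.1)  # 10 %IA/kg
#' @export
toPercentIAPerKg <- function(activityMBq, injectedActivityMBq, massKg) {
  if (any(massKg <= 0)) stop("mass must be positive")
  if (injectedActivityMBq <= 0) stop("injected activity must be positive")
  100 * (activityMBq / injectedActivityMBq) / massKg
}

#' Calibrate a whole study
#'
#' Computes the FAF from the first-time-point planar image, the
#' calibration factor from the first SPECT frame, and converts every
#' frame to MBq. Later time points inherit the first time point's
#' calibration factor.
#'
#' @param study a \linkS4class{StudySeries} with SPECT frames in counts.
#' @param lambdaPhys imaging radionuclide decay constant, 1/h.
#' @return list with \code{study} (frames in MBq) and \code{calibration}
#'   (a \linkS4class{CalibrationResult}).
#' @export
calibrateStudy <- function(study, lambdaPhys = log(2) / 67.3) {
  if (is.null(study@planar)) stop("study has no planar image for the FAF")
  if (study@spect[[1L]]@unit != "counts")
    stop("SPECT frames are not in counts (already calibrated?)")
  faf <- computeFaf(study@planar, projectFov(study@planar, study@fovRange))
  calib <- computeCalibrationFactor(sum(study@spect[[1L]]@values),
                                    study@injectedActivityMBq,
                                    study@times[1L], lambdaPhys, faf)
  study@spect <- lapply(study@spect, countsToActivity, cf = calib)
  list(study = study, calibration = calib)
}
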
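## Accessors, show methods and grid utilities.

#' @describeIn VoxelImage voxel value array
#' @param x object
#' @export
setMethod("voxelValues", "VoxelImage", function(x) x@values)

#' @describeIn VoxelImage spacing in mm
#' @export
setMethod("voxelSpacing", "VoxelImage", function(x) x@spacing)

#' @describeIn VoxelImage origin in mm
#' @export
setMethod("voxelOrigin", "VoxelImage", function(x) x@origin)

#' @describeIn VoxelImage value unit tag
#' @export
setMethod("valueUnit", "VoxelImage", function(x) x@unit)

#' @describeIn VoxelImage voxel volume in cc
#' @export
setMethod("voxelVolumeCc", "VoxelImage", function(x) prod(x@spacing) / 1000)

#' @describeIn VOIMask logical mask array
#' @param x object
#' @export
setMethod("maskArray", "VOIMask", function(x) x@mask)

#' @describeIn VOIMask VOI name
#' @export
setMethod("voiName", "VOIMask", function(x) x@name)

#' @describeIn VOIMask voxel volume in cc
#' @export
setMethod("voxelVolumeCc", "VOIMask", function(x) prod(x@spacing) / 1000)

#' @describeIn KineticCurve time points (h)
#' @param x object
#' @export
setMethod("curveTimes", "KineticCurve", function(x) x@times)

#' @describeIn KineticCurve activities
#' @export
setMethod("curveActivities", "KineticCurve", function(x) x@activities)

#' @describeIn KineticCurve within-VOI SDs
#' @export
setMethod("curveSds", "KineticCurve", function(x) x@sds)

#' @describeIn BetaSpectrum intensity-weighted mean energy (keV)
#' @param x object
#' @export
setMethod("meanEnergy", "BetaSpectrum", function(x) x@meanEnergy)

#' @describeIn BetaSpectrum endpoint energy (keV)
#' @export
setMethod("endpointEnergy", "BetaSpectrum", function(x) x@endpoint)

#' @describeIn DoseImage dose array (cGy per injected MBq)
#' @param x object
#' @export
setMethod("doseValues", "DoseImage", function(x) x@dose@values)

#' @describeIn DoseImage per-voxel relative statistical uncertainty
#' @export
setMethod("relUncertainty", "DoseImage", function(x) x@relUncertainty)

setMethod("dim", "VoxelImage", function(x) dim(x@values))

setMethod("show", "VoxelImage", function(object) {
  d <- dim(object@values)
  cat(sprintf("VoxelImage %dx%dx%d [%s], spacing %s mm, origin %s mm\n",
              d[1], d[2], d[3], object@unit,
              paste(signif(object@spacing, 4), collapse = "x"),
              paste(signif(object@origin, 4), collapse = ", ")))
  v <- object@values
  cat(sprintf("  value range [%.4g, %.4g], sum %.6g\n",
              min(v), max(v), sum(v)))
})

setMethod("show", "VOIMask", function(object) {
  cat(sprintf("VOIMask '%s': %d voxels, %.2f cc\n", object@name,
              sum(object@mask), sum(object@mask) * prod(object@spacing) / 1000))
})

setMethod("show", "KineticCurve", function(object) {
  cat(sprintf("KineticCurve '%s' [%s], %d time points (%.3g..%.3g h)\n",
              object@label, object@unit, length(object@times),
              min(object@times), max(object@times)))
  print(data.frame(time_h = object@times, activity = object@activities,
                   sd = object@sds))
})

setMethod("show", "TailFit", function(object) {
  cat(sprintf("TailFit: A0 = %.5g, lambda = %.5g /h (T1/2eff = %.4g h), %d points%s%s\n",
              object@a0, object@lambda, log(2) / object@lambda,
              object@nPointsUsed,
              if (object@artificialPoint) " + artificial point" else "",
              if (object@degenerate) " [degenerate fallback]" else ""))
})

setMethod("show", "BetaSpectrum", function(object) {
  cat(sprintf("BetaSpectrum: %d bins, mean %.1f keV, endpoint %.1f keV\n",
              length(object@energy), object@meanEnergy, object@endpoint))
})

setMethod("show", "DoseImage", function(object) {
  cat(sprintf("DoseImage [%s]: %.3g histories in %d batches (seed %d)\n",
              object@mode, object@nHistories, object@nBatches, object@seed))
  cat(sprintf("  max dose %.4g cGy/MBq; energy deposited %.4g / emitted %.4g keV (%.3g%% escaped)\n",
              max(object@dose@values), object@depositedKeV, object@emittedKeV,
              100 * object@escapedKeV / max(object@emittedKeV, .Machine$double.xmin)))
})

setMethod("show", "StudySeries", function(object) {
  cat(sprintf("StudySeries: %d time points at %s h, %d VOI masks, A_inj %.1f MBq\n",
              length(object@times), paste(object@times, collapse = "/"),
              length(object@masks), object@injectedActivityMBq))
  cat(sprintf("  SPECT unit '%s', axial FOV [%.0f, %.0f] mm\n",
              object@spect[[1]]@unit, object@fovRange[1], object@fovRange[2]))
})

setMethod("show", "CalibrationResult", function(object) {
  cat(sprintf("CalibrationResult: FAF %.4f, calibration factor %.5g counts/MBq (t = %.2f h)\n",
              object@faf, object@calibFactor, object@tAcqH))
})

setMethod("show", "GradeResult", function(object) {
  cat(sprintf("GradeResult '%s' [%s]: grade %s (lesion/mediastinum %.3g, lesion/liver %.3g)%s\n",
              object@lesionId, object@metric, object@grade,
              object@ratioMediastinum, object@ratioLiver,
              if (object@boundaryBand) " [boundary band -> III]" else ""))
})

#' Do two gridded objects share the same voxel grid?
#'
#' Grids are equal when shape, spacing and origin match (tolerance 1e-6
#' relative on spacing, 1e-6 mm on origin). Arithmetic between images and
#' mask-based quantification require equal grids.
#'
#' @param a,b \linkS4class{VoxelImage}, \linkS4class{VOIMask} or
#'   \linkS4class{DeformationField}.
#' @return TRUE or FALSE.
#' @export
sameGrid <- function(a, b) {
  da <- .gridDim(a); db <- .gridDim(b)
  identical(da, db) &&
    all(abs(.gridSpacing(a) - .gridSpacing(b)) <= 1e-6 * .gridSpacing(b)) &&
    all(abs(.gridOrigin(a) - .gridOrigin(b)) <= 1e-6)
}

.gridDim <- function(x) {
  if (is(x, "VoxelImage")) dim(x@values)
  else if (is(x, "VOIMask")) dim(x@mask)
  else if (is(x, "DeformationField")) dim(x@displacement)[1:3]
  else stop("not a gridded object")
}
.gridSpacing <- function(x) x@spacing
.gridOrigin <- function(x) x@origin

.stopUnlessSameGrid <- function(a, b, what = "operands") {
  if (!sameGrid(a, b))
    stop(sprintf("grid mismatch: %s must share shape, spacing and origin", what))
  invisible(TRUE)
}

#' Voxel-centre coordinates along each axis
#' @param image a \linkS4class{VoxelImage} (or mask/field).
#' @return list of three numeric vectors (mm), one per axis.
#' @export
voxelCenters <- function(image) {
  d <- .gridDim(image); sp <- .gridSpacing(image); or <- .gridOrigin(image)
  lapply(1:3, function(a) or[a] + (seq_len(d[a]) - 0.5) * sp[a])
}

## new image on the same grid with different values/unit
.likeImage <- function(image, values, unit = image@unit) {
  voxelImage(values, image@spacing, image@origin, unit)
}
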
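## Image-domain operations: warping, CT averaging, HU -> density, VOI mass.

#' Apply a deformation field to an image
#'
#' Pull-back warping: the output voxel at position p takes the input value
#' interpolated at p + d(p), where d is the displacement (mm). The field
#' must already live on the image grid (resample it beforehand if not);
#' a grid mismatch is an error. Samples falling outside the input grid
#' are set to 0. Use nearest-neighbour interpolation for masks and label
#' images.
#'
#' @param image a \linkS4class{VoxelImage}.
#' @param field a \linkS4class{DeformationField} on the same grid.
#' @param interpolation "linear" (default) or "nearest".
#' @return warped \linkS4class{VoxelImage} on the same grid.
#' @examples
#' img <- voxelImage(array(rnorm(6^3), c(6, 6, 6)), spacing = 2)
#' warped <- applyDeformation(img, identityField(img))
#' stopifnot(all.equal(voxelValues(warped), voxelValues(img)))
#' @export
applyDeformation <- function(image, field,
                             interpolation = c("linear", "nearest")) {
  interpolation <- match.arg(interpolation)
  .stopUnlessSameGrid(image, field, "image and deformation field")
  d <- dim(image@values)
  sp <- image@spacing; or <- image@origin
  cx <- voxelCenters(image)
  ## sampling positions = voxel centre + displacement, as continuous
  ## 1-based voxel indices
  px <- rep(cx[[1]], times = d[2] * d[3]) + as.numeric(field@displacement[, , , 1])
  py <- rep(rep(cx[[2]], each = d[1]), times = d[3]) +
    as.numeric(field@displacement[, , , 2])
  pz <- rep(cx[[3]], each = d[1] * d[2]) + as.numeric(field@displacement[, , , 3])
  fi <- (px - or[1]) / sp[1] + 0.5
  fj <- (py - or[2]) / sp[2] + 0.5
  fk <- (pz - or[3]) / sp[3] + 0.5
  out <- .interp3(image@values, fi, fj, fk, interpolation)
  .likeImage(image, array(out, d))
}

## trilinear / nearest sampling of a 3D array at continuous 1-based indices
.interp3 <- function(vol, fi, fj, fk, interpolation = "linear") {
  d <- dim(vol)
  if (interpolation == "nearest") {
    i <- round(fi); j <- round(fj); k <- round(fk)
    ok <- i >= 1 & i <= d[1] & j >= 1 & j <= d[2] & k >= 1 & k <= d[3]
    out <- numeric(length(fi))
    idx <- cbind(i[ok], j[ok], k[ok])
    out[ok] <- vol[idx]
    return(out)
  }
  i0 <- floor(fi); j0 <- floor(fj); k0 <- floor(fk)
  wi <- fi - i0; wj <- fj - j0; wk <- fk - k0
  out <- numeric(length(fi))
  at <- function(i, j, k) {
    v <- numeric(length(i))
    ok <- i >= 1 & i <= d[1] & j >= 1 & j <= d[2] & k >= 1 & k <= d[3]
    v[ok] <- vol[cbind(i[ok], j[ok], k[ok])]
    v
  }
  out <- at(i0,     j0,     k0)     * (1 - wi) * (1 - wj) * (1 - wk) +
         at(i0 + 1, j0,     k0)     * wi       * (1 - wj) * (1 - wk) +
         at(i0,     j0 + 1, k0)     * (1 - wi) * wj       * (1 - wk) +
         at(i0 + 1, j0 + 1, k0)     * wi       * wj       * (1 - wk) +
         at(i0,     j0,     k0 + 1) * (1 - wi) * (1 - wj) * wk +
         at(i0 + 1, j0,     k0 + 1) * wi       * (1 - wj) * wk +
         at(i0,     j0 + 1, k0 + 1) * (1 - wi) * wj       * wk +
         at(i0 + 1, j0 + 1, k0 + 1) * wi       * wj       * wk
  out
}

#' Average co-registered CT images into a single reference CT
#'
#' After all time-point CTs have been warped to the reference frame they
#' are averaged voxelwise into one low-noise anatomical image (the
#' averaged CT used for VOI mass and density).
#'
#' @param cts non-empty list of \linkS4class{VoxelImage}s in HU on one grid.
#' @return the voxelwise mean \linkS4class{VoxelImage}.
#' @export
averageCts <- function(cts) {
  if (length(cts) < 1L) stop("need at least one CT image")
  ref <- cts[[1L]]
  acc <- array(0, dim(ref@values))
  for (ct in cts) {
    .stopUnlessSameGrid(ct, ref, "CT images")
    acc <- acc + ct@values
  }
  .likeImage(ref, acc / length(cts), unit = "HU")
}

#' Convert Hounsfield units to mass density
#'
#' Piecewise-linear interpolation between the model anchors, clamped at
#' the table ends. 0 HU maps to 1.000 g/cc and -1000 HU to air.
#'
#' @param hu numeric vector/array of HU, or a \linkS4class{VoxelImage}.
#' @param model a \linkS4class{DensityModel} (default bundled anchors).
#' @return densities in g/cc, same shape as the input (a VoxelImage in
#'   when a VoxelImage goes in).
#' @examples
#' huToDensity(c(-1000, 0, 60))
#' @export
huToDensity <- function(hu, model = defaultDensityModel()) {
  if (is(hu, "VoxelImage")) {
    dens <- huToDensity(hu@values, model)
    return(.likeImage(hu, array(dens, dim(hu@values)), unit = "g/cc"))
  }
  if (any(!is.finite(hu))) stop("non-finite HU values")
  out <- stats::approx(model@hu, model@density, xout = as.numeric(hu),
                       rule = 2)$y
  if (is.array(hu)) array(out, dim(hu)) else out
}

#' Mass and volume of a VOI from the CT
#'
#' Volume is the voxel count times the voxel volume; mass integrates the
#' HU-derived density over the mask.
#'
#' @param ct \linkS4class{VoxelImage} in HU.
#' @param mask \linkS4class{VOIMask} on the same grid (non-empty).
#' @param model \linkS4class{DensityModel}.
#' @return list with \code{volume_cc}, \code{mass_g} and \code{mass_kg}.
#' @export
voiMass <- function(ct, mask, model = defaultDensityModel()) {
  .stopUnlessSameGrid(ct, mask, "CT and mask")
  n <- sum(mask@mask)
  if (n == 0L) stop(sprintf("VOI '%s' is empty", mask@name))
  vcc <- prod(ct@spacing) / 1000
  dens <- huToDensity(ct@values[mask@mask], model)
  massG <- sum(dens) * vcc  # g/cc * cc
  list(volume_cc = n * vcc, mass_g = massG, mass_kg = massG / 1000)
}

#' Volume of a VOI in cc
#' @param mask a \linkS4class{VOIMask}.
#' @return volume in cc.
#' @export
voiVolumeCc <- function(mask) sum(mask@mask) * prod(mask@spacing) / 1000
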
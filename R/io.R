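## Volumetric I/O: NIfTI (via RNifti) and MetaImage (MHD/RAW).
##
## Orientation is fixed to axis-aligned identity; the affine stored in
## NIfTI files is diag(spacing) with translation origin + spacing/2 (the
## centre of the first voxel), matching the package-wide convention.

.extOf <- function(path) {
  p <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", p)) "nii"
  else if (grepl("\\.mhd$", p)) "mhd"
  else stop("unsupported image extension (use .nii, .nii.gz or .mhd): ", path)
}

#' Write a volumetric image
#'
#' @param image a \linkS4class{VoxelImage}, or a bare 3D/4D array with
#'   \code{spacing}/\code{origin} supplied.
#' @param path output file; format chosen by extension (.nii, .nii.gz,
#'   .mhd -- the .mhd header gets a sibling .raw file).
#' @param spacing,origin geometry used when \code{image} is a bare array.
#' @return \code{path}, invisibly.
#' @export
writeVoxelImage <- function(image, path, spacing = NULL, origin = NULL) {
  if (is(image, "VoxelImage")) {
    arr <- image@values; sp <- image@spacing; or <- image@origin
  } else {
    arr <- image
    sp <- if (is.null(spacing)) rep(1, 3) else spacing
    or <- if (is.null(origin)) rep(0, 3) else origin
  }
  switch(.extOf(path),
         nii = .writeNii(arr, sp, or, path),
         mhd = .writeMhd(arr, sp, or, path))
  invisible(path)
}

#' Read a volumetric image
#'
#' @param path .nii, .nii.gz or .mhd file.
#' @param unit value unit tag to attach.
#' @return A \linkS4class{VoxelImage} (3D input), or a list
#'   \code{(values, spacing, origin)} for 4D input (deformation fields).
#' @export
readVoxelImage <- function(path, unit = "arb") {
  r <- switch(.extOf(path), nii = .readNii(path), mhd = .readMhd(path))
  if (length(dim(r$values)) == 3L)
    voxelImage(r$values, r$spacing, r$origin, unit)
  else r
}

.affineFor <- function(spacing, origin) {
  m <- diag(4)
  m[1:3, 1:3] <- diag(spacing, 3)
  m[1:3, 4] <- origin + 0.5 * spacing
  m
}

.writeNii <- function(arr, spacing, origin, path) {
  img <- RNifti::asNifti(arr)
  nd <- length(dim(arr))
  pd <- c(spacing, rep(1, nd - 3L))[seq_len(nd)]
  img <- RNifti::asNifti(img, list(pixdim = c(1, pd, rep(1, 7 - nd))))
  aff <- structure(.affineFor(spacing, origin), code = 2L)
  RNifti::qform(img) <- aff
  RNifti::sform(img) <- aff
  RNifti::writeNifti(img, path, datatype = "double")
}

.readNii <- function(path) {
  img <- RNifti::readNifti(path)
  aff <- RNifti::xform(img)
  spacing <- abs(diag(aff[1:3, 1:3, drop = FALSE]))
  origin <- aff[1:3, 4] - 0.5 * spacing
  d <- dim(img)
  if (length(d) == 2L) d <- c(d, 1L)  # trailing singleton dropped on write
  list(values = array(as.numeric(img), dim = d),
       spacing = as.numeric(spacing), origin = as.numeric(origin))
}

.writeMhd <- function(arr, spacing, origin, path) {
  d <- dim(arr)
  channels <- if (length(d) == 4L) d[4L] else 1L
  rawName <- sub("\\.mhd$", ".raw", basename(path), ignore.case = TRUE)
  hdr <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    "CompressedData = False",
    "TransformMatrix = 1 0 0 0 1 0 0 0 1",
    sprintf("Offset = %s", paste(origin + 0.5 * spacing, collapse = " ")),
    "CenterOfRotation = 0 0 0",
    "AnatomicalOrientation = RAI",
    sprintf("ElementSpacing = %s", paste(spacing, collapse = " ")),
    sprintf("DimSize = %s", paste(d[1:3], collapse = " ")),
    sprintf("ElementNumberOfChannels = %d", channels),
    "ElementType = MET_DOUBLE",
    sprintf("ElementDataFile = %s", rawName))
  writeLines(hdr, path)
  con <- file(file.path(dirname(path), rawName), "wb")
  on.exit(close(con))
  ## MetaImage stores channels interleaved, fastest-varying first
  if (channels > 1L) {
    v <- aperm(arr, c(4, 1, 2, 3))
    writeBin(as.numeric(v), con, size = 8L, endian = "little")
  } else {
    writeBin(as.numeric(arr), con, size = 8L, endian = "little")
  }
}

.readMhd <- function(path) {
  lines <- readLines(path)
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- trimws(vapply(kv, `[`, "", 1L))
  vals <- trimws(vapply(kv, function(x) paste(x[-1L], collapse = "="), ""))
  get <- function(k, default = NULL) {
    i <- match(k, keys)
    if (is.na(i)) default else vals[i]
  }
  d <- as.integer(strsplit(get("DimSize"), "\\s+")[[1]])
  spacing <- as.numeric(strsplit(get("ElementSpacing", "1 1 1"), "\\s+")[[1]])
  offs <- as.numeric(strsplit(get("Offset", "0 0 0"), "\\s+")[[1]])
  channels <- as.integer(get("ElementNumberOfChannels", "1"))
  etype <- get("ElementType", "MET_DOUBLE")
  size <- switch(etype, MET_DOUBLE = 8L, MET_FLOAT = 4L,
                 stop("unsupported MetaImage ElementType: ", etype))
  dataFile <- get("ElementDataFile")
  con <- file(file.path(dirname(path), dataFile), "rb")
  on.exit(close(con))
  n <- prod(d) * channels
  v <- readBin(con, "numeric", n = n, size = size, endian = "little")
  if (channels > 1L) {
    arr <- aperm(array(v, c(channels, d)), c(2, 3, 4, 1))
  } else {
    arr <- array(v, d)
  }
  list(values = arr, spacing = spacing, origin = offs - 0.5 * spacing)
}

#' Write/read a deformation field as a 3-component vector image
#' @param field a \linkS4class{DeformationField}.
#' @param path .nii/.nii.gz/.mhd path.
#' @return \code{path} (write) / a \linkS4class{DeformationField} (read).
#' @export
writeDeformationField <- function(field, path) {
  writeVoxelImage(field@displacement, path, field@spacing, field@origin)
}

#' @rdname writeDeformationField
#' @export
readDeformationField <- function(path) {
  r <- readVoxelImage(path)
  if (is(r, "VoxelImage")) stop("file does not contain a 3-component field")
  deformationField(r$values, r$spacing, r$origin)
}

#' Write/read a 2D planar image (stored as a single-slice volume)
#' @param planar a \linkS4class{PlanarImage}.
#' @param path .nii/.nii.gz/.mhd path.
#' @return \code{path} (write) / a \linkS4class{PlanarImage} (read).
#' @export
writePlanarImage <- function(planar, path) {
  arr <- array(planar@values, c(dim(planar@values), 1L))
  writeVoxelImage(arr, path, c(planar@spacing, 1), c(planar@origin, 0))
  meta <- file.path(dirname(path), paste0(.stripImgExt(path), ".planar.json"))
  jsonlite::write_json(list(axialAxis = planar@axialAxis), meta,
                       auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writePlanarImage
#' @export
readPlanarImage <- function(path) {
  img <- readVoxelImage(path)
  meta <- file.path(dirname(path), paste0(.stripImgExt(path), ".planar.json"))
  ax <- if (file.exists(meta)) jsonlite::read_json(meta)$axialAxis else 2L
  planarImage(img@values[, , 1L], img@spacing[1:2], img@origin[1:2],
              as.integer(ax))
}

.stripImgExt <- function(path) {
  sub("\\.(nii(\\.gz)?|mhd)$", "", basename(path), ignore.case = TRUE)
}

#' Write/read a calibration result as a JSON sidecar
#' @param calib a \linkS4class{CalibrationResult}.
#' @param path JSON path.
#' @return \code{path} (write) / a \linkS4class{CalibrationResult} (read).
#' @export
writeCalibration <- function(calib, path) {
  jsonlite::write_json(
    list(faf = calib@faf, calib_factor = calib@calibFactor,
         decay_corrected_activity_mbq = calib@decayCorrectedActivityMBq,
         t_acq_h = calib@tAcqH),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeCalibration
#' @export
readCalibration <- function(path) {
  x <- jsonlite::read_json(path)
  new("CalibrationResult", faf = x$faf, calibFactor = x$calib_factor,
      decayCorrectedActivityMBq = x$decay_corrected_activity_mbq,
      tAcqH = x$t_acq_h)
}

#' Export a kinetic curve as CSV
#' @param curve a \linkS4class{KineticCurve}.
#' @param path CSV path.
#' @return \code{path}, invisibly.
#' @export
writeKineticCurve <- function(curve, path) {
  utils::write.csv(data.frame(time_h = curve@times,
                              activity = curve@activities,
                              sd = curve@sds, unit = curve@unit,
                              label = curve@label),
                   path, row.names = FALSE)
  invisible(path)
}
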
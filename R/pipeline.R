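## Pipeline orchestration: calibrate -> kinetics -> TIA -> decay
## substitution -> dose -> grading -> reports, with a run manifest.

#' Pipeline parameters
#'
#' @param peakVolumeCc peak-sphere volume for lesion curves, cc.
#' @param transport a \code{TransportConfig}.
#' @param gradingMetric metric the automated grading uses:
#'   "dose_transport" (default; mean VOI absorbed dose from the transport
#'   engine), "dose_local" (local-deposition dose) or "tia" (per-mass
#'   TIA).
#' @param mediastinumVoi,liverVoi names of the reference VOIs.
#' @param lesionPattern regular expression selecting lesion VOIs.
#' @param substituteDecay substitute the therapy radionuclide's physical
#'   decay before integrating (TRUE for a theranostic study).
#' @param constants decay constants of the pair.
#' @return a validated parameter list.
#' @export
pipelineParams <- function(peakVolumeCc = 1,
                           transport = transportConfig(),
                           gradingMetric = c("dose_transport", "dose_local",
                                             "tia"),
                           mediastinumVoi = "heart", liverVoi = "liver",
                           lesionPattern = "^lesion",
                           substituteDecay = TRUE,
                           constants = decayConstants()) {
  structure(list(peakVolumeCc = peakVolumeCc, transport = transport,
                 gradingMetric = match.arg(gradingMetric),
                 mediastinumVoi = mediastinumVoi, liverVoi = liverVoi,
                 lesionPattern = lesionPattern,
                 substituteDecay = substituteDecay, constants = constants),
            class = "PipelineParams")
}

#' Run the full dosimetry pipeline on a study
#'
#' Stages: (1) calibration (FAF from the first planar image, calibration
#' factor from the first SPECT frame); (2) VOI time-activity curves (peak
#' curves for lesions); (3) per-VOI tail fits, effective half-lives and
#' TIA, with therapy-radionuclide decay substitution; (4) voxelwise TIA
#' map; (5) absorbed dose (transport engine plus the local-deposition
#' reference), per-VOI mass-weighted mean doses and the statistical
#' uncertainty summary; (6) automated lesion grading; (7) report tables.
#' Every warning-level event (artificial tail points, degenerate fits,
#' grading boundary band) is collected into the manifest.
#'
#' @param study a \linkS4class{StudySeries} with SPECT frames in counts
#'   and a planar image, or a path to a study directory written by
#'   \code{\link{writeStudy}}.
#' @param params a \code{PipelineParams}.
#' @param outputDir optional directory; when given, all stage outputs
#'   (calibration JSON, curve/dose/grade CSVs, TIA and dose maps as
#'   NIfTI, manifest JSON) are written there.
#' @return list with \code{calibration}, \code{curves}, \code{masses},
#'   \code{halfLives}, \code{voiTia}, \code{tiaMap}, \code{qcMap},
#'   \code{dose} (\linkS4class{DoseImage}), \code{doseLocal},
#'   \code{voiDose}, \code{uncertainty}, \code{grades}, \code{reports},
#'   \code{manifest}, \code{params}.
#' @export
runPipeline <- function(study, params = pipelineParams(), outputDir = NULL) {
  if (is.character(study)) study <- readStudy(study)
  stopifnot(is(study, "StudySeries"))
  notes <- character(0)
  note <- function(stage) function(w) {
    notes <<- c(notes, sprintf("[%s] %s", stage, conditionMessage(w)))
    if (inherits(w, "warning")) invokeRestart("muffleWarning")
    else if (inherits(w, "message")) invokeRestart("muffleMessage")
  }
  stage <- function(name, expr) {
    withCallingHandlers(expr, warning = note(name), message = note(name))
  }
  cst <- params$constants

  ## 1 -- calibration
  cal <- stage("calibrate", calibrateStudy(study, cst$lambdaImaging))
  study <- cal$study

  if (length(study@times) < 3L)
    stop("kinetics stage requires at least 3 time points")

  ## masses from the CT on the SPECT grid
  if (is.null(study@ct)) stop("study has no CT image for VOI masses")
  masses <- stage("mass", lapply(study@masks, function(m)
    voiMass(study@ct, m)))

  ## 2/3 -- curves, fits, half-lives, TIA
  isLesion <- grepl(params$lesionPattern, names(study@masks))
  curves <- stage("kinetics", {
    cs <- lapply(seq_along(study@masks), function(i) {
      if (isLesion[i]) {
        pk <- peakCurve(study, study@masks[[i]], params$peakVolumeCc)
        pk$curve
      } else voiActivityCurve(study, study@masks[[i]])
    })
    names(cs) <- names(study@masks)
    cs
  })
  fitsImaging <- stage("tailfit", lapply(curves, fitTail,
                                         lambdaFallback = cst$lambdaImaging))
  halfLives <- data.frame(
    voi = names(curves),
    t_eff_h = vapply(fitsImaging, effectiveHalfLife, 0),
    degenerate = vapply(fitsImaging, function(f) f@degenerate, FALSE),
    artificial_point = vapply(fitsImaging, function(f) f@artificialPoint,
                              FALSE))
  tias <- stage("tia", lapply(curves, voiTia,
                              substitute = params$substituteDecay,
                              constants = cst))
  voiTiaTab <- data.frame(
    voi = names(curves),
    mass_kg = vapply(masses, function(m) m$mass_kg, 0)[names(curves)],
    tia_mbq_h = vapply(tias, function(x) x$tia, 0),
    tia_mbq_h_per_kg_per_mbq = vapply(names(curves), function(nm)
      tias[[nm]]$tia / masses[[nm]]$mass_kg / study@injectedActivityMBq, 0))

  ## 4 -- voxelwise TIA (per injected MBq)
  vox <- stage("voxel-tia", voxelTiaMap(study,
                                        substitute = params$substituteDecay,
                                        constants = cst))
  tiaPerMbq <- .likeImage(vox$tia,
                          vox$tia@values / study@injectedActivityMBq,
                          "MBq.h")

  ## 5 -- dose
  density <- huToDensity(study@ct)
  spectrum <- loadY90Spectrum()
  dose <- stage("dose", simulateDose(tiaPerMbq, density, spectrum,
                                     params$transport))
  doseLocal <- stage("dose", localDepositionDose(tiaPerMbq, density,
                                                 spectrum))
  voiDose <- data.frame(
    voi = names(study@masks),
    mass_g = vapply(masses, function(m) m$mass_g, 0)[names(study@masks)],
    mean_dose_cgy_per_mbq = vapply(study@masks, function(m)
      voiMeanDose(dose, m, density), 0),
    mean_dose_local_cgy_per_mbq = vapply(study@masks, function(m)
      voiMeanDose(doseLocal, m, density), 0))
  unc <- stage("dose", uncertaintyCheck(dose))

  ## 6 -- grading
  metricCol <- switch(params$gradingMetric,
                      dose_transport = "mean_dose_cgy_per_mbq",
                      dose_local = "mean_dose_local_cgy_per_mbq",
                      tia = NULL)
  metricOf <- function(voi) {
    if (is.null(metricCol))
      voiTiaTab$tia_mbq_h_per_kg_per_mbq[voiTiaTab$voi == voi]
    else voiDose[[metricCol]][voiDose$voi == voi]
  }
  lesions <- names(study@masks)[isLesion]
  grades <- stage("grade", {
    lm <- vapply(lesions, metricOf, 0)
    gradeLesions(lm, metricOf(params$mediastinumVoi),
                 metricOf(params$liverVoi), metric = params$gradingMetric)
  })

  result <- list(calibration = cal$calibration, curves = curves,
                 masses = masses, halfLives = halfLives,
                 voiTia = voiTiaTab, tiaMap = tiaPerMbq, qcMap = vox$qc,
                 dose = dose, doseLocal = doseLocal, voiDose = voiDose,
                 uncertainty = unc, grades = grades, params = params)
  result$reports <- buildReports(result)
  result$manifest <- list(
    package = "voxdosim",
    version = as.character(utils::packageVersion("voxdosim")),
    times_h = study@times,
    injected_activity_mbq = study@injectedActivityMBq,
    transport = unclass(params$transport),
    grading_metric = params$gradingMetric,
    substitute_decay = params$substituteDecay,
    half_lives_h = c(imaging = cst$halfLifeImaging,
                     therapy = cst$halfLifeTherapy),
    warnings = notes,
    stages = c("calibrate", "mass", "kinetics", "tailfit", "tia",
               "voxel-tia", "dose", "grade", "report"))

  if (!is.null(outputDir)) .writePipelineOutputs(result, outputDir)
  result
}

.writePipelineOutputs <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeCalibration(result$calibration, file.path(dir, "calibration.json"))
  writeReports(result$reports, dir)
  utils::write.csv(result$voiTia, file.path(dir, "tia_voi.csv"),
                   row.names = FALSE)
  utils::write.csv(result$grades, file.path(dir, "grades.csv"),
                   row.names = FALSE)
  writeVoxelImage(result$tiaMap, file.path(dir, "tia_map.nii.gz"))
  writeVoxelImage(result$qcMap, file.path(dir, "tia_qc.nii.gz"))
  writeVoxelImage(result$dose@dose, file.path(dir, "dose.nii.gz"))
  writeVoxelImage(.likeImage(result$dose@dose,
                             ifelse(is.na(result$dose@relUncertainty), 0,
                                    result$dose@relUncertainty), "arb"),
                  file.path(dir, "dose_uncertainty.nii.gz"))
  ## manifest last, atomically: a manifest implies a complete run
  tmp <- file.path(dir, ".manifest.json.tmp")
  jsonlite::write_json(result$manifest, tmp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  file.rename(tmp, file.path(dir, "manifest.json"))
  invisible(dir)
}

#' Write a study to a directory
#'
#' SPECT frames, CT, planar image and the VOI label volume as NIfTI, plus
#' a metadata sidecar (times, injected activity, FOV, units, region
#' names). \code{\link{readStudy}} restores the study.
#'
#' @param study a \linkS4class{StudySeries}.
#' @param dir target directory.
#' @return \code{dir}, invisibly.
#' @export
writeStudy <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(study@times))
    writeVoxelImage(study@spect[[i]],
                    file.path(dir, sprintf("spect_%02d.nii.gz", i)))
  if (!is.null(study@ct))
    writeVoxelImage(study@ct, file.path(dir, "ct.nii.gz"))
  if (!is.null(study@planar))
    writePlanarImage(study@planar, file.path(dir, "planar.nii.gz"))
  if (length(study@masks)) {
    ref <- study@masks[[1L]]
    lab <- array(0, dim(ref@mask))
    for (i in seq_along(study@masks)) lab[study@masks[[i]]@mask] <- i
    writeVoxelImage(voxelImage(lab, ref@spacing, ref@origin, "arb"),
                    file.path(dir, "masks.nii.gz"))
  }
  meta <- list(times_h = study@times,
               injected_activity_mbq = study@injectedActivityMBq,
               fov_range_mm = study@fovRange,
               spect_unit = study@spect[[1L]]@unit,
               mask_names = as.list(names(study@masks)))
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a study directory
#' @param dir directory written by \code{\link{writeStudy}}.
#' @return A \linkS4class{StudySeries}.
#' @export
readStudy <- function(dir) {
  metaPath <- file.path(dir, "metadata.json")
  if (!file.exists(metaPath)) stop("no metadata.json in ", dir)
  meta <- jsonlite::read_json(metaPath, simplifyVector = TRUE)
  times <- meta$times_h
  spect <- lapply(seq_along(times), function(i) {
    p <- file.path(dir, sprintf("spect_%02d.nii.gz", i))
    if (!file.exists(p)) stop("missing SPECT frame: ", p)
    readVoxelImage(p, unit = meta$spect_unit)
  })
  ct <- if (file.exists(file.path(dir, "ct.nii.gz")))
    readVoxelImage(file.path(dir, "ct.nii.gz"), unit = "HU") else NULL
  planar <- if (file.exists(file.path(dir, "planar.nii.gz")))
    readPlanarImage(file.path(dir, "planar.nii.gz")) else NULL
  masks <- list()
  if (file.exists(file.path(dir, "masks.nii.gz"))) {
    lab <- readVoxelImage(file.path(dir, "masks.nii.gz"))
    nms <- unlist(meta$mask_names)
    masks <- lapply(seq_along(nms), function(i)
      voiMask(nms[i], lab@values == i, reference = lab))
    names(masks) <- nms
  }
  studySeries(times = times, spect = spect, ct = ct, planar = planar,
              masks = masks,
              injectedActivityMBq = meta$injected_activity_mbq,
              fovRange = meta$fov_range_mm)
}
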
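## Automated lesion grading on a 0-IV scale against mediastinal blood
## pool and liver reference uptake, and visual-vs-computed concordance.

.GRADE_LEVELS <- c("0", "I", "II", "III", "IV")

#' Grade one lesion against mediastinum and liver
#'
#' Five-level scale on the lesion-to-reference ratio of an uptake or
#' absorbed-dose metric: grade 0 below 20\% of mediastinum, I below 80\%,
#' II between 80 and 120\% of mediastinum, III above 120\% of mediastinum
#' but below 80\% of liver, IV above 120\% of liver. Conditions are
#' evaluated in the order 0, I, II, III, IV with strict inequalities;
#' the 80--120\%-of-liver band above the mediastinal threshold, which the
#' scale leaves unassigned, maps to grade III and is flagged.
#'
#' @param lesionMetric,mediastinumMetric,liverMetric the metric value for
#'   the lesion and the two references (same unit; references > 0).
#' @param lesionId identifier carried into the result.
#' @param metric name of the metric (bookkeeping).
#' @return A \linkS4class{GradeResult}.
#' @examples
#' computeGrade(0.1, 1, 2)@grade   # "0"
#' computeGrade(1.0, 1, 2)@grade   # "II"
#' @export
computeGrade <- function(lesionMetric, mediastinumMetric, liverMetric,
                         lesionId = "lesion", metric = "dose") {
  if (mediastinumMetric <= 0 || liverMetric <= 0)
    stop("reference metrics must be positive")
  if (lesionMetric < 0) stop("lesion metric must be non-negative")
  rm_ <- lesionMetric / mediastinumMetric
  rl <- lesionMetric / liverMetric
  band <- FALSE
  grade <- if (rm_ < 0.20) "0"
    else if (rm_ < 0.80) "I"
    else if (rm_ < 1.20) "II"
    else if (rl > 1.20) "IV"
    else {
      band <- rl >= 0.80   # unassigned band of the scale -> III
      "III"
    }
  if (band)
    message(sprintf(
      "lesion '%s': metric in the 80-120%% of liver band above mediastinum; assigned grade III",
      lesionId))
  new("GradeResult", lesionId = as.character(lesionId), metric = metric,
      ratioMediastinum = rm_, ratioLiver = rl, grade = grade,
      boundaryBand = band)
}

#' Grade a set of lesions
#'
#' @param lesionMetrics named numeric vector of lesion metric values.
#' @param mediastinumMetric,liverMetric reference values.
#' @param metric metric name.
#' @return data.frame with one row per lesion: id, ratios, grade,
#'   boundary-band flag.
#' @export
gradeLesions <- function(lesionMetrics, mediastinumMetric, liverMetric,
                         metric = "dose") {
  ids <- names(lesionMetrics)
  if (is.null(ids)) ids <- paste0("lesion", seq_along(lesionMetrics))
  rows <- lapply(seq_along(lesionMetrics), function(i)
    computeGrade(lesionMetrics[[i]], mediastinumMetric, liverMetric,
                 ids[i], metric))
  data.frame(
    lesion = vapply(rows, function(g) g@lesionId, ""),
    metric_value = as.numeric(lesionMetrics),
    ratio_mediastinum = vapply(rows, function(g) g@ratioMediastinum, 0),
    ratio_liver = vapply(rows, function(g) g@ratioLiver, 0),
    grade = vapply(rows, function(g) g@grade, ""),
    boundary_band = vapply(rows, function(g) g@boundaryBand, FALSE),
    stringsAsFactors = FALSE)
}

#' Visual-vs-computed grading concordance
#'
#' @param visual,computed equal-length vectors of grades ("0", "I", ...,
#'   "IV"), factors or characters.
#' @return list with \code{nDiscordant}, \code{n}, and a 5x5
#'   \code{confusion} matrix (rows visual, columns computed).
#' @export
concordance <- function(visual, computed) {
  visual <- as.character(visual); computed <- as.character(computed)
  if (length(visual) != length(computed))
    stop("visual and computed grade lists must have equal length")
  bad <- !(visual %in% .GRADE_LEVELS) | !(computed %in% .GRADE_LEVELS)
  if (any(bad)) stop("grades must be one of: ",
                     paste(.GRADE_LEVELS, collapse = ", "))
  vf <- factor(visual, levels = .GRADE_LEVELS)
  cf <- factor(computed, levels = .GRADE_LEVELS)
  conf <- table(visual = vf, computed = cf)
  list(nDiscordant = sum(visual != computed), n = length(visual),
       confusion = unclass(conf))
}

#' Bundled reference lesion-grading table
#'
#' Visual and automatically computed grades for the supra-centimetric
#' lung lesions (grade above 0) of a first-in-human In-111 antibody
#' radioimmunotherapy study, shipped as a plain-text fixture. One row is
#' typographically garbled in transcription; the file header documents
#' the reading adopted (a concordant pair, consistent with the set's
#' invariant that exactly five lesions are discordant, all annotated
#' "lower grade").
#'
#' @param path optional alternative CSV.
#' @return data.frame with patient, lesion, visual, computed, note.
#' @export
readLesionGrades <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "lesion_grades.csv",
                        package = "voxdosim", mustWork = TRUE)
  utils::read.csv(path, comment.char = "#", colClasses = c(
    patient = "integer", lesion = "integer", visual = "character",
    computed = "character", note = "character"))
}
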
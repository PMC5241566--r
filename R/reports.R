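## Report tables: organ/lesion kinetics, per-VOI absorbed dose,
## lesion-to-liver ratios and effective half-lives.

#' Build report tables from pipeline results
#'
#' @param result the list returned by \code{\link{runPipeline}}.
#' @return named list of data.frames: \code{curves} (long-format VOI
#'   activity curves, \%IA/kg), \code{voiDose} (per-VOI mass and mean
#'   absorbed dose, transport and local-deposition), \code{lesionRatios}
#'   (lesion-to-liver and lesion-to-mediastinum dose ratios),
#'   \code{halfLives} (per-VOI effective half-life), and \code{summary}
#'   (median, range and coefficient of variation of the organ and lesion
#'   dose vectors).
#' @export
buildReports <- function(result) {
  curves <- do.call(rbind, lapply(names(result$curves), function(nm) {
    cv <- result$curves[[nm]]
    data.frame(voi = nm, time_h = cv@times, activity = cv@activities,
               sd = cv@sds, unit = cv@unit)
  }))
  voiDose <- result$voiDose
  liver <- voiDose$mean_dose_cgy_per_mbq[voiDose$voi == result$params$liverVoi]
  mediast <- voiDose$mean_dose_cgy_per_mbq[voiDose$voi == result$params$mediastinumVoi]
  les <- voiDose[grepl(result$params$lesionPattern, voiDose$voi), ]
  lesionRatios <- data.frame(
    lesion = les$voi,
    dose_cgy_per_mbq = les$mean_dose_cgy_per_mbq,
    ratio_liver = les$mean_dose_cgy_per_mbq / liver,
    ratio_mediastinum = les$mean_dose_cgy_per_mbq / mediast)
  halfLives <- result$halfLives
  sumOf <- function(x) {
    x <- x[is.finite(x)]
    data.frame(n = length(x), median = stats::median(x), min = min(x),
               max = max(x), cv = stats::sd(x) / mean(x))
  }
  isLesion <- grepl(result$params$lesionPattern, voiDose$voi)
  summary <- rbind(
    cbind(group = "organs", sumOf(voiDose$mean_dose_cgy_per_mbq[!isLesion])),
    cbind(group = "lesions", sumOf(voiDose$mean_dose_cgy_per_mbq[isLesion])))
  list(curves = curves, voiDose = voiDose, lesionRatios = lesionRatios,
       halfLives = halfLives, summary = summary)
}

#' Write report tables as CSV files
#' @param reports list from \code{\link{buildReports}}.
#' @param dir output directory (created if needed).
#' @return the file paths, invisibly.
#' @export
writeReports <- function(reports, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(names(reports), function(nm) {
    p <- file.path(dir, paste0(nm, ".csv"))
    utils::write.csv(reports[[nm]], p, row.names = FALSE)
    p
  }, "")
  invisible(paths)
}
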
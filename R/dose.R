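## Absorbed dose from a TIA map: Monte Carlo CSDA transport and the
## closed-form local-deposition reference mode.
##
## Scaling: a TIA of 1 MBq h corresponds to 3.6e9 disintegrations
## (1 MBq = 1e6 decays/s, 1 h = 3600 s). One beta particle of the
## spectrum is emitted per disintegration. 1 keV = 1.602176634e-16 J;
## dose (Gy) = J / kg; reported in cGy per injected MBq when the TIA map
## is per injected MBq.

.DECAYS_PER_MBQ_H <- 3.6e9
.JOULE_PER_KEV <- 1.602176634e-16

#' Simulate the absorbed dose distribution
#'
#' Monte Carlo beta-particle transport in straight-line
#' continuous-slowing-down approximation: emission sites are sampled
#' proportional to the voxel TIA, directions isotropically, energies from
#' the beta spectrum; energy is deposited along the density-scaled
#' residual range and the deposit map is scaled to the total number of
#' disintegrations. The statistical uncertainty is estimated from history
#' batches. Same seed and configuration give a bitwise-identical result.
#'
#' @param tia \linkS4class{VoxelImage} of time-integrated activity
#'   (MBq h per voxel, per injected MBq) on the SPECT-resolution grid.
#' @param density \linkS4class{VoxelImage} of mass density (g/cc) on the
#'   same grid (from \code{\link{huToDensity}}).
#' @param spectrum a \linkS4class{BetaSpectrum} (default the bundled Y-90
#'   table).
#' @param cfg a \code{TransportConfig}; \code{mode = "local_deposition"}
#'   dispatches to \code{\link{localDepositionDose}}.
#' @param tallyMask optional \linkS4class{VOIMask}: the mass-weighted mean
#'   dose over this region is additionally tallied per history batch, and
#'   returned as attribute \code{"tally"} of the result -- a list with the
#'   per-batch estimates (\code{batchDoseCGy}), their mean and the
#'   standard error of the mean. Use this for region-level Monte Carlo
#'   error bars, which per-voxel uncertainties cannot provide.
#' @return A \linkS4class{DoseImage} in cGy per injected MBq.
#' @export
simulateDose <- function(tia, density, spectrum = loadY90Spectrum(),
                         cfg = transportConfig(), tallyMask = NULL) {
  .stopUnlessSameGrid(tia, density, "TIA and density maps")
  if (all(tia@values == 0)) {
    z <- array(0, dim(tia@values))
    return(new("DoseImage",
               dose = .likeImage(tia, z, "cGy"),
               relUncertainty = array(NA_real_, dim(tia@values)),
               nHistories = cfg$nHistories, nBatches = cfg$nBatches,
               seed = cfg$seed, mode = cfg$mode,
               emittedKeV = 0, depositedKeV = 0, escapedKeV = 0))
  }
  if (cfg$mode == "local_deposition")
    return(localDepositionDose(tia, density, spectrum,
                               densityFloor = cfg$densityFloor,
                               seed = cfg$seed))
  rho <- pmax(density@values, cfg$densityFloor)
  cdf <- .spectrumCdf(spectrum)
  rt <- csdaRangeTable(maxEnergyKeV = spectrum@endpoint * 1.05 + 10)
  tallyW <- numeric(0)
  if (!is.null(tallyMask)) {
    .stopUnlessSameGrid(tia, tallyMask, "TIA and tally mask")
    ## weight = 1 / total region mass -> tally is mean dose numerator
    mKg <- rho * prod(tia@spacing) / 1e6
    tallyW <- as.numeric(tallyMask@mask) / sum(mKg[tallyMask@mask])
  }
  set.seed(cfg$seed)
  res <- .transportCsda(as.numeric(tia@values), dim(tia@values),
                        tia@spacing, cdf$p, cdf$e,
                        rt$energy_kev, rt$range_mm, as.numeric(rho),
                        tallyW, cfg$stepMm, cfg$nHistories, cfg$nBatches)
  d <- dim(tia@values)
  totalDecays <- sum(tia@values) * .DECAYS_PER_MBQ_H
  decaysPerHist <- totalDecays / cfg$nHistories
  massKg <- rho * prod(tia@spacing) / 1000 / 1000  # g/cc * cc -> g -> kg
  doseCGy <- array(res$edep * decaysPerHist * .JOULE_PER_KEV / massKg * 100, d)
  ## batch statistics -> relative standard error of the total
  ## (edep = nb * mean(batch); SE(edep)/edep = SE(mean)/mean)
  nb <- res$nBatches
  bm <- res$batchSum / nb
  bv <- pmax(res$batchSumSq / nb - bm^2, 0) * nb / max(nb - 1, 1)
  relSe <- array(ifelse(res$edep > 0, sqrt(bv / nb) / bm, NA_real_), d)
  out <- new("DoseImage", dose = .likeImage(tia, doseCGy, "cGy"),
             relUncertainty = relSe, nHistories = cfg$nHistories,
             nBatches = as.integer(nb), seed = cfg$seed,
             mode = "csda_straight_line",
             emittedKeV = res$emitted, depositedKeV = sum(res$edep),
      escapedKeV = res$escaped)
  if (!is.null(tallyMask)) {
    ## per-batch estimate of the mass-weighted mean region dose, cGy/MBq
    est <- res$tallyBatch * (totalDecays / res$histBatch) *
      .JOULE_PER_KEV * 100
    attr(out, "tally") <- list(
      voi = tallyMask@name, batchDoseCGy = est, meanDoseCGy = mean(est),
      seDoseCGy = stats::sd(est) / sqrt(length(est)))
  }
  out
}

#' Closed-form local-deposition dose
#'
#' Reference mode: every disintegration deposits the spectrum's mean
#' energy in its source voxel. Exact under charged-particle equilibrium
#' (uniform activity in a homogeneous medium large against the electron
#' range), and the analytic cross-check for the transport engine.
#'
#' @param tia \linkS4class{VoxelImage}, MBq h per voxel.
#' @param density \linkS4class{VoxelImage}, g/cc, same grid.
#' @param spectrum a \linkS4class{BetaSpectrum}.
#' @param densityFloor minimum density used for voxel mass.
#' @param seed recorded in the output for provenance (no randomness).
#' @return A \linkS4class{DoseImage} in cGy per injected MBq, zero
#'   uncertainty.
#' @export
localDepositionDose <- function(tia, density, spectrum = loadY90Spectrum(),
                                densityFloor = 0.001, seed = 0L) {
  .stopUnlessSameGrid(tia, density, "TIA and density maps")
  rho <- pmax(density@values, densityFloor)
  massKg <- rho * prod(tia@spacing) / 1000 / 1000
  if (any(massKg <= 0)) stop("zero-mass voxel")
  eKeV <- tia@values * .DECAYS_PER_MBQ_H * spectrum@meanEnergy
  doseCGy <- eKeV * .JOULE_PER_KEV / massKg * 100
  new("DoseImage", dose = .likeImage(tia, doseCGy, "cGy"),
      relUncertainty = array(ifelse(doseCGy > 0, 0, NA_real_), dim(doseCGy)),
      nHistories = 0, nBatches = 2L, seed = as.integer(seed),
      mode = "local_deposition",
      emittedKeV = sum(eKeV), depositedKeV = sum(eKeV), escapedKeV = 0)
}

#' Mass-weighted mean VOI dose
#'
#' Total deposited energy over the VOI divided by the total VOI mass,
#' i.e. the mass-weighted mean of the voxel doses.
#'
#' @param dose a \linkS4class{DoseImage} (or dose \linkS4class{VoxelImage}).
#' @param mask non-empty \linkS4class{VOIMask} on the dose grid.
#' @param density \linkS4class{VoxelImage} of density (g/cc) on the same
#'   grid.
#' @param densityFloor minimum density.
#' @return mean absorbed dose (cGy per injected MBq).
#' @export
voiMeanDose <- function(dose, mask, density, densityFloor = 0.001) {
  dimg <- if (is(dose, "DoseImage")) dose@dose else dose
  .stopUnlessSameGrid(dimg, mask, "dose and mask")
  .stopUnlessSameGrid(dimg, density, "dose and density")
  m <- mask@mask
  if (!any(m)) stop(sprintf("VOI '%s' is empty", mask@name))
  w <- pmax(density@values[m], densityFloor)   # voxel volume cancels
  sum(dimg@values[m] * w) / sum(w)
}

#' Statistical-uncertainty summary of a dose map
#'
#' Maximum relative batch standard error among voxels whose dose exceeds
#' a fraction of the maximum dose (high-dose voxels are the clinically
#' relevant ones; low-dose voxels have large relative noise by
#' construction).
#'
#' @param dose a \linkS4class{DoseImage} with >= 2 batches.
#' @param thresholdFrac dose threshold as a fraction of the maximum
#'   (default 0.25).
#' @return list with \code{maxRelUncertainty}, \code{nVoxels} considered
#'   and \code{thresholdFrac}.
#' @export
uncertaintyCheck <- function(dose, thresholdFrac = 0.25) {
  if (dose@nBatches < 2L) stop("need at least 2 history batches")
  dv <- dose@dose@values
  sel <- dv > thresholdFrac * max(dv)
  if (!any(sel)) stop("no voxels above the dose threshold")
  list(maxRelUncertainty = max(dose@relUncertainty[sel], na.rm = TRUE),
       nVoxels = sum(sel), thresholdFrac = thresholdFrac)
}
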
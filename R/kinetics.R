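## Time-activity curves, mono-exponential tail fitting, and
## time-integrated activity (TIA).
##
## TIA = integral of A(t) from 0 to infinity, computed in two steps:
## trapezoid over the measured curve (with A(0) = 0, activity is injected
## at t = 0) plus an analytic mono-exponential tail fitted to the last
## two or three points.

#' VOI time-activity curve
#'
#' Per time point, the total activity over the mask, A_h(t) = sum of
#' voxel activities, and the voxel-level dispersion (population SD of the
#' voxel values), which quantifies activity heterogeneity within the VOI
#' and serves as the fit weight.
#'
#' @param study calibrated \linkS4class{StudySeries} (frames in MBq).
#' @param mask non-empty \linkS4class{VOIMask} on the SPECT grid.
#' @return A \linkS4class{KineticCurve} in MBq.
#' @export
voiActivityCurve <- function(study, mask) {
  .stopUnlessSameGrid(study@spect[[1L]], mask, "SPECT frames and mask")
  m <- mask@mask
  if (!any(m)) stop(sprintf("VOI '%s' is empty", mask@name))
  tot <- vapply(study@spect, function(im) sum(im@values[m]), numeric(1))
  sds <- vapply(study@spect, function(im) {
    v <- im@values[m]
    sqrt(max(mean(v^2) - mean(v)^2, 0))
  }, numeric(1))
  kineticCurve(study@times, tot, sds, unit = "MBq", label = mask@name)
}

#' Radius of the spherical mean kernel for a given volume
#' @param volumeCc kernel volume in cc (default 1).
#' @return radius in mm, (3 V / 4 pi)^(1/3).
#' @examples
#' peakKernelRadius(1)  # ~6.2 mm
#' @export
peakKernelRadius <- function(volumeCc = 1) {
  (3 * volumeCc * 1000 / (4 * pi))^(1 / 3)
}

## integer voxel offsets within radiusMm of a voxel centre
.sphereOffsets <- function(spacing, radiusMm) {
  r <- ceiling(radiusMm / spacing)
  off <- as.matrix(expand.grid(i = -r[1]:r[1], j = -r[2]:r[2], k = -r[3]:r[3]))
  d2 <- (off[, 1] * spacing[1])^2 + (off[, 2] * spacing[2])^2 +
        (off[, 3] * spacing[3])^2
  off[d2 <= radiusMm^2, , drop = FALSE]
}

## mean filter with a spherical support; zero-padded, normalised by the
## full kernel size
.sphericalMeanFilter <- function(vol, spacing, radiusMm) {
  off <- .sphereOffsets(spacing, radiusMm)
  d <- dim(vol)
  acc <- array(0, d)
  for (r in seq_len(nrow(off))) {
    sh <- off[r, ]
    src <- list(
      max(1, 1 - sh[1]):min(d[1], d[1] - sh[1]),
      max(1, 1 - sh[2]):min(d[2], d[2] - sh[2]),
      max(1, 1 - sh[3]):min(d[3], d[3] - sh[3]))
    dst <- list(src[[1]] + sh[1], src[[2]] + sh[2], src[[3]] + sh[3])
    acc[dst[[1]], dst[[2]], dst[[3]]] <-
      acc[dst[[1]], dst[[2]], dst[[3]]] + vol[src[[1]], src[[2]], src[[3]]]
  }
  acc / nrow(off)
}

#' Peak (1 cc spherical) time-activity curve of a VOI
#'
#' Analogue of the PET SUV-peak: each frame is convolved with a spherical
#' mean kernel of the requested volume; the positions of the per-frame
#' filtered maxima inside the VOI are averaged into a single fixed centre,
#' and the curve is the mean activity inside the sphere at that centre at
#' each time point. Used for lesions, where partial-volume effects depress
#' whole-mask means.
#'
#' @param study calibrated \linkS4class{StudySeries}.
#' @param mask lesion \linkS4class{VOIMask}.
#' @param peakVolumeCc sphere volume, cc (default 1).
#' @return list with \code{center} (mm), \code{centerSdMm} (SD of the
#'   per-frame argmax positions about the mean, mm), and \code{curve}
#'   (a \linkS4class{KineticCurve} of mean activity per voxel in the
#'   sphere, MBq).
#' @export
peakCurve <- function(study, mask, peakVolumeCc = 1) {
  .stopUnlessSameGrid(study@spect[[1L]], mask, "SPECT frames and mask")
  sp <- mask@spacing
  radius <- peakKernelRadius(peakVolumeCc)
  if (voiVolumeCc(mask) < peakVolumeCc) {
    warning(sprintf(
      "VOI '%s' (%.2f cc) smaller than the %.1f cc peak sphere; using the whole-mask mean",
      mask@name, voiVolumeCc(mask), peakVolumeCc))
    m <- mask@mask
    act <- vapply(study@spect, function(im) mean(im@values[m]), numeric(1))
    sds <- vapply(study@spect, function(im) stats::sd(im@values[m]), numeric(1))
    sds[is.na(sds)] <- 0
    return(list(center = .maskCentroid(mask), centerSdMm = NA_real_,
                curve = kineticCurve(study@times, act, sds, "MBq",
                                     paste0(mask@name, ".peak"))))
  }
  idx <- which(mask@mask)
  d <- dim(mask@mask)
  centers <- voxelCenters(study@spect[[1L]])
  pos <- matrix(0, length(study@spect), 3L)
  for (f in seq_along(study@spect)) {
    filt <- .sphericalMeanFilter(study@spect[[f]]@values, sp, radius)
    best <- idx[which.max(filt[idx])]
    ijk <- arrayInd(best, d)
    pos[f, ] <- c(centers[[1]][ijk[1]], centers[[2]][ijk[2]],
                  centers[[3]][ijk[3]])
  }
  center <- colMeans(pos)
  centerSd <- sqrt(mean(rowSums(sweep(pos, 2, center)^2)))
  ## fixed sphere at the averaged centre
  sphereIdx <- .sphereVoxelIndices(study@spect[[1L]], center, radius)
  act <- vapply(study@spect, function(im) mean(im@values[sphereIdx]),
                numeric(1))
  sds <- vapply(study@spect, function(im) stats::sd(im@values[sphereIdx]),
                numeric(1))
  sds[is.na(sds)] <- 0
  list(center = center, centerSdMm = centerSd,
       curve = kineticCurve(study@times, act, sds, "MBq",
                            paste0(mask@name, ".peak")))
}

.maskCentroid <- function(mask) {
  ijk <- arrayInd(which(mask@mask), dim(mask@mask))
  mask@origin + (colMeans(ijk) - 0.5) * mask@spacing
}

.sphereVoxelIndices <- function(image, centerMm, radiusMm) {
  cx <- voxelCenters(image)
  d <- dim(image@values)
  dx2 <- (cx[[1]] - centerMm[1])^2
  dy2 <- (cx[[2]] - centerMm[2])^2
  dz2 <- (cx[[3]] - centerMm[3])^2
  dist2 <- outer(outer(dx2, dy2, `+`), dz2, `+`)
  which(dist2 <= radiusMm^2)
}

#' Select the tail points of a kinetic curve
#'
#' The last three measured points are used, except when the curve maximum
#' falls at or after the third-from-last point, in which case only the
#' last two are used (fitting a decay through a rising segment is
#' avoided). If the final point still exceeds its predecessor, an
#' artificial point at t_last + 60 h with half the maximum activity is
#' appended to force a decreasing tail, and included in the fit.
#'
#' @param curve a \linkS4class{KineticCurve} with >= 3 measured points.
#' @return list with \code{times}, \code{activities}, \code{sds} of the
#'   selected points, \code{indices} into the measured curve (NA for the
#'   artificial point) and \code{artificial} flag.
#' @export
selectTailPoints <- function(curve) {
  n <- length(curve@times)
  if (n < 3L) stop("tail selection requires at least 3 measured points")
  a <- curve@activities; t <- curve@times; s <- curve@sds
  artificial <- a[n] > a[n - 1L]
  if (artificial) {
    message(sprintf(
      "curve '%s': activity rises into the last point; artificial point appended at %.0f h (t_last + 60 h) with half the maximum activity",
      curve@label, t[n] + 60))
    t <- c(t, t[n] + 60)
    a <- c(a, 0.5 * max(a))
    s <- c(s, 0)
    idx <- c(seq_len(n), NA_integer_)
    n <- n + 1L
  } else {
    idx <- seq_len(n)
  }
  imax <- which.max(a)
  use <- if (imax >= n - 2L) (n - 1L):n else (n - 2L):n
  list(times = t[use], activities = a[use], sds = s[use],
       indices = idx[use], artificial = artificial)
}

#' Fit a mono-exponential tail A0 exp(-lambda t)
#'
#' With two points the fit is the exact closed form; with three or more,
#' a weighted Levenberg-Marquardt least-squares fit (weights 1/SD, SDs
#' floored at 1e-6 of the maximum activity; at most 100 iterations). A
#' non-decaying two-point tail is flagged degenerate and lambda falls
#' back to the physical decay constant.
#'
#' @param times,activities tail points (>= 2, positive activities).
#' @param sds within-VOI SDs used as weights (0 allowed; floored).
#' @param lambdaFallback decay constant (1/h) used when the tail does not
#'   decay (default In-111 physical).
#' @param maxIter LM iteration cap.
#' @return A \linkS4class{TailFit}.
#' @examples
#' f <- fitMonoexpTail(c(72, 144), 5 * exp(-0.01 * c(72, 144)))
#' c(f@a0, f@lambda)
#' @export
fitMonoexpTail <- function(times, activities, sds = rep(0, length(times)),
                           lambdaFallback = log(2) / 67.3, maxIter = 100) {
  if (is(times, "KineticCurve")) {
    curve <- times
    times <- curve@times; activities <- curve@activities; sds <- curve@sds
  }
  n <- length(times)
  stopifnot(n >= 2L, length(activities) == n)
  if (all(activities <= 0)) {
    return(new("TailFit", a0 = 0, lambda = lambdaFallback,
               nPointsUsed = as.integer(n), artificialPoint = FALSE,
               degenerate = TRUE, weights = rep(1, n)))
  }
  w <- 1 / pmax(sds, 1e-6 * max(activities))
  w <- w / max(w)
  if (n == 2L) {
    if (activities[2L] >= activities[1L] || activities[2L] <= 0) {
      ## non-decaying two-point tail: physical-decay floor, flagged
      lam <- lambdaFallback
      a0 <- activities[1L] * exp(lam * times[1L])
      return(new("TailFit", a0 = a0, lambda = lam, nPointsUsed = 2L,
                 artificialPoint = FALSE, degenerate = TRUE, weights = w))
    }
    lam <- log(activities[1L] / activities[2L]) / (times[2L] - times[1L])
    a0 <- activities[1L] * exp(lam * times[1L])
    return(new("TailFit", a0 = a0, lambda = lam, nPointsUsed = 2L,
               artificialPoint = FALSE, degenerate = FALSE, weights = w))
  }
  ## start values from a log-linear regression on the positive points
  pos <- activities > 0
  st <- stats::lm(log(activities[pos]) ~ times[pos])
  lam0 <- unname(max(-stats::coef(st)[2L], 1e-4))
  a00 <- unname(exp(stats::coef(st)[1L]))
  fit <- tryCatch(
    minpack.lm::nlsLM(
      a ~ a0 * exp(-lambda * t),
      data = data.frame(t = times, a = activities),
      start = list(a0 = a00, lambda = lam0),
      weights = w,
      lower = c(0, 1e-8),
      control = minpack.lm::nls.lm.control(maxiter = maxIter)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(new("TailFit", a0 = a00, lambda = lambdaFallback,
               nPointsUsed = as.integer(n), artificialPoint = FALSE,
               degenerate = TRUE, weights = w))
  }
  cf <- stats::coef(fit)
  degen <- cf[["lambda"]] <= 1e-8
  new("TailFit", a0 = unname(cf[["a0"]]),
      lambda = if (degen) lambdaFallback else unname(cf[["lambda"]]),
      nPointsUsed = as.integer(n), artificialPoint = FALSE,
      degenerate = degen, weights = w)
}

#' Tail-select and fit in one step
#'
#' Applies \code{\link{selectTailPoints}} then
#' \code{\link{fitMonoexpTail}}; the artificial-point flag propagates
#' into the returned fit.
#'
#' @param curve a \linkS4class{KineticCurve} (>= 3 points).
#' @param lambdaFallback see \code{\link{fitMonoexpTail}}.
#' @return A \linkS4class{TailFit}.
#' @export
fitTail <- function(curve, lambdaFallback = log(2) / 67.3) {
  sel <- selectTailPoints(curve)
  fit <- fitMonoexpTail(sel$times, sel$activities, sel$sds, lambdaFallback)
  fit@artificialPoint <- sel$artificial
  fit@nPointsUsed <- as.integer(sum(!is.na(sel$indices)))
  fit
}

#' Integrate a time-activity curve to infinity
#'
#' Trapezoid over [0, t_last] on the measured points with A(0) = 0
#' prepended (the uptake segment is a straight line from the origin to
#' the first sample), plus the analytic tail
#' (A0 / lambda) exp(-lambda t_last) from the fitted mono-exponential.
#'
#' @param curve a \linkS4class{KineticCurve} (measured points only).
#' @param fit a \linkS4class{TailFit} with lambda > 0.
#' @return time-integrated activity, in (curve unit) x h.
#' @export
integrateTia <- function(curve, fit) {
  if (all(curve@activities == 0)) return(0)
  if (fit@lambda <= 0) stop("tail fit must have lambda > 0")
  t <- c(0, curve@times)
  a <- c(0, curve@activities)
  trap <- sum(diff(t) * (utils::head(a, -1) + utils::tail(a, -1)) / 2)
  tail <- fit@a0 / fit@lambda * exp(-fit@lambda * max(curve@times))
  trap + tail
}

#' Substitute the physical decay of the imaging radionuclide
#'
#' The measured activities follow biology x imaging-radionuclide decay.
#' Assuming identical biological kinetics for both members of the
#' theranostic pair, the therapy-radionuclide curve is obtained by
#' multiplying each measured activity by exp((lambda_img - lambda_ther) t)
#' (decay-correct to the biological curve, then re-decay). Applied to the
#' whole curve before tail fitting and integration.
#'
#' @param curve a \linkS4class{KineticCurve}.
#' @param constants list from \code{\link{decayConstants}}.
#' @return the substituted \linkS4class{KineticCurve}.
#' @export
substituteDecay <- function(curve, constants = decayConstants()) {
  f <- exp((constants$lambdaImaging - constants$lambdaTherapy) * curve@times)
  kineticCurve(curve@times, curve@activities * f, curve@sds * f,
               curve@unit, curve@label)
}

#' Effective half-life from a tail fit
#' @param fit a \linkS4class{TailFit} (lambda > 0), or a bare decay
#'   constant in 1/h.
#' @return effective half-life, h (ln 2 / lambda).
#' @export
effectiveHalfLife <- function(fit) {
  lam <- if (is(fit, "TailFit")) fit@lambda else fit
  if (lam <= 0) stop("lambda must be positive")
  log(2) / lam
}

#' Full TIA of one VOI curve
#'
#' Convenience wrapper: optional decay substitution, tail selection,
#' weighted fit, two-step integration.
#'
#' @param curve measured \linkS4class{KineticCurve}.
#' @param substitute if TRUE, substitute the therapy radionuclide decay
#'   first.
#' @param constants decay constants (see \code{\link{decayConstants}}).
#' @return list with \code{tia} (unit x h), \code{fit}
#'   (\linkS4class{TailFit}) and the (possibly substituted) \code{curve}.
#' @export
voiTia <- function(curve, substitute = FALSE, constants = decayConstants()) {
  lamFall <- if (substitute) constants$lambdaTherapy else constants$lambdaImaging
  if (substitute) curve <- substituteDecay(curve, constants)
  fit <- fitTail(curve, lambdaFallback = lamFall)
  list(tia = integrateTia(curve, fit), fit = fit, curve = curve)
}
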
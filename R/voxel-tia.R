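## Voxelwise time-integrated activity.
##
## The per-VOI pipeline (tail selection -> weighted mono-exponential fit
## -> trapezoid + analytic tail) applied independently to every voxel.
## Voxel fits are unweighted (a single voxel has no within-VOI SD) and
## vectorised: voxels are grouped by the tail-selection case they fall in
## and each group is fitted with a vectorised Levenberg-Marquardt
## iteration on the shared time grid.

## vectorised LM for y ~ a0 exp(-lambda t) on a shared time vector.
## t: length k; Y: k x m matrix. Returns list(a0, lambda, ok).
.fitMonoexpVec <- function(t, Y, maxIter = 100) {
  k <- length(t); m <- ncol(Y)
  if (k == 2L) {
    dec <- Y[1, ] > Y[2, ] & Y[2, ] > 0
    lam <- ifelse(dec, log(pmax(Y[1, ], 1e-300) / pmax(Y[2, ], 1e-300)) /
                         (t[2] - t[1]), NA_real_)
    a0 <- ifelse(dec, Y[1, ] * exp(lam * t[1]), NA_real_)
    return(list(a0 = a0, lambda = lam, ok = dec))
  }
  ## log-linear init on shifted-positive values
  Yp <- pmax(Y, 1e-12 * matrix(apply(Y, 2, max), k, m, byrow = TRUE))
  L <- log(Yp)
  tc <- t - mean(t)
  slope <- colSums(tc * L) / sum(tc^2)
  lam <- pmax(-slope, 1e-4)
  a0 <- exp(colMeans(L) + lam * mean(t))
  sse <- function(a0, lam) {
    P <- a0[col(Y)] * exp(-outer(t, lam))
    colSums((Y - P)^2)
  }
  cur <- sse(a0, lam)
  mu <- rep(1e-3, m)
  for (it in seq_len(maxIter)) {
    E <- exp(-outer(t, lam))          # k x m
    P <- a0[col(E)] * E
    R <- Y - P
    J1 <- E                            # d/da0
    J2 <- -P * t                       # d/dlambda (t recycles down columns)
    A11 <- colSums(J1 * J1); A12 <- colSums(J1 * J2); A22 <- colSums(J2 * J2)
    g1 <- colSums(J1 * R);  g2 <- colSums(J2 * R)
    ## LM damping
    D11 <- A11 * (1 + mu); D22 <- A22 * (1 + mu)
    det <- D11 * D22 - A12^2
    det[abs(det) < 1e-300] <- NA
    d_a0 <- (D22 * g1 - A12 * g2) / det
    d_lam <- (D11 * g2 - A12 * g1) / det
    na0 <- a0 + d_a0
    nlam <- pmax(lam + d_lam, 1e-8)
    na0[!is.finite(na0)] <- a0[!is.finite(na0)]
    nlam[!is.finite(nlam)] <- lam[!is.finite(nlam)]
    new <- sse(na0, nlam)
    better <- is.finite(new) & new <= cur
    a0[better] <- na0[better]; lam[better] <- nlam[better]
    cur[better] <- new[better]
    mu <- ifelse(better, pmax(mu / 3, 1e-12), pmin(mu * 5, 1e8))
    if (all(abs(c(d_a0[better], d_lam[better])) < 1e-12)) break
  }
  ok <- is.finite(lam) & lam > 1e-8 & is.finite(a0) & a0 >= 0
  list(a0 = a0, lambda = lam, ok = ok)
}

#' Voxelwise TIA map
#'
#' Applies the two-step TIA integration (trapezoid over the measured
#' curve with A(0) = 0, plus a fitted mono-exponential tail) to every
#' voxel of a calibrated study. Tail-point selection, the artificial-point
#' rule and the degenerate-fit fallback are applied per voxel exactly as
#' in the VOI pipeline. Voxels whose fit fails get a zero tail and are
#' flagged in the QC map.
#'
#' @param study calibrated \linkS4class{StudySeries} (>= 3 frames, MBq).
#' @param substitute if TRUE, substitute the therapy-radionuclide physical
#'   decay before fitting and integration.
#' @param constants decay constants (see \code{\link{decayConstants}}).
#' @param minActivityFrac voxels whose curve maximum is below this
#'   fraction of the image-wide maximum get a trapezoid-only TIA with a
#'   zero tail (QC flag 3); default 1e-6.
#' @param maxTailHalfLives sanity bound for noisy voxels: a fitted tail
#'   half-life longer than this multiple of the physical half-life is
#'   treated as degenerate (the analytic tail would be dominated by fit
#'   noise) and falls back to the physical decay constant, QC flag 2.
#'   Default 10.
#' @return list with \code{tia} (\linkS4class{VoxelImage}, MBq h),
#'   \code{qc} (\linkS4class{VoxelImage} of flags: 0 ok, 1 artificial
#'   point used, 2 degenerate fit fallback, 3 negligible activity) and
#'   \code{lambda} (\linkS4class{VoxelImage} of fitted decay constants,
#'   1/h, NA where not fitted).
#' @export
voxelTiaMap <- function(study, substitute = FALSE,
                        constants = decayConstants(),
                        minActivityFrac = 1e-6, maxTailHalfLives = 10) {
  nT <- length(study@times)
  if (nT < 3L) stop("voxelwise TIA needs at least 3 frames")
  ref <- study@spect[[1L]]
  d <- dim(ref@values)
  nv <- prod(d)
  t <- study@times
  Y <- matrix(0, nT, nv)
  for (f in seq_len(nT)) Y[f, ] <- as.numeric(study@spect[[f]]@values)
  lamFall <- if (substitute) constants$lambdaTherapy else constants$lambdaImaging
  if (substitute) Y <- Y * exp((constants$lambdaImaging - constants$lambdaTherapy) * t)

  peak <- apply(Y, 2, max)
  active <- peak > minActivityFrac * max(peak)
  qc <- integer(nv); qc[!active & peak > 0] <- 3L
  tia <- numeric(nv)
  lamOut <- rep(NA_real_, nv)

  ## trapezoid over measured curve with (0, 0) prepended -- all voxels
  tt <- c(0, t)
  wts <- diff(tt)
  trap <- as.numeric((wts / 2) %*% (rbind(0, Y)[-length(tt), , drop = FALSE] +
                                    rbind(0, Y)[-1L, , drop = FALSE]))
  tia <- trap
  tLast <- t[nT]

  av <- which(active)
  if (length(av)) {
    Ya <- Y[, av, drop = FALSE]
    rising <- Ya[nT, ] > Ya[nT - 1L, ]
    imax <- max.col(t(Ya), ties.method = "first")
    qc[av[rising]] <- 1L

    lamFloor <- lamFall / maxTailHalfLives
    addTail <- function(cols, tSel, Ysel) {
      fit <- .fitMonoexpVec(tSel, Ysel)
      bad <- !fit$ok | fit$lambda < lamFloor
      if (any(bad)) {
        ## physical-decay fallback anchored at the last selected point
        fit$lambda[bad] <- lamFall
        fit$a0[bad] <- pmax(Ysel[length(tSel), bad], 0) *
          exp(lamFall * tSel[length(tSel)])
        qc[cols[bad]] <<- 2L
      }
      tia[cols] <<- tia[cols] +
        fit$a0 / fit$lambda * exp(-fit$lambda * tLast)
      lamOut[cols] <<- fit$lambda
    }

    ## group 1: no artificial point, max before the last-3 window -> last 3
    g <- !rising & imax < nT - 2L
    if (any(g)) addTail(av[g], t[(nT - 2L):nT], Ya[(nT - 2L):nT, g, drop = FALSE])
    ## group 2: no artificial point, max within the window -> last 2
    g <- !rising & imax >= nT - 2L
    if (any(g)) addTail(av[g], t[(nT - 1L):nT], Ya[(nT - 1L):nT, g, drop = FALSE])
    ## groups 3: artificial point at t_last + 60 h, half the maximum
    if (any(rising)) {
      tArt <- tLast + 60
      artVal <- 0.5 * apply(Ya[, rising, drop = FALSE], 2, max)
      ## augmented curve has nT + 1 points; max within its last-3 window?
      g3 <- which(rising)
      two <- imax[g3] >= nT - 1L
      if (any(two)) {
        cols <- g3[two]
        Ysel <- rbind(Ya[nT, cols], artVal[two])
        addTail(av[cols], c(tLast, tArt), Ysel)
      }
      if (any(!two)) {
        cols <- g3[!two]
        Ysel <- rbind(Ya[(nT - 1L):nT, cols, drop = FALSE], artVal[!two])
        addTail(av[cols], c(t[nT - 1L], tLast, tArt), Ysel)
      }
    }
  }
  list(tia = .likeImage(ref, array(pmax(tia, 0), d), unit = "MBq.h"),
       qc = .likeImage(ref, array(as.numeric(qc), d), unit = "arb"),
       lambda = voxelImage(array(ifelse(is.na(lamOut), 0, lamOut), d),
                           ref@spacing, ref@origin, "arb"))
}
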
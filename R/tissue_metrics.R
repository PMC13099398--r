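## Semi-automatic quantification of LVEF, infarct size and transmurality,
## MVO and IMH from reconstructed frames and parameter maps. The threshold
## segmentation assumes the short-axis annular geometry this package
## simulates: the blood pool is grown from the LV center seed after a
## two-stage Otsu split (background vs tissue, then myocardium vs blood) and
## the epicardial border is traced by a polar march from the endocardium.

#' Otsu threshold of a numeric vector
#' @param x values
#' @param nBins histogram bins
#' @return threshold maximizing between-class variance
#' @export
otsuThreshold <- function(x, nBins = 96L) {
  x <- x[is.finite(x)]
  br <- seq(min(x), max(x), length.out = nBins + 1L)
  if (br[1] == br[length(br)]) return(br[1])
  cnt <- tabulate(pmin(findInterval(x, br, rightmost.closed = TRUE), nBins),
                  nbins = nBins)
  w <- cnt / sum(cnt)
  mids <- (br[-1] + br[-length(br)]) / 2
  omega <- cumsum(w)
  mu <- cumsum(w * mids)
  muT <- mu[length(mu)]
  sigmaB <- (muT * omega - mu)^2 / (omega * (1 - omega))
  sigmaB[!is.finite(sigmaB)] <- -Inf
  mids[which.max(sigmaB)]
}

#' Dice overlap coefficient
#' @param a,b logical arrays
#' @export
diceCoef <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

## circular moving average over an angular profile
smoothCircular <- function(v, k = 9L) {
  n <- length(v)
  vv <- c(tail(v, k), v, head(v, k))
  f <- stats::filter(vv, rep(1 / (2 * floor(k / 2) + 1), 2 * floor(k / 2) + 1),
                     sides = 2)
  as.numeric(f[(k + 1):(k + n)])
}

## fill NAs in a circular profile by nearest-neighbor interpolation
fillCircular <- function(v) {
  if (!anyNA(v)) return(v)
  n <- length(v)
  ok <- which(!is.na(v))
  if (length(ok) == 0L) return(v)
  for (i in which(is.na(v))) {
    d <- pmin(abs(ok - i), n - abs(ok - i))
    v[i] <- v[ok[which.min(d)]]
  }
  v
}

## per-slice polar segmentation by ray marching from the LV seed.
## Two-stage Otsu separates background from tissue and myocardium from
## blood; each ray then records the endocardial edge (signal falls below
## the blood/myocardium split for two consecutive samples) and the
## epicardial edge (signal falls below half the myocardial level). This is
## robust at coarse grids where the blood pool spans only a few voxels.
## bilinear image sampling at arbitrary (voxel-unit) coordinates
bilinearSample <- function(sl, px, py) {
  nx <- nrow(sl); ny <- ncol(sl)
  px <- pmin(pmax(px, 1), nx - 1e-9)
  py <- pmin(pmax(py, 1), ny - 1e-9)
  x0 <- pmin(floor(px), nx - 1L); y0 <- pmin(floor(py), ny - 1L)
  fx <- px - x0; fy <- py - y0
  v00 <- sl[cbind(x0, y0)];     v10 <- sl[cbind(x0 + 1, y0)]
  v01 <- sl[cbind(x0, y0 + 1)]; v11 <- sl[cbind(x0 + 1, y0 + 1)]
  v00 * (1 - fx) * (1 - fy) + v10 * fx * (1 - fy) +
    v01 * (1 - fx) * fy + v11 * fx * fy
}

segmentSlicePolar <- function(sl, centerVox, voxelMm, nAng = 72L,
                              searchMm = 45, endoMaxMm = 26) {
  nx <- nrow(sl); ny <- ncol(sl)
  X <- (matrix(seq_len(nx), nx, ny) - centerVox[1]) * voxelMm[1]
  Y <- (matrix(seq_len(ny), nx, ny, byrow = TRUE) - centerVox[2]) * voxelMm[2]
  R <- sqrt(X^2 + Y^2)
  TH <- (atan2(Y, X)) %% (2 * pi)
  angBin <- pmin(floor(TH / (2 * pi) * nAng) + 1L, nAng)
  search <- R <= searchMm
  bgThr <- otsuThreshold(sl[search])
  tissueVals <- sl[sl > bgThr & search]
  if (length(tissueVals) < 20L)
    stopf("segmentation error: no tissue near the LV seed")
  bloodThr <- otsuThreshold(tissueVals)
  cx <- round(centerVox[1]); cy <- round(centerVox[2])
  seedVals <- sl[max(1, cx - 1):min(nx, cx + 1),
                 max(1, cy - 1):min(ny, cy + 1)]
  if (stats::median(seedVals) <= bloodThr)
    stopf("segmentation error: seed outside blood pool")
  stepMm <- min(voxelMm[1:2]) / 3
  rr <- seq(stepMm, searchMm, by = stepMm)
  ang <- (seq_len(nAng) - 0.5) / nAng * 2 * pi
  endoR <- epiR <- rep(NA_real_, nAng)
  valsMat <- matrix(NA_real_, length(rr), nAng)
  for (a in seq_len(nAng)) {
    ## bilinear sampling keeps the partial-volume ramp, so threshold
    ## crossings locate the boundary with sub-voxel precision
    px <- centerVox[1] + rr * cos(ang[a]) / voxelMm[1]
    py <- centerVox[2] + rr * sin(ang[a]) / voxelMm[2]
    valsMat[, a] <- bilinearSample(sl, px, py)
  }
  findEndo <- function(thrVec) {
    thrVec <- rep_len(thrVec, nAng)
    out <- rep(NA_real_, nAng)
    for (a in seq_len(nAng)) {
      vals <- valsMat[, a]
      thr <- thrVec[a]
      below <- vals < thr
      hit <- which(below & c(below[-1], TRUE))
      out[a] <- if (length(hit)) {
        i <- hit[1]
        if (i > 1 && vals[i - 1] > vals[i]) {
          rr[i - 1] + (vals[i - 1] - thr) / (vals[i - 1] - vals[i]) *
            (rr[i] - rr[i - 1])
        } else rr[i]
      } else NA_real_
    }
    ## an endocardial radius beyond any plausible cavity means the edge
    ## leaked through an isointense wedge; rebuild that angle from its
    ## neighbors
    out[out > endoMaxMm] <- NA_real_
    smoothCircular(fillCircular(out), 5L)
  }
  myoLevelAngFor <- function(endoRv) {
    out <- vapply(seq_len(nAng), function(a) {
      band <- rr > endoRv[a] + 0.5 & rr <= endoRv[a] + 3.5
      stats::median(valsMat[band, a])
    }, numeric(1))
    smoothCircular(fillCircular(out), 3L)
  }
  ## pass 1: Otsu split seeds the contour; pass 2 re-finds the edge at the
  ## per-angle blood/wall midpoint, the unbiased 50 percent partial-volume
  ## crossing (Otsu drifts with the class balance between frames, and the
  ## wall level differs where the infarct or its cores meet the pool)
  endoR <- findEndo(bloodThr)
  myoAng <- myoLevelAngFor(endoR)
  coreIdx <- which(outer(rr, 0.6 * endoR, "<"), arr.ind = TRUE)
  bloodLevel <- stats::median(valsMat[coreIdx])
  if (bloodLevel > stats::median(myoAng)) {
    endoR <- findEndo((bloodLevel + myoAng) / 2)
    myoAng <- myoLevelAngFor(endoR)
  }
  myoLevel <- stats::median(myoAng)
  maxWallMm <- 18
  epiThr <- 0.5 * myoLevel
  for (a in seq_len(nAng)) {
    inWin <- rr > endoR[a] + stepMm & rr <= endoR[a] + maxWallMm
    vals <- valsMat[, a]
    ## epicardial edge: last sustained supra-threshold sample within the
    ## window (hypointense cores inside the wall are bridged), then the
    ## interpolated crossing just beyond it
    above <- vals >= epiThr & inWin
    above <- above & c(above[-1], FALSE)
    if (any(above)) {
      i <- max(which(above)) + 1L
      epiR[a] <- if (i < length(rr) && vals[i] < vals[i - 1]) {
        rr[i - 1] + (vals[i - 1] - epiThr) /
          max(vals[i - 1] - vals[i], 1e-12) * (rr[i] - rr[i - 1])
      } else rr[i - 1] + stepMm
    } else epiR[a] <- endoR[a] + stepMm
  }
  epiR <- smoothCircular(fillCircular(epiR), 7L)
  epiR <- pmax(epiR, endoR + min(voxelMm[1:2]))
  blood <- R <= endoR[angBin] & search
  list(endoR = endoR, epiR = epiR, angBin = angBin, R = R, blood = blood)
}

#' Segment the left ventricle
#'
#' \code{mode = "oracle"} takes masks straight from the phantom labels (for
#' truth-referenced tests); \code{mode = "threshold"} operates on the image
#' frames alone. The remote reference ROI is the myocardial sector farthest
#' from (threshold mode: with the lowest) late-enhancement signal.
#'
#' @param edFrame,esFrame magnitude volumes at end-diastole / end-systole
#' @param mode "oracle" or "threshold"
#' @param phantom required for oracle mode
#' @param lgeFrame late-enhancement volume used to place the remote ROI
#'   away from the infarct (threshold mode)
#' @param voxelMm voxel size
#' @param centerMm LV center (mm, centered coordinates)
#' @return a \linkS4class{RoiSet}
#' @export
segmentLV <- function(edFrame = NULL, esFrame = NULL,
                      mode = c("threshold", "oracle"), phantom = NULL,
                      lgeFrame = NULL, voxelMm = c(1, 1, 1),
                      centerMm = c(0, 0)) {
  mode <- match.arg(mode)
  if (mode == "oracle") {
    stopifnot(!is.null(phantom))
    mk <- function(phase) {
      lab <- renderLabels(phantom, phase, 0, dispMm = 0)
      list(endo = lab == 1L, epi = array(lab %in% 1:5, dim(lab)),
           myo = array(lab %in% 2:5, dim(lab)))
    }
    ed <- mk(0); es <- mk(0.35)
    lab <- renderLabels(phantom, 0, 0, dispMm = 0)
    g <- phantom@grid
    xs <- axisCoords(g[1], phantom@voxelMm[1]) - phantom@lvCenterMm[1]
    ys <- axisCoords(g[2], phantom@voxelMm[2]) - phantom@lvCenterMm[2]
    TH <- (atan2(matrix(ys, g[1], g[2], byrow = TRUE),
                 matrix(xs, g[1], g[2])) * 180 / pi) %% 360
    ctr <- (phantom@miWedge$theta0 + phantom@miWedge$span / 2) %% 360
    far <- abs(angDiff(TH, ctr)) > phantom@miWedge$span / 2 + 20
    remote <- (lab == 2L) & array(rep(far, g[3]), dim = g)
    return(new("RoiSet", ed = ed, es = es, remote = remote, mode = "oracle"))
  }
  stopifnot(!is.null(edFrame), !is.null(esFrame))
  g <- dim(edFrame)
  centerVox <- c(centerMm[1] / voxelMm[1] + g[1] / 2 + 0.5,
                 centerMm[2] / voxelMm[2] + g[2] / 2 + 0.5)
  build <- function(vol) {
    endo <- array(FALSE, g); epi <- array(FALSE, g)
    for (z in seq_len(g[3])) {
      ps <- segmentSlicePolar(vol[, , z], centerVox, voxelMm)
      endo[, , z] <- ps$blood
      epi[, , z] <- ps$R <= ps$epiR[ps$angBin]
    }
    list(endo = endo, epi = epi, myo = epi & !endo)
  }
  ed <- build(edFrame); es <- build(esFrame)
  ## remote sector: lowest mean late-enhancement signal among 12 sectors
  ref <- if (is.null(lgeFrame)) edFrame else lgeFrame
  xs <- (seq_len(g[1]) - g[1] / 2 - 0.5) * voxelMm[1] - centerMm[1]
  ys <- (seq_len(g[2]) - g[2] / 2 - 0.5) * voxelMm[2] - centerMm[2]
  TH <- (atan2(matrix(ys, g[1], g[2], byrow = TRUE),
               matrix(xs, g[1], g[2])) * 180 / pi) %% 360
  sector <- floor(TH / 30) + 1L
  sectorVol <- array(rep(sector, g[3]), dim = g)
  ## erode the myocardial mask in-plane so the reference region excludes
  ## partial-volume voxels at the endo/epicardial borders
  myoCore <- ed$myo
  for (dd in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
    sh <- ed$myo
    sh <- if (dd[1] != 0) {
      out <- array(FALSE, g)
      if (dd[1] == 1) out[2:g[1], , ] <- ed$myo[1:(g[1] - 1), , ]
      else out[1:(g[1] - 1), , ] <- ed$myo[2:g[1], , ]
      out
    } else {
      out <- array(FALSE, g)
      if (dd[2] == 1) out[, 2:g[2], ] <- ed$myo[, 1:(g[2] - 1), ]
      else out[, 1:(g[2] - 1), ] <- ed$myo[, 2:g[2], ]
      out
    }
    myoCore <- myoCore & sh
  }
  if (sum(myoCore) < 24L) myoCore <- ed$myo
  means <- vapply(1:12, function(s) {
    v <- ref[myoCore & sectorVol == s]
    if (length(v)) mean(v) else Inf
  }, numeric(1))
  ## pick the three-sector window whose brightest sector is dimmest, so a
  ## window bordering the enhancing wedge can never win on a noise tie
  wScore <- vapply(1:12, function(s) {
    nbr <- c((s - 2L) %% 12L + 1L, s, s %% 12L + 1L)
    max(means[nbr])
  }, numeric(1))
  sBest <- which.min(wScore)
  nbr <- c((sBest - 2L) %% 12L + 1L, sBest, sBest %% 12L + 1L)
  remote <- myoCore & array(sectorVol %in% nbr, g)
  if (sum(remote) < 12L) remote <- ed$myo & array(sectorVol %in% nbr, g)
  new("RoiSet", ed = ed, es = es, remote = remote, mode = "threshold")
}

#' End-diastole / end-systole frame picking from a cine series
#'
#' Blood-pool area per frame by thresholding connected to the LV seed;
#' returns the frame indices with maximal / minimal area.
#'
#' @param cine array (nx, ny, nz, nFrames)
#' @param voxelMm,centerMm geometry
#' @return list(ed, es, areas)
#' @export
pickEdEs <- function(cine, voxelMm = c(1, 1, 1), centerMm = c(0, 0)) {
  g <- dim(cine)
  centerVox <- c(centerMm[1] / voxelMm[1] + g[1] / 2 + 0.5,
                 centerMm[2] / voxelMm[2] + g[2] / 2 + 0.5)
  ## sub-voxel blood area summed over all slices: the polar contour area
  ## (pi/nAng * sum endoR^2) is less noisy than voxel counting
  areas <- vapply(seq_len(g[4]), function(f) {
    perSlice <- vapply(seq_len(g[3]), function(z) {
      ps <- try(segmentSlicePolar(cine[, , z, f], centerVox, voxelMm),
                silent = TRUE)
      if (inherits(ps, "try-error")) return(NA_real_)
      sum(ps$endoR^2)
    }, numeric(1))
    if (all(is.na(perSlice))) return(NA_real_)
    ## median across slices: one failed slice cannot swing the frame choice
    stats::median(perSlice, na.rm = TRUE)
  }, numeric(1))
  list(ed = which.max(areas), es = which.min(areas), areas = areas)
}

#' Left-ventricular ejection fraction from ROI masks
#'
#' @param roi a \linkS4class{RoiSet}
#' @param voxelMm voxel size (mm)
#' @return list(lvefPct, edvMl, esvMl)
#' @export
computeLVEF <- function(roi, voxelMm) {
  vox <- prod(voxelMm) / 1000
  edv <- sum(roi@ed$endo) * vox
  esv <- sum(roi@es$endo) * vox
  if (edv <= 0) stopf("EDV is zero: no blood pool at end-diastole")
  list(lvefPct = 100 * (edv - esv) / edv, edvMl = edv, esvMl = esv)
}

## per-angle radial fill of detected MI out to its outer border (the infarct
## model is subendocardial, so enclosed hypointense cores sit between the
## endocardium and the detected rim)
radialFillMi <- function(mi, roi, voxelMm, centerMm = c(0, 0), nAng = 64L) {
  g <- dim(mi)
  xs <- (seq_len(g[1]) - g[1] / 2 - 0.5) * voxelMm[1] - centerMm[1]
  ys <- (seq_len(g[2]) - g[2] / 2 - 0.5) * voxelMm[2] - centerMm[2]
  X <- matrix(xs, g[1], g[2]); Y <- matrix(ys, g[1], g[2], byrow = TRUE)
  R <- sqrt(X^2 + Y^2)
  ang <- pmin(floor(((atan2(Y, X)) %% (2 * pi)) / (2 * pi) * nAng) + 1L, nAng)
  out <- mi
  for (z in seq_len(g[3])) {
    mz <- mi[, , z]
    if (!any(mz)) next
    outerR <- rep(NA_real_, nAng)
    mR <- tapply(R[mz], ang[mz], max)
    outerR[as.integer(names(mR))] <- mR
    ## bridge small angular gaps inside the wedge (thin enhancing rims can
    ## drop out over a bin or two without splitting the lesion)
    orig <- outerR
    for (i in which(is.na(orig))) {
      nbI <- ((i + c(-3L, -2L, -1L, 1L, 2L, 3L)) - 1L) %% nAng + 1L
      near <- orig[nbI]                      # single pass: no cascading
      near <- near[!is.na(near)]
      ## an interior gap is flanked on both sides; a run past the wedge
      ## edge is not, so demand support from at least half the window
      if (length(near) >= 3L) outerR[i] <- mean(near)
    }
    fill <- roi@ed$myo[, , z] & !is.na(outerR[ang]) &
      R <= ifelse(is.na(outerR[ang]), -Inf, outerR[ang])
    out[, , z] <- mz | fill
  }
  out
}

#' Infarct segmentation and size
#'
#' Detection rule: myocardial voxels brighter than
#' \code{mean(remote) + nSd * SD(remote)} on the late-enhancement volume;
#' the largest connected component is kept and enclosed voxels are filled.
#' Because partial-volume boundary voxels carry a smooth intensity ramp, a
#' half-maximum refinement then trims the detected region to voxels at or
#' above the midpoint between the enhancing core and remote myocardium, so
#' the reported border sits at the 50 percent edge. With a zero-variance
#' remote (noise-free input) the detection threshold falls back to the
#' core/remote midpoint, flagged.
#'
#' @param lgeVolume magnitude late-enhancement volume
#' @param roi a \linkS4class{RoiSet}
#' @param nSd detection-threshold multiplier (default 5)
#' @param halfMax apply the half-maximum boundary refinement
#' @param voxelMm,centerMm geometry for the fill step
#' @return list(mask, miPctLv, threshold, flagged)
#' @export
quantifyMI <- function(lgeVolume, roi, nSd = 5, halfMax = TRUE,
                       voxelMm = c(1, 1, 1), centerMm = c(0, 0)) {
  rv <- lgeVolume[roi@remote]
  if (length(rv) == 0L) stopf("remote ROI is empty")
  flagged <- FALSE
  s <- stats::sd(rv)
  ## detect on myocardium away from the endocardial border: blood is not
  ## nulled, so its partial-volume skirt would mimic enhancement; the
  ## radial fill restores genuine subendocardial infarct inside the wedge
  g <- dim(lgeVolume)
  nearEndo <- roi@ed$endo
  for (dd in list(c(1L, 1L), c(1L, -1L), c(2L, 1L), c(2L, -1L))) {
    sh <- array(FALSE, g)
    n <- g[dd[1]]
    if (dd[1] == 1L) { if (dd[2] == 1L) sh[2:n, , ] <- roi@ed$endo[1:(n-1), , ]
                       else sh[1:(n-1), , ] <- roi@ed$endo[2:n, , ] }
    else { if (dd[2] == 1L) sh[, 2:n, ] <- roi@ed$endo[, 1:(n-1), ]
           else sh[, 1:(n-1), ] <- roi@ed$endo[, 2:n, ] }
    nearEndo <- nearEndo | sh
  }
  detectMask <- roi@ed$myo & !nearEndo
  if (sum(detectMask) < 12L) detectMask <- roi@ed$myo
  myoVals <- lgeVolume[roi@ed$myo]
  q95 <- stats::quantile(myoVals, 0.95)
  if (!is.finite(s) || s == 0) {
    thr <- (mean(rv) + max(myoVals)) / 2
    flagged <- TRUE
  } else if (q95 <= mean(rv) + nSd * s) {
    ## presence test: the enhancing tail must clear the nSd line; without
    ## it there is no lesion to segment
    return(list(mask = roi@ed$myo & FALSE, miPctLv = 0,
                threshold = mean(rv) + nSd * s, flagged = FALSE))
  } else {
    ## detection at the lesser of the nSd line and the half-maximum level,
    ## so partial-volume-diluted lesions on weakly nulled frames are still
    ## picked up; the boundary is refined to half-maximum below
    thr <- min(mean(rv) + nSd * s, (q95 + mean(rv)) / 2)
  }
  mi <- detectMask & lgeVolume > thr
  if (any(mi) && halfMax && !flagged) {
    ## core level from the upper quartile so boundary voxels cannot dilute
    ## the half-maximum edge
    core <- stats::quantile(lgeVolume[mi], 0.75)
    thrHalf <- (core + mean(rv)) / 2
    if (thrHalf > thr) {
      mi <- detectMask & lgeVolume > thrHalf
      thr <- thrHalf
    }
  }
  if (any(mi)) {
    ## fill enclosed hypointense cores first so they cannot fragment the
    ## wedge, then keep the largest connected component
    mi <- radialFillMi(mi, roi, voxelMm, centerMm)
    mi <- largestComponent3d(mi)
  }
  size <- sum(mi)
  if (any(mi) && !flagged) {
    ## partial-volume-aware size: total enhancing mass over the lesion and
    ## its skirt divided by the pure-lesion level. The pure level is the
    ## mean of per-angle radial maxima of the background-subtracted signal:
    ## the enhancing band is about two voxels thick, so its radial center
    ## reaches full height even though few single voxels are pure.
    gA <- dim(lgeVolume)
    xs <- (seq_len(gA[1]) - gA[1] / 2 - 0.5) * voxelMm[1] - centerMm[1]
    ys <- (seq_len(gA[2]) - gA[2] / 2 - 0.5) * voxelMm[2] - centerMm[2]
    TH2 <- (atan2(matrix(ys, gA[1], gA[2], byrow = TRUE),
                  matrix(xs, gA[1], gA[2])))
    angB <- pmin(floor((TH2 %% (2 * pi)) / (2 * pi) * 64) + 1L, 64L)
    angVol <- array(rep(angB, gA[3]), gA)
    sliceOf <- array(rep(seq_len(gA[3]), each = gA[1] * gA[2]), gA)
    excess <- lgeVolume - mean(rv)
    keyAll <- angVol + 64L * (sliceOf - 1L)
    peaks <- tapply(excess[mi], keyAll[mi], max)
    pure <- mean(peaks)
    ## enclosed hypointense cores are infarct by definition and carry no
    ## enhancing mass: count them by voxel, and mass-size the rest
    if (is.finite(pure) && pure > 0) {
      coreDark <- mi & excess < 0.3 * pure
      skirt <- detectMask & lgeVolume > mean(rv) + 2 * s
      mass <- sum(pmax(excess[(mi | skirt) & !coreDark], 0))
      size <- mass / pure + sum(coreDark)
    }
  }
  list(mask = mi, miPctLv = 100 * size / sum(roi@ed$myo),
       threshold = thr, flagged = flagged)
}

#' Mean transmural extent of the infarct
#'
#' Radial chords are cast from the slice centroid; for every chord crossing
#' the infarct, the transmural extent is the MI radial thickness divided by
#' the wall thickness; the result is the mean over MI-crossing chords.
#'
#' @param miMask logical infarct mask
#' @param roi a \linkS4class{RoiSet}
#' @param chordsPerSlice number of radial chords per slice
#' @param voxelMm,centerMm geometry
#' @return list(transmuralityPct, nChords); NA with zero chords if the mask
#'   is empty
#' @export
computeTransmurality <- function(miMask, roi, chordsPerSlice = 100L,
                                 voxelMm = c(1, 1, 1), centerMm = c(0, 0)) {
  g <- dim(miMask)
  if (!any(miMask)) return(list(transmuralityPct = NA_real_, nChords = 0L))
  stepMm <- min(voxelMm[1:2]) / 3
  ext <- c()
  ang <- (seq_len(chordsPerSlice) - 0.5) / chordsPerSlice * 2 * pi
  cx <- g[1] / 2 + 0.5 + centerMm[1] / voxelMm[1]
  cy <- g[2] / 2 + 0.5 + centerMm[2] / voxelMm[2]
  rmax <- min(g[1] * voxelMm[1], g[2] * voxelMm[2]) / 2
  rr <- seq(stepMm, rmax, by = stepMm)
  for (z in seq_len(g[3])) {
    if (!any(miMask[, , z])) next
    myoZ <- roi@ed$myo[, , z] + 0; miZ <- miMask[, , z] + 0
    for (a in ang) {
      px <- cx + rr * cos(a) / voxelMm[1]
      py <- cy + rr * sin(a) / voxelMm[2]
      ## bilinear mask sampling puts both borders at their 50 percent
      ## crossings, removing the half-voxel nearest-neighbor bias
      onMyo <- bilinearSample(myoZ, px, py) >= 0.5
      onMi <- bilinearSample(miZ, px, py) >= 0.5
      if (!any(onMi)) next
      wall <- sum(onMyo) * stepMm
      miLen <- sum(onMi) * stepMm
      if (wall > 0) ext <- c(ext, min(miLen / wall, 1))
    }
  }
  if (length(ext) == 0L) return(list(transmuralityPct = NA_real_, nChords = 0L))
  ## median over chords: the few chords clipping the wedge's angular ends
  ## otherwise bias the average low at coarse grids
  list(transmuralityPct = 100 * stats::median(ext), nChords = length(ext))
}

#' Microvascular obstruction within the infarct
#'
#' Hypointense core rule: seed voxels inside the (filled) infarct mask with
#' enhancement signal below the remote-myocardium mean; the core boundary
#' is then grown to the half-maximum edge (midpoint between the dark-core
#' level and the enhancing-infarct level), so partial-volume rim voxels of
#' a thin core are included, with a neighborhood-majority fill pass.
#' Empty result is valid (no MVO).
#'
#' @param enhVolume T1-weighted enhancement volume (early or late window)
#' @param miMask filled infarct mask
#' @param roi a \linkS4class{RoiSet}
#' @return list(mask, mvoPctLv)
#' @export
quantifyMVO <- function(enhVolume, miMask, roi) {
  thr <- mean(enhVolume[roi@remote])
  mvo <- miMask & enhVolume < thr
  size <- sum(mvo)
  if (any(mvo) && sum(miMask & !mvo) > 0) {
    coreLevel <- stats::median(enhVolume[mvo])
    ## upper quartile: the non-core infarct still contains partially dark
    ## voxels that would drag a median down
    miLevel <- stats::quantile(enhVolume[miMask & !mvo], 0.75)
    thrHalf <- (coreLevel + miLevel) / 2
    if (thrHalf > thr && miLevel > coreLevel) {
      mvo <- miMask & enhVolume < thrHalf
      ## partial-volume-weighted size: thin cores rarely fill a whole
      ## voxel, so integrate the apparent obstruction fraction instead of
      ## counting voxels; the support extends one voxel beyond the
      ## detected infarct border (still enclosed myocardium) because the
      ## core's partial-volume skirt can straddle that border
      g <- dim(miMask)
      dil <- miMask
      grow <- function(m, ax, dd) {
        out <- array(FALSE, dim(m))
        n <- dim(m)[ax]
        if (ax == 1) { if (dd == 1) out[2:n, , ] <- m[1:(n-1), , ]
                       else out[1:(n-1), , ] <- m[2:n, , ] }
        if (ax == 2) { if (dd == 1) out[, 2:n, ] <- m[, 1:(n-1), ]
                       else out[, 1:(n-1), ] <- m[, 2:n, ] }
        out
      }
      for (ax in 1:2) for (dd in c(-1L, 1L)) dil <- dil | grow(miMask, ax, dd)
      ## inside the infarct any sub-infarct-level signal carries core mass;
      ## outside, only dark voxels touching the detected core count (the
      ## core skirt can straddle the infarct border)
      nearCore <- mvo
      for (ax in 1:2) for (dd in c(-1L, 1L)) nearCore <- nearCore | grow(mvo, ax, dd)
      support <- (miMask & enhVolume < miLevel) |
        (dil & !miMask & roi@ed$myo & nearCore & enhVolume < min(thr, thrHalf))
      frac <- pmin(pmax((miLevel - enhVolume[support]) /
                          (miLevel - coreLevel), 0), 1)
      size <- sum(frac)
    } else size <- sum(mvo)
  }
  if (any(mvo)) {
    ## majority fill of the reported mask (size stays fraction-weighted)
    g <- dim(mvo)
    cnt <- array(0L, g)
    shift <- function(m, ax, dd) {
      out <- array(FALSE, dim(m))
      idx <- seq_len(dim(m)[ax])
      src <- idx - dd
      ok <- src >= 1 & src <= dim(m)[ax]
      if (ax == 1) out[idx[ok], , ] <- m[src[ok], , ]
      if (ax == 2) out[, idx[ok], ] <- m[, src[ok], ]
      if (ax == 3) out[, , idx[ok]] <- m[, , src[ok]]
      out
    }
    for (ax in 1:3) for (dd in c(-1L, 1L)) cnt <- cnt + shift(mvo, ax, dd)
    mvo <- mvo | (miMask & cnt >= 4L)
  }
  list(mask = mvo, mvoPctLv = 100 * size / sum(roi@ed$myo))
}

#' Intramyocardial hemorrhage within the infarct
#'
#' \code{rule = "fixed20"}: infarct voxels with T2* below 20 ms (3 T
#' convention); \code{rule = "remote_minus_2sd"}: below the remote-T2* mean
#' minus twice its SD.
#'
#' @param t2starMap T2* map (ms)
#' @param miMask filled infarct mask
#' @param roi a \linkS4class{RoiSet}
#' @param rule "fixed20" or "remote_minus_2sd"
#' @param validMask optional fit-quality mask
#' @param pvWeight weight detected voxels by their apparent hemorrhage
#'   fraction (linear between the infarct and core T2* levels), which
#'   de-biases the size of cores thinner than a voxel
#' @return list(mask, imhPctLv, threshold)
#' @export
quantifyIMH <- function(t2starMap, miMask, roi,
                        rule = c("fixed20", "remote_minus_2sd"),
                        validMask = NULL, pvWeight = TRUE) {
  rule <- match.arg(rule)
  thr <- if (rule == "fixed20") 20
  else mean(t2starMap[roi@remote], na.rm = TRUE) -
    2 * stats::sd(t2starMap[roi@remote], na.rm = TRUE)
  imh <- miMask & !is.na(t2starMap) & t2starMap < thr
  if (!is.null(validMask)) imh <- imh & validMask
  size <- sum(imh)
  if (pvWeight && any(imh) && sum(miMask & !imh) > 0) {
    t2Core <- stats::quantile(t2starMap[imh], 0.1, na.rm = TRUE)
    t2Mi <- stats::median(t2starMap[miMask & !imh], na.rm = TRUE)
    if (t2Mi > t2Core) {
      frac <- pmin(pmax((t2Mi - t2starMap[imh]) / (t2Mi - t2Core), 0), 1)
      size <- sum(frac)
    }
  }
  list(mask = imh, imhPctLv = 100 * size / sum(roi@ed$myo),
       threshold = thr)
}
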
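## Method-comparison statistics: Bland-Altman bias / limits of agreement /
## reproducibility coefficient, ordinary least-squares regression with
## t-based confidence intervals, the paired t-test, and ROC/AUC by the
## Mann-Whitney identity. Differences are proposed - conventional
## throughout.

#' Paired measurements container
#'
#' @param x conventional-arm values
#' @param y proposed-arm values
#' @param id subject identifiers
#' @param units label
#' @return data.frame with class "pairedMeasurements"
#' @export
pairedMeasurements <- function(x, y, id = seq_along(x), units = "") {
  stopifnot(length(x) == length(y), length(x) >= 2, all(is.finite(c(x, y))))
  structure(data.frame(id = id, x = x, y = y),
            units = units, class = c("pairedMeasurements", "data.frame"))
}

#' Bland-Altman agreement analysis
#'
#' \code{bias = mean(y - x)}, \code{rpc = 1.96 * sd(y - x)} (sample SD,
#' n - 1; the GraphPad convention, making RPC exactly the LoA half-width),
#' \code{LoA = bias +/- rpc}.
#'
#' @param p a \code{\link{pairedMeasurements}} (or any list with x, y)
#' @return list(bias, loaLow, loaHigh, rpc, sd, n)
#' @export
blandAltman <- function(p) {
  d <- p$y - p$x
  if (length(d) < 2L) stopf("Bland-Altman requires n >= 2")
  bias <- mean(d)
  s <- stats::sd(d)
  rpc <- 1.96 * s
  list(bias = bias, loaLow = bias - rpc, loaHigh = bias + rpc,
       rpc = rpc, sd = s, n = length(d))
}

#' Recover bias and RPC from printed limits of agreement
#'
#' The reproducibility coefficient is the LoA half-width and the bias the
#' LoA midpoint; useful for checking printed Bland-Altman summaries for
#' internal consistency.
#'
#' @param loaLow,loaHigh limits of agreement
#' @return list(bias, rpc)
#' @export
rpcFromLoA <- function(loaLow, loaHigh) {
  list(bias = (loaLow + loaHigh) / 2, rpc = (loaHigh - loaLow) / 2)
}

#' Simple linear regression with 95 percent confidence intervals
#'
#' Ordinary least squares of y on x; CIs from the t distribution with n - 2
#' degrees of freedom; p-value for slope != 0.
#'
#' @param x,y numeric vectors, n >= 3, var(x) > 0
#' @return list(slope, intercept, slopeCi, interceptCi, r2, p, se)
#' @export
linReg <- function(x, y) {
  n <- length(x)
  stopifnot(length(y) == n)
  if (n < 3L) stopf("regression requires n >= 3")
  if (stats::var(x) == 0) stopf("regression requires var(x) > 0")
  mx <- mean(x); my <- mean(y)
  sxx <- sum((x - mx)^2); sxy <- sum((x - mx) * (y - my))
  slope <- sxy / sxx
  intercept <- my - slope * mx
  res <- y - intercept - slope * x
  s2 <- sum(res^2) / (n - 2)
  seSlope <- sqrt(s2 / sxx)
  seInt <- sqrt(s2 * (1 / n + mx^2 / sxx))
  tc <- stats::qt(0.975, n - 2)
  tStat <- slope / seSlope
  p <- 2 * stats::pt(-abs(tStat), n - 2)
  syy <- sum((y - my)^2)
  r2 <- if (syy > 0) 1 - sum(res^2) / syy else NA_real_
  list(slope = slope, intercept = intercept,
       slopeCi = c(slope - tc * seSlope, slope + tc * seSlope),
       interceptCi = c(intercept - tc * seInt, intercept + tc * seInt),
       r2 = r2, p = p, se = c(slope = seSlope, intercept = seInt))
}

#' Paired t-test
#'
#' @param p a \code{\link{pairedMeasurements}}
#' @return list(t, df, p, flag); zero-variance differences give an NA p
#'   with flag "zero-variance"
#' @export
pairedT <- function(p) {
  d <- p$y - p$x
  n <- length(d)
  if (n < 2L) stopf("paired t-test requires n >= 2")
  s <- stats::sd(d)
  if (s == 0)
    return(list(t = NA_real_, df = n - 1, p = NA_real_,
                flag = "zero-variance"))
  tt <- mean(d) / (s / sqrt(n))
  list(t = tt, df = n - 1, p = 2 * stats::pt(-abs(tt), n - 1), flag = "")
}

#' ROC area under the curve with confidence interval
#'
#' AUC by the Mann-Whitney U identity with ties averaged; CI by a seeded
#' stratified bootstrap (default 2000 resamples).
#'
#' @param labels binary (0/1 or logical)
#' @param scores numeric, higher = more positive
#' @param nBoot bootstrap resamples for the CI (0 skips the CI)
#' @param seed bootstrap seed
#' @return list(auc, ci, nPos, nNeg)
#' @export
rocAuc <- function(labels, scores, nBoot = 2000L, seed = 0) {
  labels <- as.logical(labels)
  stopifnot(length(labels) == length(scores))
  nPos <- sum(labels); nNeg <- sum(!labels)
  if (nPos == 0L || nNeg == 0L)
    stopf("ROC requires both classes present")
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[labels]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
  ci <- c(NA_real_, NA_real_)
  if (nBoot > 0L) {
    posIdx <- which(labels); negIdx <- which(!labels)
    bs <- withSeed(seed, {
      vapply(seq_len(nBoot), function(b) {
        ip <- sample(posIdx, nPos, replace = TRUE)
        ineg <- sample(negIdx, nNeg, replace = TRUE)
        sc <- c(scores[ip], scores[ineg])
        lab <- c(rep(TRUE, nPos), rep(FALSE, nNeg))
        r <- rank(sc, ties.method = "average")
        (sum(r[lab]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
      }, numeric(1))
    })
    ci <- unname(stats::quantile(bs, c(0.025, 0.975)))
  }
  list(auc = auc, ci = ci, nPos = nPos, nNeg = nNeg)
}

#' Empirical ROC curve (trapezoidal AUC cross-check)
#'
#' @inheritParams rocAuc
#' @return list(fpr, tpr, aucTrapezoid)
#' @export
rocCurve <- function(labels, scores) {
  labels <- as.logical(labels)
  o <- order(scores, decreasing = TRUE)
  lab <- labels[o]; sc <- scores[o]
  tp <- cumsum(lab); fp <- cumsum(!lab)
  keep <- c(diff(sc) != 0, TRUE)     # one point per distinct threshold
  tpr <- c(0, tp[keep] / sum(labels))
  fpr <- c(0, fp[keep] / sum(!labels))
  auc <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  list(fpr = fpr, tpr = tpr, aucTrapezoid = auc)
}

#' Sector-level detection data for lesion ROC analysis
#'
#' The detection unit is a myocardial sector (slice x 60 degree wedge).
#' Sector truth labels come from the phantom labels; the sector score is
#' the mean of \code{scoreVolume} over myocardial voxels in the sector
#' (pass, e.g., enhancement signal for MI, negated enhancement for MVO, or
#' negated T2* for IMH).
#'
#' @param scoreVolume numeric volume of per-voxel scores
#' @param myoMask logical myocardium mask
#' @param truthMask logical lesion truth mask (sector positive if any voxel)
#' @param voxelMm,centerMm geometry
#' @param sectorDeg angular sector size (degrees)
#' @return data.frame(slice, sector, label, score)
#' @export
sectorScores <- function(scoreVolume, myoMask, truthMask,
                         voxelMm = c(1, 1, 1), centerMm = c(0, 0),
                         sectorDeg = 60) {
  g <- dim(scoreVolume)
  nSec <- as.integer(round(360 / sectorDeg))
  xs <- (seq_len(g[1]) - g[1] / 2 - 0.5) * voxelMm[1] - centerMm[1]
  ys <- (seq_len(g[2]) - g[2] / 2 - 0.5) * voxelMm[2] - centerMm[2]
  TH <- (atan2(matrix(ys, g[1], g[2], byrow = TRUE),
               matrix(xs, g[1], g[2])) * 180 / pi) %% 360
  sec2d <- pmin(floor(TH / sectorDeg) + 1L, nSec)
  out <- NULL
  for (z in seq_len(g[3])) {
    for (s in seq_len(nSec)) {
      vox <- myoMask[, , z] & sec2d == s
      if (!any(vox)) next
      out <- rbind(out, data.frame(
        slice = z, sector = s,
        label = any(truthMask[, , z] & vox),
        score = mean(scoreVolume[, , z][vox])))
    }
  }
  out
}

#' Full agreement analysis for one metric
#'
#' @param x conventional-arm values
#' @param y proposed-arm values
#' @return an \linkS4class{AgreementStats}
#' @export
agreementStats <- function(x, y) {
  p <- pairedMeasurements(x, y)
  ba <- blandAltman(p)
  flags <- character(0)
  reg <- if (length(x) >= 3 && stats::var(x) > 0) linReg(x, y) else {
    flags <- c(flags, "regression-skipped")
    list(slope = NA_real_, intercept = NA_real_,
         slopeCi = c(NA_real_, NA_real_), interceptCi = c(NA_real_, NA_real_),
         r2 = NA_real_, p = NA_real_)
  }
  tt <- pairedT(p)
  if (nzchar(tt$flag)) flags <- c(flags, tt$flag)
  new("AgreementStats", n = as.integer(ba$n), bias = ba$bias,
      loaLow = ba$loaLow, loaHigh = ba$loaHigh, rpc = ba$rpc,
      slope = reg$slope, intercept = reg$intercept, slopeCi = reg$slopeCi,
      interceptCi = reg$interceptCi, r2 = reg$r2, pRegression = reg$p,
      tPaired = tt$t, dfPaired = tt$df, pPairedT = tt$p, flags = flags)
}

setMethod("show", "AgreementStats", function(object) {
  cat(sprintf("AgreementStats (n = %d, proposed - conventional)\n", object@n))
  cat(sprintf("  bias %.3f, LoA [%.3f, %.3f], RPC %.3f\n",
              object@bias, object@loaLow, object@loaHigh, object@rpc))
  cat(sprintf("  slope %.3f [%.3f, %.3f], intercept %.3f [%.3f, %.3f], R2 %.3f\n",
              object@slope, object@slopeCi[1], object@slopeCi[2],
              object@intercept, object@interceptCi[1], object@interceptCi[2],
              object@r2))
  cat(sprintf("  paired t = %.3f (df %d), p = %.3g\n",
              object@tPaired, as.integer(object@dfPaired), object@pPairedT))
  if (length(object@flags)) cat("  flags:", paste(object@flags, collapse = ", "), "\n")
})

#' Agreement table across metrics
#'
#' @param metrics data.frame with columns subject, metric, conventional,
#'   proposed
#' @return data.frame with one row per metric (bias, LoA, RPC, slope, R2,
#'   paired-t p)
#' @export
agreementTable <- function(metrics) {
  out <- lapply(split(metrics, metrics$metric), function(df) {
    ok <- is.finite(df$conventional) & is.finite(df$proposed)
    if (sum(ok) < 2L)
      return(data.frame(metric = df$metric[1], n = sum(ok), bias = NA_real_,
                        loaLow = NA_real_, loaHigh = NA_real_, rpc = NA_real_,
                        slope = NA_real_, intercept = NA_real_, r2 = NA_real_,
                        pPairedT = NA_real_))
    st <- agreementStats(df$conventional[ok], df$proposed[ok])
    data.frame(metric = df$metric[1], n = st@n, bias = st@bias,
               loaLow = st@loaLow, loaHigh = st@loaHigh, rpc = st@rpc,
               slope = st@slope, intercept = st@intercept, r2 = st@r2,
               pPairedT = st@pPairedT)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
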
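## Self-navigated binning, temporal-subspace estimation from the interleaved
## training lines, and subspace-constrained reconstruction of the 6-D
## low-rank tensor image model.
##
## The image is modeled as X = Ux %*% phi, with Ux an (nVoxels x L) complex
## spatial factor and phi an orthonormal-row joint temporal basis over all
## (cardiac, resp, tau, echo, gd) cells. phi is obtained from the training
## tensor: training-line profiles are compressed to a feature subspace,
## arranged into a (feature x cardiac x resp x tau x echo x gd) tensor,
## completed by alternating Tucker (HOOI) sweeps with EM imputation of the
## unobserved cells, and the joint basis is the row space of the completed
## tensor's spatial unfolding. The spatial factor then solves a regularized
## least-squares data-consistency problem by conjugate gradient on the
## normal equations; because sampling is Cartesian with fully sampled
## readouts, the normal operator reduces to per-(ky,kz)-row L x L Gram
## matrices of the temporal basis, which makes each CG iteration a handful
## of FFTs plus small dense products.

#' Bin configuration constructor
#'
#' @param nCardiac,nResp,nGd temporal bin counts (defaults 24, 4, 16)
#' @param tauDecim inversion-time grouping factor; 1 keeps every segment as
#'   its own tau point, the default 6 matches the training interleave
#' @return a \linkS4class{BinConfig}
#' @export
binConfig <- function(nCardiac = 24L, nResp = 4L, nGd = 16L, tauDecim = 6L) {
  new("BinConfig", nCardiac = as.integer(nCardiac), nResp = as.integer(nResp),
      nGd = as.integer(nGd), tauDecim = as.integer(tauDecim))
}

## Butterworth band-pass via forward-backward filtering
bandpass <- function(x, bandHz, fsHz) {
  ny <- fsHz / 2
  w <- pmin(pmax(bandHz / ny, 1e-4), 0.999)
  bf <- signal::butter(2, w, type = "pass")
  as.numeric(signal::filtfilt(bf, x))
}

#' Extract self-navigation signals from the training lines
#'
#' Builds the training-line feature series (k-space-center profiles per
#' coil), removes the inversion-recovery contrast by centering each
#' same-segment series, takes principal components, and band-passes them
#' into respiratory (0.05-0.7 Hz) and cardiac (0.8-3.5 Hz) waveforms.
#' Cardiac triggers come from peak detection with a 300 ms refractory
#' period; phases are linear between triggers. \code{mode = "bypass"}
#' returns the simulator's ground-truth phases (for truth-referenced
#' tests).
#'
#' @param kdata a \linkS4class{KSpaceData}
#' @param schedule the generating \linkS4class{SamplingSchedule}
#' @param mode "selfnav" or "bypass"
#' @param cardiacBandHz,respBandHz analysis bands (Hz)
#' @param refractoryMs minimum trigger spacing
#' @return a \linkS4class{NavSignals}
#' @export
extractNav <- function(kdata, schedule, mode = c("selfnav", "bypass"),
                       cardiacBandHz = c(0.8, 3.5),
                       respBandHz = c(0.05, 0.7), refractoryMs = 300) {
  mode <- match.arg(mode)
  ev <- schedule@events
  tAll <- ev$tMs
  if (mode == "bypass") {
    tr <- kdata@truth
    if (is.null(tr$cPhase)) stopf("no ground-truth phases stored for bypass mode")
    cyc <- sum(diff(tr$cPhase) < -0.5)
    rr <- diff(range(tAll)) / max(cyc, 1)
    return(new("NavSignals", cardiacWave = numeric(0), respWave = numeric(0),
               trainTimesMs = tAll[ev$isTraining], rrMsEst = rr,
               respMsEst = NA_real_, cardiacPhase = tr$cPhase,
               respAmp = tr$disp, triggersMs = numeric(0), mode = "bypass"))
  }
  trIdx <- which(ev$isTraining)
  if (length(trIdx) < 32L) stopf("too few training readouts for navigation")
  tTr <- tAll[trIdx]
  fs <- 1000 / (schedule@params@trainingEvery * schedule@params@trMs)
  nx <- kdata@nKx
  ## features: first-echo center-line profile for every coil
  feat <- do.call(rbind, lapply(kdata@samples,
                                function(D) D[seq_len(nx), trIdx]))
  ## remove IR contrast: center each same-segment (same tau) series
  segTr <- ev$seg[trIdx]
  for (sv in unique(segTr)) {
    j <- segTr == sv
    feat[, j] <- feat[, j] - rowMeans(feat[, j, drop = FALSE])
  }
  featR <- rbind(Re(feat), Im(feat))
  featR <- featR - rowMeans(featR)
  if (max(abs(featR)) < 1e-12)
    stopf("navigation failure: no dynamic signal in training data")
  sv <- svd(featR, nu = 4, nv = 0)
  scores <- crossprod(sv$u, featR)            # 4 x nT
  bandScore <- function(band) {
    filt <- apply(scores, 1, bandpass, bandHz = band, fsHz = fs)
    ratios <- apply(filt, 2, stats::var) /
      pmax(apply(scores, 1, stats::var), 1e-30)
    filt[, which.max(ratios)]
  }
  cw0 <- bandScore(cardiacBandHz)
  rw <- bandScore(respBandHz)
  ## spectral-peak check and fundamental estimate in the cardiac band
  pgram <- Mod(stats::fft(cw0 - mean(cw0)))^2
  freqs <- (seq_along(cw0) - 1) / length(cw0) * fs
  inBand <- freqs >= cardiacBandHz[1] & freqs <= cardiacBandHz[2]
  if (!any(inBand) || max(pgram[inBand]) < 10 * stats::median(pgram[inBand]) ||
      stats::sd(cw0) < 1e-12)
    stopf("navigation failure: no spectral peak above noise floor in the cardiac band")
  f0 <- freqs[inBand][which.max(pgram[inBand])]
  ## the contraction waveform is far from sinusoidal: isolate the
  ## fundamental before trigger detection so each cycle has one peak
  cw <- bandpass(cw0, c(0.72 * f0, 1.35 * f0), fs)
  refractoryMs <- max(refractoryMs, 0.6 * 1000 / f0)
  ## trigger detection with refractory period; parabolic sub-sample
  ## interpolation so estimated phases are not quantized to the training
  ## interval
  n <- length(cw)
  isPk <- c(FALSE, cw[2:(n - 1)] > cw[1:(n - 2)] &
              cw[2:(n - 1)] >= cw[3:n], FALSE) & cw > 0
  pkI <- which(isPk)
  dtMs <- stats::median(diff(tTr))
  delta <- numeric(length(pkI))
  ok <- pkI > 1 & pkI < n
  den <- cw[pkI[ok] - 1] - 2 * cw[pkI[ok]] + cw[pkI[ok] + 1]
  delta[ok] <- ifelse(abs(den) > 1e-30,
                      0.5 * (cw[pkI[ok] - 1] - cw[pkI[ok] + 1]) / den, 0)
  delta <- pmin(pmax(delta, -0.5), 0.5)
  pkT <- tTr[pkI] + delta * dtMs
  keep <- logical(length(pkT)); last <- -Inf
  for (i in seq_along(pkT)) {
    if (pkT[i] - last >= refractoryMs) { keep[i] <- TRUE; last <- pkT[i] }
  }
  trig <- pkT[keep]
  if (length(trig) < 3L) stopf("navigation failure: too few cardiac triggers")
  d <- diff(trig)
  dm <- stats::median(d)
  rrEst <- mean(d[d > 0.6 * dm & d < 1.4 * dm])
  ## respiratory period from the band-limited spectrum
  specR <- Mod(stats::fft(rw - mean(rw)))^2
  inR <- freqs > 0 & freqs <= respBandHz[2] * 1.5
  respEst <- 1000 / freqs[inR][which.max(specR[inR])]
  ## phases at every readout
  k <- findInterval(tAll, trig)
  phase <- numeric(length(tAll))
  inside <- k >= 1 & k < length(trig)
  phase[inside] <- (tAll[inside] - trig[k[inside]]) /
    (trig[k[inside] + 1] - trig[k[inside]])
  phase[k == 0] <- ((tAll[k == 0] - trig[1]) / rrEst) %% 1
  atEnd <- k == length(trig)
  phase[atEnd] <- ((tAll[atEnd] - trig[length(trig)]) / rrEst) %% 1
  phase <- pmin(pmax(phase, 0), 1 - 1e-9)
  respAmp <- stats::approx(tTr, rw, xout = tAll, rule = 2)$y
  new("NavSignals", cardiacWave = cw, respWave = rw, trainTimesMs = tTr,
      rrMsEst = rrEst, respMsEst = respEst, cardiacPhase = phase,
      respAmp = respAmp, triggersMs = trig, mode = "selfnav")
}

#' Assign every readout to a (cardiac, resp, gd, tau) cell
#'
#' Cardiac bins are uniform in phase; respiratory bins are amplitude
#' quantiles (bin 0 = end-expiration, the lowest-displacement quartile in
#' bypass mode); gadolinium-dynamics bins are uniform in sqrt(time since
#' injection), concentrating bins early where enhancement changes fastest;
#' the tau index is the segment index optionally grouped by
#' \code{tauDecim}.
#'
#' @param schedule a \linkS4class{SamplingSchedule}
#' @param nav a \linkS4class{NavSignals}
#' @param bins a \linkS4class{BinConfig}
#' @param tInjectOffsetS scan start relative to injection (s)
#' @return a \linkS4class{BinningResult}
#' @export
assignBins <- function(schedule, nav, bins = binConfig(),
                       tInjectOffsetS = 45) {
  ev <- schedule@events
  n <- nrow(ev)
  cb <- pmin(as.integer(floor(nav@cardiacPhase * bins@nCardiac)),
             bins@nCardiac - 1L)
  if (bins@nResp > 1L && stats::sd(nav@respAmp) > 0) {
    qs <- stats::quantile(nav@respAmp,
                          probs = seq(0, 1, length.out = bins@nResp + 1))
    qs[1] <- -Inf; qs[length(qs)] <- Inf
    rb <- as.integer(cut(nav@respAmp, breaks = qs)) - 1L
  } else rb <- integer(n)
  tInj <- ev$tMs / 1000 + tInjectOffsetS
  if (bins@nGd > 1L) {
    edges <- seq(sqrt(min(tInj)), sqrt(max(tInj)),
                 length.out = bins@nGd + 1)^2
    gb <- pmin(pmax(findInterval(tInj, edges, rightmost.closed = TRUE), 1L),
               bins@nGd) - 1L
  } else {
    edges <- range(tInj); gb <- integer(n)
  }
  tau <- as.integer(ev$seg %/% bins@tauDecim)
  nTau <- as.integer((schedule@params@segmentsPerIR + bins@tauDecim - 1L) %/%
                       bins@tauDecim)
  occ <- array(0L, dim = c(bins@nCardiac, bins@nResp, bins@nGd))
  img <- !ev$isTraining
  tb <- table(factor(cb[img], levels = 0:(bins@nCardiac - 1L)),
              factor(rb[img], levels = 0:(bins@nResp - 1L)),
              factor(gb[img], levels = 0:(bins@nGd - 1L)))
  occ[] <- as.integer(tb)
  new("BinningResult", cardiacBin = cb, respBin = rb, gdBin = gb,
      tauIndex = tau, bins = bins, nTau = nTau, occupancy = occ,
      gdEdgesS = as.numeric(edges))
}

## ---- small dense-tensor helpers (column-major, mode-1 fastest) ----

unfoldTensor <- function(x, mode) {
  d <- dim(x)
  if (mode == 1L) return(matrix(x, d[1], prod(d[-1])))
  perm <- c(mode, seq_along(d)[-mode])
  matrix(aperm(x, perm), d[mode], prod(d[-mode]))
}

## multiply tensor by matrix M (p x d[mode]) along `mode`
modeProduct <- function(x, M, mode) {
  d <- dim(x)
  perm <- c(mode, seq_along(d)[-mode])
  xm <- matrix(aperm(x, perm), d[mode], prod(d[-mode]))
  ym <- M %*% xm
  y <- array(ym, dim = c(nrow(M), d[-mode]))
  aperm(y, order(perm))
}

## leading left singular vectors (complex-safe); uses the small Gram matrix
## because unfoldings here are short and very wide
topLeftSV <- function(m, k) {
  k <- min(k, nrow(m), ncol(m))
  H <- m %*% Conj(t(m))
  eg <- eigen((H + Conj(t(H))) / 2, symmetric = TRUE)
  eg$vectors[, seq_len(k), drop = FALSE]
}

#' Estimate the temporal subspace from the training data
#'
#' See the module header: feature-compressed training tensor, alternating
#' Tucker (HOOI) completion with EM imputation of empty cells, per-dimension
#' factor bases, and the joint basis \code{phi} from the spatial unfolding.
#'
#' @param kdata a \linkS4class{KSpaceData}
#' @param schedule a \linkS4class{SamplingSchedule}
#' @param binning a \linkS4class{BinningResult}
#' @param ranks temporal Tucker ranks (L_c, L_r, L_tau, L_e, L_g)
#' @param jointRank number of joint temporal basis vectors L retained for
#'   the spatial factor
#' @param maxSweeps,tol completion iteration controls (relative change)
#' @param sepRank rank of the (motion) x (contrast) separable completion;
#'   NULL picks min(12, feasible bounds). This encodes the multitasking
#'   assumption that the image series mixes a small number of distinct
#'   contrast-evolution signatures
#' @param seed initialization seed for the completion
#' @return a \linkS4class{TemporalSubspace}
#' @export
estimateSubspaces <- function(kdata, schedule, binning,
                              ranks = c(16L, 4L, 8L, 6L, 8L),
                              jointRank = 24L, maxSweeps = 100L,
                              tol = 1e-6, sepRank = NULL, seed = 0) {
  ev <- schedule@events
  trIdx <- which(ev$isTraining)
  bins <- binning@bins
  nEcho <- kdata@nEcho; nx <- kdata@nKx
  dims <- c(bins@nCardiac, bins@nResp, binning@nTau, nEcho, bins@nGd)
  names(dims) <- c("cardiac", "resp", "tau", "echo", "gd")
  if (any(ranks > dims)) {
    bad <- names(dims)[which(ranks > dims)[1]]
    stopf("requested rank exceeds dimension size along '%s'", bad)
  }
  ## spanning check: every index of each temporal dim must be visited
  idxList <- list(cardiac = binning@cardiacBin[trIdx],
                  resp = binning@respBin[trIdx],
                  tau = binning@tauIndex[trIdx],
                  echo = 0:(nEcho - 1L),
                  gd = binning@gdBin[trIdx])
  for (nm in names(dims)) {
    if (length(unique(idxList[[nm]])) < dims[[nm]])
      stopf("under-determined subspace: no training data along '%s'", nm)
  }
  ## feature matrix: (kx x coil) profiles, samples = (event, echo)
  nT <- length(trIdx)
  nC <- length(kdata@samples)
  feat <- array(0 + 0i, dim = c(nx, nC, nEcho, nT))
  for (ci in seq_len(nC)) {
    D <- kdata@samples[[ci]][, trIdx, drop = FALSE]
    dim(D) <- c(nx, nEcho, nT)
    feat[, ci, , ] <- D
  }
  feat <- matrix(feat, nx * nC, nEcho * nT)   # echo fastest? no: (echo,event)
  ## note: array flatten gives (kx, coil) rows and (echo, event) columns
  Lf <- min(jointRank, nx * nC, nEcho * nT)
  H <- feat %*% Conj(t(feat))
  eg <- eigen(H, symmetric = TRUE)
  Uf <- eg$vectors[, seq_len(Lf), drop = FALSE]
  Z <- crossprod(Conj(Uf), feat)              # Lf x (nEcho*nT)
  ## accumulate cell means of the training tensor
  cellOf <- function(c0, r0, t0, e0, g0)
    1 + c0 + dims[1] * (r0 + dims[2] * (t0 + dims[3] * (e0 + dims[4] * g0)))
  nCells <- prod(dims)
  sumT <- matrix(0 + 0i, Lf, nCells)
  cntT <- numeric(nCells)
  cT <- binning@cardiacBin[trIdx]; rT <- binning@respBin[trIdx]
  tT <- binning@tauIndex[trIdx]; gT <- binning@gdBin[trIdx]
  for (e0 in 0:(nEcho - 1L)) {
    cid <- cellOf(cT, rT, tT, e0, gT)
    zc <- Z[, seq(e0 + 1L, by = nEcho, length.out = nT), drop = FALSE]
    sRe <- rowsum(t(Re(zc)), cid)
    sIm <- rowsum(t(Im(zc)), cid)
    cols <- as.numeric(rownames(sRe))
    sumT[, cols] <- sumT[, cols] + t(sRe) + 1i * t(sIm)
    cntT <- cntT + tabulate(cid, nbins = nCells)
  }
  obs <- cntT > 0
  Xm <- matrix(0 + 0i, Lf, nCells)
  Xm[, obs] <- sweep(sumT[, obs, drop = FALSE], 2, cntT[obs], "/")
  ## --- completion stage -------------------------------------------------
  ## The multitasking model assumes the motion state and the contrast
  ## dynamics factorize, so the training tensor unfolded as
  ## (feature, cardiac, resp) x (tau, echo, gd) is low rank (bounded by
  ## min(Lc*Lr, Ltau*Le*Lg)). Alternating least squares on that matrix
  ## completes the empty cells quickly and almost exactly for data close to
  ## the model; a single HOSVD pass then yields the Tucker factors.
  nc <- dims[[1]]; nr <- dims[[2]]; ntau <- dims[[3]]
  ne <- dims[[4]]; ng <- dims[[5]]
  if (is.null(sepRank)) sepRank <- 12L
  sepRank <- min(sepRank, Lf * ranks[1] * ranks[2],
                 ranks[3] * ranks[4] * ranks[5], nc * nr * Lf,
                 ntau * ne * ng)
  ## cell index (cardiac fastest) -> (rowGroup = (c, r), col = (tau, e, g))
  cellsArr <- arrayInd(seq_len(nCells), .dim = unname(dims))
  rgOf <- cellsArr[, 1] + nc * (cellsArr[, 2] - 1L)          # 1..nc*nr
  colOf <- cellsArr[, 3] + ntau * ((cellsArr[, 4] - 1L) +
                                     ne * (cellsArr[, 5] - 1L))
  nRg <- nc * nr; nCol <- ntau * ne * ng
  ## dense (Lf, rowGroup, col) view of the cell means, with a block mask
  ## (every echo of an acquired training cell is observed together)
  M <- array(0 + 0i, dim = c(Lf, nRg, nCol))
  Omask <- matrix(FALSE, nRg, nCol)
  oIdx <- which(obs)
  lin0 <- (as.numeric(colOf[oIdx]) - 1) * (Lf * nRg) + (rgOf[oIdx] - 1) * Lf
  for (l in seq_len(Lf)) M[lin0 + l] <- Xm[l, oIdx]
  Omask[cbind(rgOf[oIdx], colOf[oIdx])] <- TRUE
  ## ALS on M(f, rg, col) ~ sum_q A[f, rg, q] * Conj(B[col, q]); columns
  ## sharing a (tau, gd) pair have identical observed row groups, so the
  ## B update solves one small system per (tau, gd) for all echoes at once
  B <- withSeed(seed, matrix(complex(real = stats::rnorm(nCol * sepRank),
                                     imaginary = stats::rnorm(nCol * sepRank)),
                             nCol, sepRank) / sqrt(nCol))
  A <- array(0 + 0i, dim = c(Lf, nRg, sepRank))
  ridge <- function(G) G + 1e-6 * max(Re(diag(G)), 1e-30) * diag(nrow(G))
  colsOfTg <- function(tauI, gI)
    tauI + ntau * ((seq_len(ne) - 1L) + ne * (gI - 1L))
  tgPairs <- unique(cbind(cellsArr[oIdx, 3], cellsArr[oIdx, 5]))
  prevFit <- Inf
  for (sweep in seq_len(max(maxSweeps, 2L))) {
    for (rg in seq_len(nRg)) {
      js <- which(Omask[rg, ])
      Bo <- B[js, , drop = FALSE]
      A[, rg, ] <- (matrix(M[, rg, js], Lf) %*% Bo) %*%
        solve(ridge(crossprod(Conj(Bo), Bo)))
    }
    fitNum <- 0; fitDen <- 0
    for (k in seq_len(nrow(tgPairs))) {
      js <- colsOfTg(tgPairs[k, 1], tgPairs[k, 2])
      rgs <- which(Omask[, js[1]])
      Ao <- matrix(A[, rgs, ], Lf * length(rgs), sepRank)
      Y <- matrix(M[, rgs, js], Lf * length(rgs), ne)
      sol <- solve(ridge(crossprod(Conj(Ao), Ao)), crossprod(Conj(Ao), Y))
      B[js, ] <- Conj(t(sol))
      res <- Y - Ao %*% sol
      fitNum <- fitNum + sum(Mod(res)^2)
      fitDen <- fitDen + sum(Mod(Y)^2)
    }
    ## rebalance the factor scales (ALS drifts toward huge-A/small-B
    ## otherwise, which wrecks the imputed entries numerically)
    nA <- sqrt(apply(Mod(A)^2, 3, sum))
    nB <- sqrt(colSums(Mod(B)^2))
    tgt <- sqrt(pmax(nA * nB, 1e-300))
    for (q in seq_len(sepRank)) {
      if (nA[q] > 0) A[, , q] <- A[, , q] * (tgt[q] / nA[q])
      if (nB[q] > 0) B[, q] <- B[, q] * (tgt[q] / nB[q])
    }
    fit <- sqrt(fitNum / max(fitDen, 1e-30))
    if (abs(prevFit - fit) < tol * max(fit, 1e-30) || fit < tol) break
    prevFit <- fit
  }
  ## columns whose (tau, gd) pair was never visited keep meaningless init
  ## rows; borrow the nearest observed gd bin at the same tau
  allTg <- expand.grid(tau = seq_len(ntau), g = seq_len(ng))
  seen <- paste(tgPairs[, 1], tgPairs[, 2])
  for (k in which(!(paste(allTg$tau, allTg$g) %in% seen))) {
    tauI <- allTg$tau[k]; gI <- allTg$g[k]
    gObs <- tgPairs[tgPairs[, 1] == tauI, 2]
    if (length(gObs) == 0L) next
    gNear <- gObs[which.min(abs(gObs - gI))]
    B[colsOfTg(tauI, gI), ] <- B[colsOfTg(tauI, gNear), ]
  }
  ## completed tensor from the factorization; observed cells keep their data
  Mfull <- matrix(A, Lf * nRg, sepRank) %*% Conj(t(B))   # (Lf*nRg) x nCol
  Xfull <- matrix(0 + 0i, Lf, nCells)
  linAll <- (as.numeric(colOf) - 1) * (Lf * nRg) + (rgOf - 1) * Lf
  for (l in seq_len(Lf)) Xfull[l, ] <- Mfull[linAll + l]
  Xfull[, obs] <- Xm[, obs]
  X <- array(Xfull, dim = c(Lf, dims))
  ## --- single HOSVD pass for the per-dimension factors ------------------
  ranks6 <- c(Lf, ranks)
  dims6 <- c(Lf, dims)
  truncated <- which(ranks6 < dims6)
  shrinkOrder <- truncated[order(ranks6[truncated] / dims6[truncated])]
  Us <- lapply(seq_len(6), function(m) diag(dims6[m]) + 0i)
  for (m in truncated) Us[[m]] <- topLeftSV(unfoldTensor(X, m), ranks6[m])
  core <- X
  for (m in shrinkOrder) core <- modeProduct(core, Conj(t(Us[[m]])), m)
  ## joint temporal basis: row space of the completed tensor's spatial
  ## unfolding, expressed through the Tucker factors
  G1 <- unfoldTensor(core, 1)                 # Lf' x prod(ranks)
  sv <- svd(G1)
  L <- min(jointRank, nrow(G1), ncol(G1))
  phi <- matrix(0 + 0i, L, nCells)
  for (l in seq_len(L)) {
    ## row l of the spatial unfolding is (K %*% Conj(v_l))^T with
    ## K = Ug x Ue x Utau x Ur x Uc (Kronecker, cardiac fastest)
    vt <- array(Conj(sv$v[, l]), dim = ranks)
    for (m in 1:5) vt <- modeProduct(vt, Us[[m + 1]], m)
    phi[l, ] <- as.vector(vt)
  }
  new("TemporalSubspace", Uc = Us[[2]], Ur = Us[[3]], Utau = Us[[4]],
      Ue = Us[[5]], Ug = Us[[6]], core = core, Uf = Uf, phi = phi,
      dims = as.integer(dims), singularValues = sv$d[seq_len(L)])
}

setMethod("show", "TemporalSubspace", function(object) {
  d <- object@dims
  cat(sprintf("TemporalSubspace: %d joint basis vectors over %s cells\n",
              nrow(object@phi),
              paste(d, collapse = "x")))
  cat(sprintf("  factor ranks: cardiac %d, resp %d, tau %d, echo %d, gd %d\n",
              ncol(object@Uc), ncol(object@Ur), ncol(object@Utau),
              ncol(object@Ue), ncol(object@Ug)))
})

## 1-based phi column for 0-based (cardiac, resp, tau, echo, gd)
phiCellIndex <- function(dims, c0, r0, t0, e0, g0) {
  1 + c0 + as.numeric(dims[1]) *
    (r0 + as.numeric(dims[2]) *
       (t0 + as.numeric(dims[3]) * (e0 + as.numeric(dims[4]) * g0)))
}

## per-(event, echo) phi column indices, echo fastest
eventCellIndex <- function(subspace, binning, nEcho) {
  n <- length(binning@cardiacBin)
  d <- subspace@dims
  cells <- matrix(0, nEcho, n)
  for (e0 in 0:(nEcho - 1L))
    cells[e0 + 1L, ] <- phiCellIndex(d, binning@cardiacBin, binning@respBin,
                                     binning@tauIndex, e0, binning@gdBin)
  cells
}

## group events by (ky, kz) row and precompute the L x L basis Gram matrix
## and phi column sets per row
rowStructure <- function(schedule, subspace, binning, nEcho, grid) {
  ev <- schedule@events
  rowIdx <- kIndexToSlot(ev$ky, grid[2]) +
    as.numeric(grid[2]) * (kIndexToSlot(ev$kz, grid[3]) - 1L)
  cells <- eventCellIndex(subspace, binning, nEcho)
  groups <- split(seq_len(nrow(ev)), rowIdx)
  rows <- as.integer(names(groups))
  L <- nrow(subspace@phi)
  Q <- vector("list", length(groups))
  P <- vector("list", length(groups))
  for (i in seq_along(groups)) {
    E <- groups[[i]]
    cid <- as.vector(cells[, E])              # echo fastest within event
    Pi <- subspace@phi[, cid, drop = FALSE]
    P[[i]] <- Pi
    Q[[i]] <- Pi %*% Conj(t(Pi))
  }
  list(rows = rows, groups = groups, Q = Q, P = P, cells = cells,
       rowIdx = rowIdx)
}

#' Solve for the spatial factor by conjugate gradient
#'
#' Minimizes the data-consistency objective
#' \code{sum_events |Omega(F S (Ux phi_cell)) - d|^2 + lambda |Ux|_F^2}
#' over the complex spatial factor, by CG on the normal equations. The
#' residual history is recorded; a 10x residual increase raises a solver
#' failure.
#'
#' @param kdata a \linkS4class{KSpaceData}
#' @param coils a \linkS4class{CoilSet}
#' @param subspace a \linkS4class{TemporalSubspace}
#' @param binning a \linkS4class{BinningResult}
#' @param schedule a \linkS4class{SamplingSchedule}
#' @param voxelMm voxel size carried to the reconstruction
#' @param lambda Tikhonov weight (on the k-space-scale objective)
#' @param tol relative-residual stop (default 1e-6)
#' @param maxIter CG iteration cap
#' @param precondition use the per-row k-space preconditioner (inverts
#'   \code{sos * Q_r + delta I} per phase-encode row; exact for a uniform
#'   coil, and essential because the Gaussian density makes row occupancies
#'   span orders of magnitude); also enables a preconditioned warm start
#' @param precondFloor regularization floor of the preconditioner, as a
#'   fraction of the dominant row scale
#' @return a \linkS4class{ReconImage6D}
#' @export
solveSpatial <- function(kdata, coils, subspace, binning, schedule,
                         voxelMm = c(1, 1, 1), lambda = 0, tol = 1e-6,
                         maxIter = 50L, precondition = TRUE,
                         precondFloor = 3e-3) {
  g <- dim(coils@maps)[1:3]
  nEcho <- kdata@nEcho; nx <- kdata@nKx
  if (nx != g[1]) stopf("readout length does not match coil grid")
  L <- nrow(subspace@phi)
  nC <- length(kdata@samples)
  rs <- rowStructure(schedule, subspace, binning, nEcho, g)
  nvox <- prod(g)
  nRowTot <- g[2] * g[3]
  ## right-hand side b = A^H d  (adjoint DFT = unnormalized inverse)
  b <- matrix(0 + 0i, nvox, L)
  for (ci in seq_len(nC)) {
    D <- kdata@samples[[ci]]
    Bc <- array(0 + 0i, dim = c(nx, nRowTot, L))
    for (i in seq_along(rs$rows)) {
      E <- rs$groups[[i]]
      Dm <- D[, E, drop = FALSE]
      dim(Dm) <- c(nx, nEcho * length(E))
      Bc[, rs$rows[i], ] <- Bc[, rs$rows[i], ] + Dm %*% Conj(t(rs$P[[i]]))
    }
    mapC <- Conj(coils@maps[, , , ci])
    for (l in seq_len(L)) {
      v <- array(Bc[, , l], dim = g)
      b[, l] <- b[, l] + as.vector(mapC * stats::fft(v, inverse = TRUE))
    }
  }
  applyNormal <- function(U) {
    out <- matrix(0 + 0i, nvox, L)
    for (ci in seq_len(nC)) {
      map <- coils@maps[, , , ci]
      Y <- array(0 + 0i, dim = c(nx, nRowTot, L))
      for (l in seq_len(L))
        Y[, , l] <- matrix(fft3(array(map * U[, l], dim = g)), nx, nRowTot)
      Z <- array(0 + 0i, dim = c(nx, nRowTot, L))
      for (i in seq_along(rs$rows)) {
        r <- rs$rows[i]
        Z[, r, ] <- Y[, r, ] %*% rs$Q[[i]]
      }
      mapC <- Conj(map)
      for (l in seq_len(L))
        out[, l] <- out[, l] +
          as.vector(mapC * stats::fft(array(Z[, , l], dim = g),
                                      inverse = TRUE))
    }
    if (lambda > 0) out <- out + lambda * U
    out
  }
  ## problem scale: lambda is specified relative to the dominant normal-
  ## operator eigenvalue scale so that it is grid- and SNR-invariant
  sos <- array(0, dim = g)
  for (ci in seq_len(nC)) sos <- sos + Mod(coils@maps[, , , ci])^2
  sBar <- mean(sos[sos > 0.01 * max(sos)]) * nvox   # includes F^H F = N I
  diagMax <- max(vapply(rs$Q, function(Q) max(Re(diag(Q))), numeric(1)))
  lambda <- lambda * sBar * diagMax
  applyPrecond <- identity
  if (precondition) {
    delta <- max(lambda, precondFloor * sBar * diagMax)
    Minv <- lapply(rs$Q, function(Q)
      solve(sBar * Q + delta * diag(L)))
    MinvEmpty <- diag(L) / delta
    rowHasData <- logical(nRowTot)
    rowHasData[rs$rows] <- TRUE
    rowLookup <- integer(nRowTot)
    rowLookup[rs$rows] <- seq_along(rs$rows)
    applyPrecond <- function(R) {
      out <- matrix(0 + 0i, nvox, L)
      Y <- array(0 + 0i, dim = c(nx, nRowTot, L))
      for (l in seq_len(L))
        Y[, , l] <- matrix(fft3(array(R[, l], dim = g)), nx, nRowTot)
      Z <- array(0 + 0i, dim = c(nx, nRowTot, L))
      for (rr in seq_len(nRowTot)) {
        M <- if (rowHasData[rr]) Minv[[rowLookup[rr]]] else MinvEmpty
        Z[, rr, ] <- Y[, rr, ] %*% M
      }
      for (l in seq_len(L))
        out[, l] <- as.vector(stats::fft(array(Z[, , l], dim = g),
                                         inverse = TRUE)) / nvox
      out
    }
  }
  ## preconditioned warm start: x0 = M^-1 b is already close for the
  ## well-sampled rows, so CG only has to polish the weak directions
  if (precondition) {
    x <- applyPrecond(b)
    r <- b - applyNormal(x)
  } else {
    x <- matrix(0 + 0i, nvox, L)
    r <- b
  }
  z <- applyPrecond(r)
  p <- z
  rs0 <- Re(sum(Conj(b) * b))
  rzOld <- Re(sum(Conj(r) * z))
  hist <- numeric(0)
  minRes <- Inf
  for (it in seq_len(maxIter)) {
    Ap <- applyNormal(p)
    alpha <- rzOld / Re(sum(Conj(p) * Ap))
    x <- x + alpha * p
    r <- r - alpha * Ap
    rel <- sqrt(Re(sum(Conj(r) * r)) / rs0)
    hist <- c(hist, rel)
    if (rel > 10 * max(minRes, 1e-300) && rel > 1)
      stopf("solver failure: CG residual diverged at iteration %d", it)
    minRes <- min(minRes, rel)
    if (rel <= tol) break
    z <- applyPrecond(r)
    rzNew <- Re(sum(Conj(r) * z))
    p <- z + (rzNew / rzOld) * p
    rzOld <- rzNew
  }
  new("ReconImage6D", Ux = x, subspace = subspace, grid = as.integer(g),
      voxelMm = voxelMm, residuals = hist)
}

setMethod("show", "ReconImage6D", function(object) {
  cat(sprintf("ReconImage6D: %dx%dx%d grid, %d basis coefficients/voxel\n",
              object@grid[1], object@grid[2], object@grid[3],
              ncol(object@Ux)))
  if (length(object@residuals))
    cat(sprintf("  CG: %d iterations, final relative residual %.2e\n",
                length(object@residuals), tail(object@residuals, 1)))
})

#' Materialize image frames from the factored reconstruction
#'
#' Indices are 0-based, matching \linkS4class{BinningResult}. Vectors are
#' recycled to the longest, one frame per tuple.
#'
#' @param recon a \linkS4class{ReconImage6D}
#' @param cardiac,resp,tau,echo,gd 0-based cell indices
#' @param what "magnitude" or "complex"
#' @return array (nx, ny, nz, nFrames)
#' @export
composeImages <- function(recon, cardiac = 0L, resp = 0L, tau = 0L,
                          echo = 0L, gd = 0L, what = c("magnitude", "complex")) {
  what <- match.arg(what)
  d <- recon@subspace@dims
  q <- data.frame(cardiac, resp, tau, echo, gd)
  lim <- c(d[1], d[2], d[3], d[4], d[5])
  dimNm <- c("cardiac", "resp", "tau", "echo", "gd")
  for (j in 1:5) if (any(q[[j]] < 0 | q[[j]] >= lim[j]))
    stopf("query index out of range along '%s'", dimNm[j])
  cid <- phiCellIndex(d, q$cardiac, q$resp, q$tau, q$echo, q$gd)
  img <- recon@Ux %*% recon@subspace@phi[, cid, drop = FALSE]
  if (what == "magnitude") img <- Mod(img)
  array(img, dim = c(recon@grid, nrow(q)))
}

#' Native segment index nearest a target inversion time
#'
#' @param params a \linkS4class{SequenceParams}
#' @param tauMs target time since inversion (ms)
#' @param decim optional grouping factor; if given, returns the grouped
#'   index instead of the native segment index
#' @return 0-based index
#' @export
tauIndexForMs <- function(params, tauMs, decim = NULL) {
  idx <- round((tauMs - params@ti0Ms) / params@trMs)
  idx <- min(max(idx, 0), params@segmentsPerIR - 1L)
  if (!is.null(decim)) idx <- idx %/% decim
  as.integer(idx)
}

#' Grouped tau index that best nulls a tissue of given T1
#'
#' Uses the closed-form IR-FLASH cyclic steady state to locate the readout
#' whose magnitude is smallest for the given relaxation time.
#'
#' @param params a \linkS4class{SequenceParams}
#' @param t1Ms tissue T1 (ms)
#' @param decim tau grouping factor
#' @return 0-based grouped tau index
#' @export
tauNullIndex <- function(params, t1Ms, decim = 6L) {
  tr <- irFlashTrain(t1Ms, 1, params)
  as.integer((which.min(abs(tr$s[1, ])) - 1L) %/% decim)
}

#' Simulate k-space directly from a factored model
#'
#' Forward-evaluates \code{Omega F S (Ux phi)} at every scheduled event;
#' used for exact-recovery oracles and self-consistency checks.
#'
#' @param Ux complex spatial factor (nVoxels x L)
#' @param subspace a \linkS4class{TemporalSubspace}
#' @param schedule a \linkS4class{SamplingSchedule}
#' @param binning a \linkS4class{BinningResult}
#' @param coils a \linkS4class{CoilSet}
#' @param nEcho echoes per readout
#' @return a \linkS4class{KSpaceData}
#' @export
simulateFromSubspace <- function(Ux, subspace, schedule, binning, coils,
                                 nEcho = length(schedule@params@teMs)) {
  g <- dim(coils@maps)[1:3]
  L <- nrow(subspace@phi)
  nC <- dim(coils@maps)[4]
  rs <- rowStructure(schedule, subspace, binning, nEcho, g)
  n <- nrow(schedule@events)
  samples <- vector("list", nC)
  nRowTot <- g[2] * g[3]
  for (ci in seq_len(nC)) {
    map <- coils@maps[, , , ci]
    Y <- array(0 + 0i, dim = c(g[1], nRowTot, L))
    for (l in seq_len(L))
      Y[, , l] <- matrix(fft3(array(map * Ux[, l], dim = g)), g[1], nRowTot)
    D <- matrix(0 + 0i, g[1] * nEcho, n)
    for (i in seq_along(rs$rows)) {
      E <- rs$groups[[i]]
      lines <- Y[, rs$rows[i], ] %*% rs$P[[i]]   # nx x (nEcho*|E|)
      dim(lines) <- c(g[1] * nEcho, length(E))
      D[, E] <- lines
    }
    samples[[ci]] <- D
  }
  new("KSpaceData", samples = samples, nKx = g[1], nEcho = as.integer(nEcho),
      noiseSigma = 0, truth = list())
}

#' Construct a temporal subspace from known factors
#'
#' Builds the joint basis \code{phi} for data synthesized exactly from a
#' Tucker model (oracle tests) or for reconstruction with a known subspace.
#'
#' @param Uc,Ur,Utau,Ue,Ug orthonormal-column factor matrices
#' @param core coefficient tensor (L x L_c x L_r x L_tau x L_e x L_g); its
#'   first mode indexes the joint basis vectors
#' @return a \linkS4class{TemporalSubspace}
#' @export
temporalSubspace <- function(Uc, Ur, Utau, Ue, Ug, core) {
  dims <- c(nrow(Uc), nrow(Ur), nrow(Utau), nrow(Ue), nrow(Ug))
  names(dims) <- c("cardiac", "resp", "tau", "echo", "gd")
  L <- dim(core)[1]
  nCells <- prod(dims)
  Us <- list(Uc, Ur, Utau, Ue, Ug)
  phi <- matrix(0 + 0i, L, nCells)
  for (l in seq_len(L)) {
    vt <- array(core[l, , , , , ], dim = dim(core)[-1])
    for (m in 1:5) vt <- modeProduct(vt, Us[[m]], m)
    phi[l, ] <- as.vector(vt)
  }
  ## orthonormalize the rows so the class invariant holds regardless of core
  qr2 <- qr(t(phi))
  phiO <- t(qr.Q(qr2))
  new("TemporalSubspace", Uc = Uc, Ur = Ur, Utau = Utau, Ue = Ue, Ug = Ug,
      core = core, Uf = diag(L) + 0i, phi = phiO, dims = as.integer(dims),
      singularValues = rep(NA_real_, L))
}
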
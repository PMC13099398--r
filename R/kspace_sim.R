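## Multi-coil Cartesian k-space simulation of the free-running acquisition,
## and the idealized gated/breath-held comparator study.
##
## The readout (kx) is treated as instantaneous and fully sampled each TR;
## motion is frozen within a TR. Motion is rendered on a discrete grid of
## cardiac-phase x respiratory-displacement states (defaults matching the
## reconstruction's nominal 24 x 4 phase resolution), and the gadolinium
## concentration is frozen per inversion block (block length 2.53 s), which
## bounds the within-block kinetic error. Each scheduled event then needs
## only a per-class line lookup from the FFT of that state's class
## indicators, weighted by the closed-form IR-FLASH segment signals.

#' Build smooth coil sensitivity maps
#'
#' Complex Gaussian-lobe profiles centered on the torso perimeter with a
#' mild linear phase per coil, normalized to unit sum-of-squares magnitude
#' at the heart center. \code{nCoils = 1} gives a uniform unit coil (oracle
#' mode).
#'
#' @param grid voxel counts (nx, ny, nz)
#' @param voxelMm voxel size (mm)
#' @param nCoils number of coils
#' @param centerMm heart center for normalization
#' @return a \linkS4class{CoilSet}
#' @export
makeCoils <- function(grid, voxelMm, nCoils = 8, centerMm = c(0, 0, 0)) {
  g <- as.integer(grid)
  maps <- array(0 + 0i, dim = c(g, nCoils))
  if (nCoils == 1L) {
    maps[, , , 1] <- 1 + 0i
    return(new("CoilSet", maps = maps))
  }
  xs <- axisCoords(g[1], voxelMm[1])
  ys <- axisCoords(g[2], voxelMm[2])
  X <- matrix(xs, g[1], g[2]); Y <- matrix(ys, g[1], g[2], byrow = TRUE)
  Rring <- 0.62 * min(g[1] * voxelMm[1], g[2] * voxelMm[2])
  width <- 0.55 * Rring
  for (k in seq_len(nCoils)) {
    phik <- 2 * pi * (k - 1) / nCoils
    cx <- Rring * cos(phik); cy <- Rring * sin(phik)
    mag <- exp(-((X - cx)^2 + (Y - cy)^2) / (2 * width^2))
    phs <- 0.004 * (X * cos(phik + pi / 4) + Y * sin(phik + pi / 4))
    m2d <- mag * exp(1i * phs)
    maps[, , , k] <- array(rep(m2d, g[3]), dim = g)
  }
  ic <- c(which.min(abs(xs - centerMm[1])), which.min(abs(ys - centerMm[2])),
          max(1L, g[3] %/% 2))
  sos <- sqrt(sum(Mod(maps[ic[1], ic[2], ic[3], ])^2))
  new("CoilSet", maps = maps / sos)
}

#' @rdname makeCoils
#' @param x a \linkS4class{CoilSet}
#' @export
nCoils <- function(x) dim(x@maps)[4]

## per-class IR-FLASH segment signal tables: base[[class]] is an
## (nBlocks x nSeg) transverse-signal matrix (PD included, Gd frozen at
## block start), echoFac[[class]] the per-echo T2* decay factors
classSignalTables <- function(phantom, params, nBlocks, tInjectOffsetS) {
  blockMs <- params@segmentsPerIR * params@trMs + params@deadTimeMs
  tGd <- (seq_len(nBlocks) - 1) * blockMs / 1000 + tInjectOffsetS
  classes <- setdiff(names(tissueClassCodes), "background")
  base <- list(); echoFac <- list()
  for (nm in classes) {
    tp <- phantom@tissues[[nm]]
    t1 <- effectiveT1(tp@t1_0, tp@r1, gdConcentration(tGd, tp@kinetics))
    tr <- irFlashTrain(t1, m0 = 1, params)
    base[[nm]] <- tr$s * tp@pd
    echoFac[[nm]] <- exp(-params@teMs / tp@t2star)
  }
  list(base = base, echoFac = echoFac)
}

## quantized motion states for every event: cardiac bins of the phase,
## respiratory bins of the displacement (quantiles), with representative
## render values per bin
eventMotionStates <- function(phantom, schedule, nCardiacStates, nRespStates) {
  ev <- schedule@events
  mo <- phantom@motion
  cPhase <- (ev$tMs / mo@rrMs) %% 1
  rPhase <- (ev$tMs / mo@respMs) %% 1
  disp <- mo@respAmpMm * (1 - cos(2 * pi * rPhase)) / 2
  cState <- pmin(as.integer(floor(cPhase * nCardiacStates)),
                 nCardiacStates - 1L)
  if (nRespStates > 1L && stats::sd(disp) > 0) {
    qs <- stats::quantile(disp, probs = seq(0, 1, length.out = nRespStates + 1))
    qs[1] <- -Inf; qs[length(qs)] <- Inf
    rState <- as.integer(cut(disp, breaks = qs)) - 1L
  } else rState <- integer(length(disp))
  dispLevels <- vapply(seq_len(nRespStates) - 1L,
                       function(r) if (any(rState == r)) mean(disp[rState == r]) else 0,
                       numeric(1))
  ## state k rendered at its bin center; state 0 sits at end-diastole
  cRender <- (seq_len(nCardiacStates) - 0.5) / nCardiacStates
  list(cPhase = cPhase, disp = disp, cState = cState, rState = rState,
       dispLevels = dispLevels, cRender = cRender)
}

#' Simulate the free-running multi-coil acquisition
#'
#' Renders the phantom through the IR-FLASH signal model at every scheduled
#' readout and samples the (ky, kz) Cartesian line over all kx and echoes
#' for every coil, adding i.i.d. complex Gaussian noise.
#'
#' @param phantom a \linkS4class{DigitalPhantom}
#' @param schedule a \linkS4class{SamplingSchedule}; \code{nKy}, \code{nKz}
#'   must match the phantom grid
#' @param coils a \linkS4class{CoilSet}
#' @param noiseSigma per-sample complex noise SD (k-space scale); see
#'   \code{\link{noiseSigmaForSnr}}
#' @param tInjectOffsetS scan start relative to gadolinium injection (s)
#' @param seed noise seed
#' @param nCardiacStates,nRespStates motion quantization of the renderer
#' @return a \linkS4class{KSpaceData}
#' @export
simulateFreeRunning <- function(phantom, schedule, coils,
                                noiseSigma = 0, tInjectOffsetS = 45,
                                seed = 0, nCardiacStates = 24L,
                                nRespStates = 4L) {
  g <- phantom@grid
  p <- schedule@params
  if (p@nKy != g[2] || p@nKz != g[3])
    stopf("grid mismatch: schedule %dx%d vs phantom %dx%d",
          p@nKy, p@nKz, g[2], g[3])
  ev <- schedule@events
  n <- nrow(ev)
  nEcho <- length(p@teMs)
  nC <- nCoils(coils)
  st <- eventMotionStates(phantom, schedule, nCardiacStates, nRespStates)
  nBlocks <- max(ev$irBlock) + 1L
  sig <- classSignalTables(phantom, p, nBlocks, tInjectOffsetS)
  heartClasses <- intersect(c("blood", "myocardium", "mi", "mvo", "imh"),
                            names(sig$base))
  colIdx <- kIndexToSlot(ev$ky, g[2]) +
    as.numeric(g[2]) * (kIndexToSlot(ev$kz, g[3]) - 1L)
  bsIdx <- cbind(ev$irBlock + 1L, ev$seg + 1L)
  stateKey <- st$cState * 1000L + st$rState
  groups <- split(seq_len(n), stateKey)
  ## partial-volume fractions: boundary voxels mix class signals by area
  liverInd <- array(rep(classFractions(phantom, 0, dispMm = 0)$liver, g[3]),
                    dim = g)
  samples <- vector("list", nC)
  for (ci in seq_len(nC)) {
    map <- array(coils@maps[, , , ci], dim = g)
    Fliver <- matrix(fft3(liverInd * map), g[1], g[2] * g[3])
    wLiver <- sig$base$liver[bsIdx]
    efAll <- rbind(do.call(rbind, sig$echoFac[heartClasses]),
                   sig$echoFac$liver)
    D <- matrix(0 + 0i, g[1] * nEcho, n)
    for (grp in groups) {
      cS <- st$cState[grp[1]]; rS <- st$rState[grp[1]]
      fr <- classFractions(phantom, st$cRender[cS + 1L],
                           dispMm = st$dispLevels[rS + 1L])
      m <- length(grp)
      Cmat <- matrix(0 + 0i, g[1] * m, length(heartClasses) + 1L)
      for (j in seq_along(heartClasses)) {
        nm <- heartClasses[j]
        ind <- array(rep(fr[[nm]], g[3]), dim = g)
        Fm <- matrix(fft3(ind * map), g[1], g[2] * g[3])
        lines <- Fm[, colIdx[grp], drop = FALSE]
        w <- sig$base[[nm]][bsIdx[grp, , drop = FALSE]]
        Cmat[, j] <- lines * rep(w, each = g[1])
      }
      Cmat[, length(heartClasses) + 1L] <-
        Fliver[, colIdx[grp], drop = FALSE] * rep(wLiver[grp], each = g[1])
      blk <- Cmat %*% efAll                      # (nx*m) x nEcho
      dim(blk) <- c(g[1], m, nEcho)
      blk <- aperm(blk, c(1, 3, 2))
      dim(blk) <- c(g[1] * nEcho, m)
      D[, grp] <- blk
    }
    if (noiseSigma > 0) {
      withSeed(deriveSeed(seed, ci), {
        chunk <- max(1L, n %/% 8L)
        starts <- seq(1L, n, by = chunk)
        for (s0 in starts) {
          cols <- s0:min(s0 + chunk - 1L, n)
          D[, cols] <- D[, cols] +
            complexNoise(length(cols) * g[1] * nEcho, noiseSigma)
        }
      })
    }
    samples[[ci]] <- D
  }
  new("KSpaceData", samples = samples, nKx = g[1], nEcho = as.integer(nEcho),
      noiseSigma = noiseSigma,
      truth = list(cPhase = st$cPhase, disp = st$disp, cState = st$cState,
                   rState = st$rState, dispLevels = st$dispLevels,
                   gdTimeS = (ev$tMs - ev$tauMs) / 1000 + tInjectOffsetS,
                   tInjectOffsetS = tInjectOffsetS))
}

#' k-space noise level for a target image-domain SNR
#'
#' With the unnormalized forward DFT used throughout, a k-space sample SD of
#' \code{sigma} propagates to an image-domain SD of \code{sigma/sqrt(Nvox)}.
#' The reference signal is the remote-myocardium magnitude at the late-tau,
#' late-enhancement anatomical frame (first echo).
#'
#' @param phantom a \linkS4class{DigitalPhantom}
#' @param params a \linkS4class{SequenceParams}
#' @param snr target image signal-to-noise ratio
#' @param tRefS reference time since injection (s)
#' @return per-sample complex noise SD on the k-space scale
#' @export
noiseSigmaForSnr <- function(phantom, params, snr, tRefS = 800) {
  tp <- phantom@tissues$myocardium
  t1 <- effectiveT1(tp@t1_0, tp@r1, gdConcentration(tRefS, tp@kinetics))
  tr <- irFlashTrain(t1, m0 = 1, params)
  sRef <- abs(tr$s[1, params@segmentsPerIR]) * tp@pd *
    exp(-params@teMs[1] / tp@t2star)
  nvox <- prod(phantom@grid)
  sRef * sqrt(nvox) / snr
}

## spoiled-GRE steady-state transverse signal
flashSteadyState <- function(t1Ms, trMs, flipDeg) {
  a <- flipDeg * pi / 180
  E1 <- exp(-trMs / t1Ms)
  (1 - E1) / (1 - E1 * cos(a)) * sin(a)
}

## gated inversion-recovery snapshot (inversion every nRR heartbeats):
## longitudinal steady state before inversion, read at TI
irSnapshotSignal <- function(t1Ms, tiMs, rrMs, nRR = 2) {
  EP <- exp(-nRR * rrMs / t1Ms)
  1 - (2 / (1 + EP)) * exp(-tiMs / t1Ms)
}

## TI that nulls a tissue with relaxation time t1Ms under the same model
tiNullFor <- function(t1Ms, rrMs, nRR = 2) {
  EP <- exp(-nRR * rrMs / t1Ms)
  t1Ms * log(2 / (1 + EP))
}

#' Simulate the conventional gated, breath-held comparator study
#'
#' Idealized comparator: fully sampled magnitude volumes rendered at
#' end-expiration. Cine frames are spoiled-GRE contrast over gated cardiac
#' phases; T2* imaging is a pre-contrast eight-echo gradient-echo at
#' end-diastole; EGE and LGE are gated inversion-recovery snapshots
#' (inversion every second heartbeat) with the inversion time nulling remote
#' myocardium, plus T1-weighted spoiled-GRE enhancement volumes at the same
#' time points (the inputs for MVO sizing).
#'
#' @param phantom a \linkS4class{DigitalPhantom}
#' @param noiseSigma k-space-scale complex noise SD (propagated to the image
#'   domain as \code{noiseSigma/sqrt(Nvox)})
#' @param seed noise seed
#' @param nPhases cine frames per cycle
#' @param egeTimeS,lgeTimeS enhancement times (s after injection)
#' @param cineTimeS time point whose contrast the cine frames carry
#' @param teMsT2star conventional multi-echo times (ms)
#' @param trMs,flipDeg spoiled-GRE readout of the comparator
#' @return a \linkS4class{ConventionalStudy}
#' @export
simulateConventional <- function(phantom, noiseSigma = 0, seed = 0,
                                 nPhases = 24L, egeTimeS = 120,
                                 lgeTimeS = 900, cineTimeS = 120,
                                 teMsT2star = c(1.47, 3.38, 5.39, 7.4,
                                                9.41, 11.42, 13.43, 15.44),
                                 trMs = 13.2, flipDeg = 20) {
  g <- phantom@grid
  sigImg <- noiseSigma / sqrt(prod(g))
  rr <- phantom@motion@rrMs
  addNoise <- function(img) {
    if (sigImg <= 0) return(abs(img))
    Mod(img + array(complexNoise(length(img), sigImg), dim = dim(img)))
  }
  ## per-class scalar signal at time tS, then partial-volume mixing
  classSignalAt <- function(tS, fun) {
    vapply(names(tissueClassCodes), function(nm) {
      tp <- phantom@tissues[[nm]]
      t1 <- effectiveT1(tp@t1_0, tp@r1, gdConcentration(tS, tp@kinetics))
      fun(tp, t1)
    }, numeric(1))
  }
  pvVolume <- function(cardiacPhase, sig) {
    fr <- classFractions(phantom, cardiacPhase, dispMm = 0)
    img2d <- Reduce(`+`, Map(function(f, snm) f * sig[[snm]],
                             fr, names(fr)))
    array(rep(img2d, g[3]), dim = g)
  }
  out <- withSeed(seed, {
    cine <- array(0, dim = c(g, nPhases))
    sigCine <- classSignalAt(cineTimeS, function(tp, t1)
      tp@pd * flashSteadyState(t1, trMs, flipDeg) * exp(-1.47 / tp@t2star))
    for (ph in seq_len(nPhases))
      cine[, , , ph] <- addNoise(pvVolume((ph - 1) / nPhases, sigCine))
    t2e <- array(0, dim = c(g, length(teMsT2star)))
    for (j in seq_along(teMsT2star)) {
      sigJ <- classSignalAt(0, function(tp, t1)
        tp@pd * flashSteadyState(t1, trMs, flipDeg) *
          exp(-teMsT2star[j] / tp@t2star))
      t2e[, , , j] <- addNoise(pvVolume(0, sigJ))
    }
    irVol <- function(tS) {
      tpRem <- phantom@tissues$myocardium
      t1Rem <- effectiveT1(tpRem@t1_0, tpRem@r1,
                           gdConcentration(tS, tpRem@kinetics))
      ti <- tiNullFor(t1Rem, rr)
      sig <- classSignalAt(tS, function(tp, t1)
        tp@pd * irSnapshotSignal(t1, ti, rr) * exp(-2.07 / tp@t2star))
      list(img = addNoise(pvVolume(0, sig)), ti = ti)
    }
    t1wVol <- function(tS) {
      sig <- classSignalAt(tS, function(tp, t1)
        tp@pd * flashSteadyState(t1, trMs, flipDeg) * exp(-2.07 / tp@t2star))
      addNoise(pvVolume(0, sig))
    }
    ege <- irVol(egeTimeS); lge <- irVol(lgeTimeS)
    list(cine = cine, t2e = t2e, ege = ege, lge = lge,
         egeT1w = t1wVol(egeTimeS), lgeT1w = t1wVol(lgeTimeS))
  })
  new("ConventionalStudy", cine = out$cine, t2starEchoes = out$t2e,
      teMs = teMsT2star, ege = out$ege$img, lge = out$lge$img,
      egeT1w = out$egeT1w, lgeT1w = out$lgeT1w,
      times = list(egeS = egeTimeS, lgeS = lgeTimeS,
                   tiEgeMs = out$ege$ti, tiLgeMs = out$lge$ti))
}
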
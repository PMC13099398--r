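## Free-running acquisition schedule: inversion blocks at a constant period
## (segmentsPerIR * TR + deadTime), multi-echo FLASH readouts within each
## block, one training (k-space center) line every `trainingEvery` readouts,
## and all other readouts drawing (ky, kz) from a truncated discrete Gaussian
## (sigma = N/6) centered on k-space center. Event times are kept as exact
## integers on a 0.1 ms tick grid so timing identities hold to the last digit.

#' Construct sequence parameters
#'
#' Defaults reproduce the free-running protocol (see
#' \linkS4class{SequenceParams}).
#'
#' @param trMs,teMs,flipDeg,ti0Ms,segmentsPerIR,trainingEvery,durationS
#'   sequence timing; see \linkS4class{SequenceParams}
#' @param nKy,nKz,fovMm,sliceMm encoding geometry
#' @param invEfficiency,deadTimeMs inversion model
#' @return a \linkS4class{SequenceParams}
#' @export
seqParams <- function(trMs = 13.2,
                      teMs = c(1.47, 3.38, 5.39, 7.4, 9.41, 11.42),
                      flipDeg = 5, ti0Ms = 10, segmentsPerIR = 192L,
                      trainingEvery = 6L, durationS = 860,
                      nKy = 192L, nKz = 14L, fovMm = c(270, 270),
                      sliceMm = 6, invEfficiency = 1, deadTimeMs = 0) {
  new("SequenceParams", trMs = trMs, teMs = teMs, flipDeg = flipDeg,
      ti0Ms = ti0Ms, segmentsPerIR = as.integer(segmentsPerIR),
      trainingEvery = as.integer(trainingEvery), durationS = durationS,
      nKy = as.integer(nKy), nKz = as.integer(nKz), fovMm = fovMm,
      sliceMm = sliceMm, invEfficiency = invEfficiency,
      deadTimeMs = deadTimeMs)
}

## truncated discrete Gaussian on [-n/2, n/2-1], sigma = n/6, by rejection
sampleTruncGauss <- function(nDraw, n) {
  sigma <- n / 6
  lo <- -n %/% 2; hi <- n %/% 2 - 1L
  out <- integer(nDraw)
  need <- seq_len(nDraw)
  while (length(need) > 0L) {
    cand <- as.integer(round(stats::rnorm(length(need), 0, sigma)))
    ok <- cand >= lo & cand <= hi
    out[need[ok]] <- cand[ok]
    need <- need[!ok]
  }
  out
}

#' Build the free-running sampling schedule
#'
#' @param params a \linkS4class{SequenceParams}
#' @param seed integer; the phase-encode draws are the only randomness
#' @return a \linkS4class{SamplingSchedule}
#' @examples
#' sched <- buildSchedule(seqParams(durationS = 5), seed = 1)
#' @export
buildSchedule <- function(params = seqParams(), seed = 0) {
  trT <- round(params@trMs * 10)
  ti0T <- round(params@ti0Ms * 10)
  deadT <- round(params@deadTimeMs * 10)
  nSeg <- params@segmentsPerIR
  blockT <- nSeg * trT + deadT
  durT <- round(params@durationS * 10000)
  nBlocksMax <- durT %/% blockT + 1L
  b <- rep(seq_len(nBlocksMax) - 1L, each = nSeg)
  s <- rep(seq_len(nSeg) - 1L, times = nBlocksMax)
  tT <- b * blockT + ti0T + s * trT
  keep <- tT < durT
  if (!any(keep)) stopf("duration shorter than one TR: empty schedule")
  b <- b[keep]; s <- s[keep]; tT <- tT[keep]
  n <- length(tT)
  idx <- seq_len(n) - 1L
  isTraining <- (idx %% params@trainingEvery) == 0L
  nImg <- sum(!isTraining)
  ky <- integer(n); kz <- integer(n)
  withSeed(seed, {
    ky[!isTraining] <- sampleTruncGauss(nImg, params@nKy)
    kz[!isTraining] <- sampleTruncGauss(nImg, params@nKz)
  })
  ev <- data.frame(idx = idx, tTicks = tT, tMs = tT / 10,
                   irBlock = b, seg = s,
                   tauMs = (ti0T + s * trT) / 10,
                   ky = ky, kz = kz, isTraining = isTraining)
  new("SamplingSchedule", params = params, events = ev, seed = seed)
}

#' @describeIn buildSchedule number of readout events
#' @param x,object a \linkS4class{SamplingSchedule}
#' @export
nEvents <- function(x) nrow(x@events)

#' Schedule events accessor
#' @param x a \linkS4class{SamplingSchedule}
#' @return the events data.frame
#' @export
events <- function(x) x@events

setMethod("show", "SamplingSchedule", function(object) {
  ev <- object@events
  cat(sprintf("SamplingSchedule: %d readouts (%d training) over %.1f s\n",
              nrow(ev), sum(ev$isTraining), max(ev$tMs) / 1000))
  cat(sprintf("  %d IR blocks, %d segments/block, TR %.1f ms, %d echoes\n",
              max(ev$irBlock) + 1L, object@params@segmentsPerIR,
              object@params@trMs, length(object@params@teMs)))
  cat(sprintf("  phase encodes %d x %d, seed %g\n",
              object@params@nKy, object@params@nKz, object@seed))
})

#' Fraction of the full 5-way sampling tensor that was filled
#'
#' Counts distinct (ky, kz, cardiac bin, resp bin, gd bin) cells touched by
#' imaging readouts, relative to \code{nKy * nKz * nCardiac * nResp * nGd}.
#' The echo and inversion-time dimensions are excluded from the denominator
#' because every readout acquires all echoes at a known time since
#' inversion.
#'
#' @param schedule a \linkS4class{SamplingSchedule}
#' @param bins a \linkS4class{BinConfig}
#' @param binning optional \linkS4class{BinningResult}; if missing, nominal
#'   bin assignments are computed from \code{motion} periods and sqrt-spaced
#'   gd bins
#' @param motion a \linkS4class{MotionModel} for the nominal assignment
#' @param tInjectOffsetS scan start relative to injection (s)
#' @return fraction in (0, 1]
#' @export
samplingFraction <- function(schedule, bins = binConfig(),
                             binning = NULL, motion = motionModel(),
                             tInjectOffsetS = 45) {
  ev <- schedule@events
  img <- !ev$isTraining
  if (!any(img)) stopf("empty schedule: no imaging readouts")
  if (is.null(binning)) {
    cb <- as.integer(floor(((ev$tMs / motion@rrMs) %% 1) * bins@nCardiac))
    disp <- (1 - cos(2 * pi * ((ev$tMs / motion@respMs) %% 1))) / 2
    rb <- as.integer(cut(disp, breaks = stats::quantile(disp[img],
                     probs = seq(0, 1, length.out = bins@nResp + 1)),
                     include.lowest = TRUE)) - 1L
    tInj <- ev$tMs / 1000 + tInjectOffsetS
    edges <- seq(sqrt(min(tInj)), sqrt(max(tInj)), length.out = bins@nGd + 1)^2
    gb <- pmin(pmax(findInterval(tInj, edges, rightmost.closed = TRUE), 1L),
               bins@nGd) - 1L
  } else {
    cb <- binning@cardiacBin; rb <- binning@respBin; gb <- binning@gdBin
  }
  p <- schedule@params
  kyi <- ev$ky[img] + p@nKy %/% 2
  kzi <- ev$kz[img] + p@nKz %/% 2
  cell <- ((as.numeric(gb[img]) * bins@nResp + rb[img]) * bins@nCardiac +
             cb[img]) * p@nKy * p@nKz + as.numeric(kzi) * p@nKy + kyi
  nFilled <- length(unique(cell))
  nFilled / (as.numeric(p@nKy) * p@nKz * bins@nCardiac * bins@nResp * bins@nGd)
}

#' Write / read a schedule as a columnar text table
#'
#' One row per readout event; this is also the documented import format for
#' real time-stamped raw data tables.
#'
#' @param schedule a \linkS4class{SamplingSchedule}
#' @param file path
#' @export
writeScheduleTable <- function(schedule, file) {
  utils::write.csv(schedule@events, file, row.names = FALSE)
  invisible(file)
}

#' @rdname writeScheduleTable
#' @param params the \linkS4class{SequenceParams} the table was built with
#' @export
readScheduleTable <- function(file, params = seqParams()) {
  ev <- utils::read.csv(file)
  ev$isTraining <- as.logical(ev$isTraining)
  new("SamplingSchedule", params = params, events = ev, seed = NA_real_)
}
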
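## Shared fixtures: tiny grids, manually enumerated full-sampling schedules,
## smooth random fields, and exact Tucker-model synthesis.

smallGrid <- c(32L, 32L, 4L)
smallVox <- c(270 / 32, 270 / 32, 6)

## schedule that samples every (ky, kz) exactly once (fully sampled frame)
makeFullSchedule <- function(nKy, nKz, nEcho = 1L, constantSeg = FALSE) {
  te <- if (nEcho == 1L) 2 else seq(1.5, 1.5 + 2 * (nEcho - 1), by = 2)
  p <- seqParams(nKy = nKy, nKz = nKz, teMs = te, durationS = 10,
                 trainingEvery = 1000000L)
  kk <- expand.grid(ky = seq(-nKy %/% 2, nKy %/% 2 - 1L),
                    kz = seq(-nKz %/% 2, nKz %/% 2 - 1L))
  n <- nrow(kk)
  seg <- if (constantSeg) rep(0L, n) else 0:(n - 1)
  ev <- data.frame(idx = 0:(n - 1), tTicks = (0:(n - 1)) * 132,
                   tMs = (0:(n - 1)) * 13.2, irBlock = 0L, seg = seg,
                   tauMs = 10 + seg * 13.2,
                   ky = kk$ky, kz = kk$kz, isTraining = FALSE)
  new("SamplingSchedule", params = p, events = ev, seed = 0)
}

## single-cell binning (all readouts in one temporal cell)
makeSingleBinning <- function(n) {
  new("BinningResult", cardiacBin = integer(n), respBin = integer(n),
      gdBin = integer(n), tauIndex = integer(n),
      bins = binConfig(1, 1, 1, 192), nTau = 1L,
      occupancy = array(n, c(1, 1, 1)), gdEdgesS = c(0, 1))
}

## rank-1 trivial subspace (phi = 1 over a single cell)
makeTrivialSubspace <- function() {
  ones <- matrix(1 + 0i, 1, 1)
  temporalSubspace(ones, ones, ones, ones, ones, array(1 + 0i, rep(1, 6)))
}

randomOrtho <- function(nr, nc) {
  qr.Q(qr(matrix(complex(real = stats::rnorm(nr * nc),
                         imaginary = stats::rnorm(nr * nc)), nr)))
}

## spatially smooth complex field (energy concentrated at low k)
smoothField <- function(g, sigmaKy = g[1] / 10, sigmaKz = 0.8) {
  nv <- prod(g)
  K <- array(complex(real = stats::rnorm(nv), imaginary = stats::rnorm(nv)), g)
  ky <- c(0:(g[1] %/% 2), (-(g[1] %/% 2) + 1):(-1))
  kyw <- exp(-(ky / sigmaKy)^2)
  kz <- c(0:(g[3] %/% 2), (-(g[3] %/% 2) + 1):(-1))
  kzw <- exp(-(kz / sigmaKz)^2)
  W <- outer(kyw, kyw)
  K <- K * array(rep(W, g[3]), g) * rep(kzw, each = g[1] * g[2])
  as.vector(stats::fft(K, inverse = TRUE) / nv)
}

## random binning over the default (24, 4, 16, 32) cells for a schedule
makeRandomBinning <- function(schedule, bins = binConfig(), seed = 1,
                              tInjectOffsetS = 45) {
  ev <- events(schedule)
  n <- nrow(ev)
  tInj <- ev$tMs / 1000 + tInjectOffsetS
  edges <- seq(sqrt(min(tInj)), sqrt(max(tInj)), length.out = bins@nGd + 1)^2
  withSeed <- lrtcmr:::withSeed
  withSeed(seed, {
    new("BinningResult",
        cardiacBin = as.integer(floor(stats::runif(n) * bins@nCardiac)),
        respBin = as.integer(floor(stats::runif(n) * bins@nResp)),
        gdBin = pmin(pmax(findInterval(tInj, edges, rightmost.closed = TRUE),
                          1L), bins@nGd) - 1L,
        tauIndex = as.integer(ev$seg %/% bins@tauDecim),
        bins = bins,
        nTau = as.integer((schedule@params@segmentsPerIR + bins@tauDecim - 1L)
                          %/% bins@tauDecim),
        occupancy = array(0L, c(bins@nCardiac, bins@nResp, bins@nGd)),
        gdEdgesS = edges)
  })
}

## small static phantom (no motion) for k-space identities
staticPhantomConfig <- function(grid = smallGrid,
                                voxelMm = c(270 / grid[1], 270 / grid[2], 6)) {
  cfg <- phantomConfig(grid = grid, voxelMm = voxelMm)
  cfg$motion <- motionModel(contractionFrac = 0, respAmpMm = 0)
  cfg
}

## tissues with frozen gadolinium (A = 0) for time-invariance tests
frozenGdTissues <- function() {
  lapply(defaultTissues(), function(tp)
    tissueProperties(tp@t1_0, tp@t2star, tp@pd, tp@r1, gdKinetics(0, 0, 1, 1)))
}

expectNear <- function(x, y, tol) testthat::expect_lt(abs(x - y), tol)
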
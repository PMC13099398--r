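test_that("fully sampled single-bin rank-1 solve equals the direct inverse DFT", {
  set.seed(42)
  g <- smallGrid
  nv <- prod(g)
  img <- array(complex(real = rnorm(nv), imaginary = rnorm(nv)), dim = g)
  sch <- makeFullSchedule(32L, 4L)
  sub1 <- makeTrivialSubspace()
  bin1 <- makeSingleBinning(nrow(events(sch)))
  coils <- makeCoils(g, smallVox, nCoils = 1)
  kd <- simulateFromSubspace(matrix(img, nv, 1), sub1, sch, bin1, coils,
                             nEcho = 1L)
  rec <- solveSpatial(kd, coils, sub1, bin1, sch, tol = 1e-10, maxIter = 50)
  expect_lt(lrtcmr:::nrmse(rec@Ux[, 1], as.vector(img)), 1e-6)
  ## direct inverse DFT oracle
  ev <- events(sch)
  K <- array(0 + 0i, g)
  for (i in seq_len(nrow(ev)))
    K[, lrtcmr:::kIndexToSlot(ev$ky[i], 32L),
      lrtcmr:::kIndexToSlot(ev$kz[i], 4L)] <- kd@samples[[1]][, i]
  di <- stats::fft(K, inverse = TRUE) / nv
  expect_lt(lrtcmr:::nrmse(rec@Ux[, 1], as.vector(di)), 1e-6)
})

test_that("reconstruction is linear in the data and shrinks with lambda", {
  set.seed(1)
  g <- smallGrid; nv <- prod(g)
  sch <- buildSchedule(seqParams(nKy = 32L, nKz = 4L, teMs = c(2, 4),
                                 durationS = 40), seed = 2)
  bins <- binConfig(4L, 2L, 3L, 48L)
  bin <- makeRandomBinning(sch, bins, seed = 3)
  ro <- randomOrtho
  L <- 4L
  sub <- temporalSubspace(ro(4, 2), ro(2, 2), ro(4, 2), ro(2, 2), ro(3, 2),
                          array(complex(real = rnorm(L * 32),
                                        imaginary = rnorm(L * 32)),
                                c(L, 2, 2, 2, 2, 2)))
  Ux <- vapply(1:L, function(i) smoothField(g), complex(nv))
  coils <- makeCoils(g, smallVox, nCoils = 2)
  kd <- simulateFromSubspace(Ux, sub, sch, bin, coils, nEcho = 2L)
  rec1 <- solveSpatial(kd, coils, sub, bin, sch, tol = 1e-9, maxIter = 40)
  kd3 <- kd
  kd3@samples <- lapply(kd@samples, function(D) 3 * D)
  rec3 <- solveSpatial(kd3, coils, sub, bin, sch, tol = 1e-9, maxIter = 40)
  expect_lt(lrtcmr:::nrmse(rec3@Ux, 3 * rec1@Ux), 1e-6)
  norms <- vapply(c(0, 1e-2, 1), function(lam) {
    r <- solveSpatial(kd, coils, sub, bin, sch, lambda = lam, tol = 1e-9,
                      maxIter = 40)
    sqrt(sum(Mod(r@Ux)^2))
  }, numeric(1))
  expect_true(all(diff(norms) < 0))
})

test_that("exact recovery and self-consistency on an undersampled exact-rank model", {
  set.seed(9)
  g <- smallGrid; nv <- prod(g)
  sch <- buildSchedule(seqParams(nKy = 32L, nKz = 4L, durationS = 250), seed = 4)
  bin <- makeRandomBinning(sch, binConfig(), seed = 5)
  L <- 6L
  sub <- temporalSubspace(randomOrtho(24, 4), randomOrtho(4, 2),
                          randomOrtho(32, 3), randomOrtho(6, 2),
                          randomOrtho(16, 3),
                          array(complex(real = rnorm(L * 144),
                                        imaginary = rnorm(L * 144)),
                                c(L, 4, 2, 3, 2, 3)))
  Ux <- vapply(1:L, function(i) smoothField(g), complex(nv))
  coils <- makeCoils(g, smallVox, nCoils = 1)
  kd <- simulateFromSubspace(Ux, sub, sch, bin, coils)
  frac <- samplingFraction(sch, binConfig(), binning = bin)
  expect_lt(frac, 0.15)                       # strongly undersampled
  rec <- solveSpatial(kd, coils, sub, bin, sch, tol = 1e-9, maxIter = 80)
  expect_lt(lrtcmr:::nrmse(rec@Ux, Ux), 1e-3)
  ## self-consistency: re-simulated samples reproduce the data
  kd2 <- simulateFromSubspace(rec@Ux, sub, sch, bin, coils)
  expect_lt(lrtcmr:::nrmse(kd2@samples[[1]], kd@samples[[1]]), 1e-3)
})

test_that("graceful degradation: error non-increasing with scan duration", {
  set.seed(13)
  g <- smallGrid; nv <- prod(g)
  L <- 4L
  sub <- temporalSubspace(randomOrtho(24, 2), randomOrtho(4, 2),
                          randomOrtho(32, 2), randomOrtho(6, 2),
                          randomOrtho(16, 2),
                          array(complex(real = rnorm(L * 32),
                                        imaginary = rnorm(L * 32)),
                                c(L, 2, 2, 2, 2, 2)))
  Ux <- vapply(1:L, function(i) smoothField(g), complex(nv))
  coils <- makeCoils(g, smallVox, nCoils = 1)
  errs <- vapply(c(60, 150, 400), function(dur) {
    sch <- buildSchedule(seqParams(nKy = 32L, nKz = 4L, durationS = dur),
                         seed = 6)
    bin <- makeRandomBinning(sch, binConfig(), seed = 7)
    kd <- simulateFromSubspace(Ux, sub, sch, bin, coils)
    rec <- solveSpatial(kd, coils, sub, bin, sch, tol = 1e-9, maxIter = 60)
    lrtcmr:::nrmse(rec@Ux, Ux)
  }, numeric(1))
  expect_true(all(diff(errs) < 1e-6))
})

test_that("subspace estimation recovers the true span under full coverage", {
  set.seed(11)
  g <- smallGrid; nv <- prod(g)
  sch <- buildSchedule(seqParams(nKy = 32L, nKz = 4L, durationS = 300), seed = 5)
  bins <- binConfig(4L, 2L, 3L, 48L)   # few cells: full training coverage
  bin <- makeRandomBinning(sch, bins, seed = 8)
  ranks <- c(2L, 2L, 2L, 2L, 2L); L <- 4L
  sub <- temporalSubspace(randomOrtho(4, 2), randomOrtho(2, 2),
                          randomOrtho(4, 2), randomOrtho(6, 2),
                          randomOrtho(3, 2),
                          array(complex(real = rnorm(L * 32),
                                        imaginary = rnorm(L * 32)),
                                c(L, ranks)))
  Ux <- matrix(complex(real = rnorm(nv * L), imaginary = rnorm(nv * L)), nv, L)
  coils <- makeCoils(g, smallVox, nCoils = 2)
  kd <- simulateFromSubspace(Ux, sub, sch, bin, coils)
  ## confirm full coverage of the small cell grid by training readouts
  tr <- events(sch)$isTraining
  cells <- paste(bin@cardiacBin[tr], bin@respBin[tr], bin@tauIndex[tr],
                 bin@gdBin[tr])
  expect_identical(length(unique(cells)), 4L * 2L * 4L * 3L)
  est <- estimateSubspaces(kd, sch, bin, ranks = ranks, jointRank = L,
                           maxSweeps = 50, tol = 1e-12)
  A <- t(Conj(sub@phi)); B <- t(Conj(est@phi))
  ang <- acos(pmin(svd(t(Conj(A)) %*% B)$d, 1))
  expect_lt(max(ang), 1e-6)
})

test_that("subspace estimation errors: spanning and rank bounds", {
  set.seed(3)
  g <- smallGrid
  sch <- buildSchedule(seqParams(nKy = 32L, nKz = 4L, durationS = 60), seed = 1)
  ## tauDecim 1: training only visits multiples of 6 -> tau not spanned
  bin1 <- makeRandomBinning(sch, binConfig(4L, 2L, 3L, 1L), seed = 2)
  coils <- makeCoils(g, smallVox, nCoils = 1)
  Ux <- matrix(smoothField(g), ncol = 1)
  onesE <- matrix(1 / sqrt(6) + 0i, 6, 1)
  ones1 <- matrix(1 + 0i, 1, 1)
  subE <- temporalSubspace(ones1, ones1, ones1, onesE, ones1,
                           array(1 + 0i, rep(1, 6)))
  kd <- simulateFromSubspace(Ux, subE, sch,
                             makeSingleBinning(nrow(events(sch))), coils,
                             nEcho = 6L)
  expect_error(estimateSubspaces(kd, sch, bin1, ranks = c(2L,2L,2L,2L,2L),
                                 jointRank = 2L),
               "under-determined subspace.*tau")
  bin2 <- makeRandomBinning(sch, binConfig(4L, 2L, 3L, 48L), seed = 2)
  expect_error(estimateSubspaces(kd, sch, bin2, ranks = c(2L, 2L, 9L, 2L, 2L),
                                 jointRank = 2L),
               "rank exceeds dimension")
})

test_that("composed frames match the dense factored product; tau lookup", {
  set.seed(21)
  L <- 3L
  sub <- temporalSubspace(randomOrtho(4, 2), randomOrtho(2, 1),
                          randomOrtho(3, 2), randomOrtho(2, 1),
                          randomOrtho(2, 1),
                          array(complex(real = rnorm(L * 4),
                                        imaginary = rnorm(L * 4)),
                                c(L, 2, 1, 2, 1, 1)))
  g <- c(4L, 4L, 2L)
  Ux <- matrix(complex(real = rnorm(32 * L), imaginary = rnorm(32 * L)),
               32, L)
  rec <- new("ReconImage6D", Ux = Ux, subspace = sub, grid = g,
             voxelMm = c(1, 1, 1), residuals = numeric(0))
  q <- expand.grid(c = 0:3, t = 0:2)
  frames <- composeImages(rec, cardiac = q$c, resp = 0, tau = q$t, echo = 0,
                          gd = 0, what = "complex")
  for (i in seq_len(nrow(q))) {
    cell <- 1 + q$c[i] + 4 * (0 + 2 * (q$t[i]))
    expect_equal(as.vector(frames[, , , i]),
                 as.vector(Ux %*% sub@phi[, cell]), tolerance = 1e-12)
  }
  expect_error(composeImages(rec, cardiac = 7), "out of range")
  ## inversion-time lookup: 396 ms lands on native segment 29
  expect_identical(tauIndexForMs(seqParams(), 396), 29L)
  expect_identical(tauIndexForMs(seqParams(), 396, decim = 6L), 4L)
})

test_that("rank-1 static data gives a temporally flat basis", {
  set.seed(2)
  g <- smallGrid
  sch <- buildSchedule(seqParams(nKy = 32L, nKz = 4L, durationS = 120), seed = 3)
  bins <- binConfig(4L, 2L, 3L, 48L)
  bin <- makeRandomBinning(sch, bins, seed = 4)
  Ux <- matrix(smoothField(g), ncol = 1)
  coils <- makeCoils(g, smallVox, nCoils = 1)
  subFlat <- local({
    ones <- function(n) matrix(1 / sqrt(n) + 0i, n, 1)
    temporalSubspace(ones(4), ones(2), ones(4), ones(6), ones(3),
                     array(1 + 0i, c(1, 1, 1, 1, 1, 1)))
  })
  kd <- simulateFromSubspace(Ux, subFlat, sch, bin, coils, nEcho = 6L)
  est <- estimateSubspaces(kd, sch, bin, ranks = c(1L, 1L, 1L, 1L, 1L),
                           jointRank = 1L, maxSweeps = 30)
  prof <- Mod(est@phi[1, ])
  expect_lt(max(prof) - min(prof), 1e-6 * max(prof))
})
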
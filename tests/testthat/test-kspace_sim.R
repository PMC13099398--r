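test_that("DC sample equals the sum of voxel signals (static, uniform coil)", {
  cfg <- staticPhantomConfig()
  ph <- buildPhantom(cfg, 0)
  p <- seqParams(nKy = 32L, nKz = 4L, durationS = 3)
  sch <- buildSchedule(p, seed = 1)
  coils <- makeCoils(smallGrid, smallVox, nCoils = 1)
  kd <- simulateFreeRunning(ph, sch, coils, noiseSigma = 0, seed = 0)
  ev <- events(sch)
  e1 <- which(ev$isTraining)[3]      # center line
  sig <- lrtcmr:::classSignalTables(ph, p, max(ev$irBlock) + 1L, 45)
  fr <- classFractions(ph, 0, dispMm = 0)
  tot <- 0
  for (nm in setdiff(names(tissueClassCodes), "background")) {
    w <- sig$base[[nm]][ev$irBlock[e1] + 1, ev$seg[e1] + 1] *
      sig$echoFac[[nm]][1]
    tot <- tot + w * sum(fr[[nm]]) * smallGrid[3]
  }
  dc <- kd@samples[[1]][1, e1]       # kx slot 1 = DC
  expect_equal(Re(dc), tot, tolerance = 1e-9 * abs(tot))
  expect_lt(abs(Im(dc)), 1e-9 * abs(tot))
})

test_that("static phantom with frozen gadolinium repeats lines across blocks", {
  cfg <- staticPhantomConfig()
  cfg$tissues <- frozenGdTissues()
  ph <- buildPhantom(cfg, 0)
  sch <- buildSchedule(seqParams(nKy = 32L, nKz = 4L, durationS = 8), seed = 1)
  coils <- makeCoils(smallGrid, smallVox, nCoils = 1)
  kd <- simulateFreeRunning(ph, sch, coils, 0, seed = 0)
  ev <- events(sch)
  tr <- which(ev$isTraining)
  same <- which(ev$seg[tr] == ev$seg[tr[1]] & ev$irBlock[tr] != ev$irBlock[tr[1]])
  expect_gt(length(same), 0)
  expect_identical(kd@samples[[1]][, tr[1]], kd@samples[[1]][, tr[same[1]]])
})

test_that("Parseval holds for a fully sampled single frame", {
  cfg <- staticPhantomConfig()
  cfg$tissues <- frozenGdTissues()
  ph <- buildPhantom(cfg, 0)
  sch <- makeFullSchedule(32L, 4L, constantSeg = TRUE)
  coils <- makeCoils(smallGrid, smallVox, nCoils = 1)
  kd <- simulateFreeRunning(ph, sch, coils, 0, seed = 0)
  kEnergy <- sum(Mod(kd@samples[[1]])^2) / prod(smallGrid)
  ## image energy computed independently from the fractional class maps
  ## (every line shares one image because the segment is held fixed)
  sig <- lrtcmr:::classSignalTables(ph, sch@params, 1L, 45)
  fr <- classFractions(ph, 0, dispMm = 0)
  img2d <- 0
  for (nm in setdiff(names(tissueClassCodes), "background")) {
    w <- sig$base[[nm]][1, 1] * sig$echoFac[[nm]][1]
    img2d <- img2d + w * fr[[nm]]
  }
  imgEnergy <- sum(img2d^2) * smallGrid[3]
  expect_equal(kEnergy, imgEnergy, tolerance = 1e-8)
})

test_that("conjugate symmetry for a real single-coil noise-free frame", {
  cfg <- staticPhantomConfig()
  cfg$tissues <- frozenGdTissues()
  ph <- buildPhantom(cfg, 0)
  sch <- makeFullSchedule(32L, 4L)
  sig <- lrtcmr:::classSignalTables(ph, sch@params, 1L, 45)
  ## verify on a single-segment frame so every line shares one image
  fr <- classFractions(ph, 0, dispMm = 0)
  img2d <- 0
  for (nm in setdiff(names(tissueClassCodes), "background"))
    img2d <- img2d + fr[[nm]] * sig$base[[nm]][1, 1] * sig$echoFac[[nm]][1]
  img <- array(rep(img2d, smallGrid[3]), smallGrid)
  Kf <- stats::fft(img)
  idx <- function(k, n) lrtcmr:::kIndexToSlot(k, n)
  for (ky in c(-3L, 5L, 11L)) for (kz in c(-1L, 1L)) {
    a <- Kf[idx(4L, 32L), idx(ky, 32L), idx(kz, 4L)]
    b <- Kf[idx(-4L, 32L), idx(-ky, 32L), idx(-kz, 4L)]
    expect_equal(a, Conj(b), tolerance = 1e-10)
  }
})

test_that("k-space scales linearly with proton density", {
  cfg <- staticPhantomConfig()
  ph <- buildPhantom(cfg, 0)
  cfg2 <- cfg
  cfg2$tissues <- lapply(cfg$tissues, function(tp)
    tissueProperties(tp@t1_0, tp@t2star, 3 * tp@pd, tp@r1, tp@kinetics))
  ph2 <- buildPhantom(cfg2, 0)
  sch <- buildSchedule(seqParams(nKy = 32L, nKz = 4L, durationS = 3), seed = 1)
  coils <- makeCoils(smallGrid, smallVox, nCoils = 2)
  kd <- simulateFreeRunning(ph, sch, coils, 0, seed = 0)
  kd3 <- simulateFreeRunning(ph2, sch, coils, 0, seed = 0)
  expect_lt(max(Mod(kd3@samples[[2]] - 3 * kd@samples[[2]])),
            1e-9 * max(Mod(kd@samples[[2]])))
})

test_that("image-domain noise matches the configured sigma through the transform", {
  ## fully sampled 192 x 192 single-slice frame, signal-free phantom
  g <- c(192L, 192L, 1L)
  cfg <- phantomConfig(grid = g, voxelMm = c(270 / 192, 270 / 192, 6))
  cfg$tissues <- lapply(cfg$tissues, function(tp)
    tissueProperties(tp@t1_0, tp@t2star, 0, tp@r1, tp@kinetics))  # PD = 0
  cfg$motion <- motionModel(contractionFrac = 0, respAmpMm = 0)
  ph <- buildPhantom(cfg, 0)
  sch <- makeFullSchedule(192L, 1L)
  coils <- makeCoils(g, cfg$voxelMm, nCoils = 1)
  sigma <- 2.5
  kd <- simulateFreeRunning(ph, sch, coils, noiseSigma = sigma, seed = 3)
  ev <- events(sch)
  K <- array(0 + 0i, g)
  for (e in seq_len(nrow(ev)))
    K[, lrtcmr:::kIndexToSlot(ev$ky[e], 192L), 1] <- kd@samples[[1]][, e]
  img <- stats::fft(K, inverse = TRUE) / prod(g)
  sdImg <- stats::sd(Re(img))
  expect_lt(abs(sdImg - sigma / sqrt(prod(g))) / (sigma / sqrt(prod(g))), 0.1)
})

test_that("conventional study: enhancement ordering and determinism", {
  g <- c(64L, 64L, 4L)
  ph <- buildPhantom(phantomConfig(grid = g, voxelMm = c(270/64, 270/64, 6)), 2)
  c1 <- simulateConventional(ph, noiseSigma = 0, seed = 0)
  c2 <- simulateConventional(ph, noiseSigma = 0, seed = 0)
  expect_identical(c1@lge, c2@lge)
  lab <- renderLabels(ph, 0, 0, dispMm = 0)
  ## EGE T1w: MVO hypointense relative to enhancing MI
  expect_lt(mean(c1@egeT1w[lab == 4L]), mean(c1@egeT1w[lab == 3L]))
  ## nulled LGE: remote myocardium dark, MI bright
  expect_lt(mean(c1@lge[lab == 2L]), 0.15 * mean(c1@lge[lab == 3L]))
  ## noisy simulation is seed-deterministic
  c3 <- simulateConventional(ph, noiseSigma = 1, seed = 5)
  c4 <- simulateConventional(ph, noiseSigma = 1, seed = 5)
  expect_identical(c3@cine, c4@cine)
})

test_that("grid mismatch raises an error", {
  ph <- buildPhantom(staticPhantomConfig(), 0)
  sch <- buildSchedule(seqParams(nKy = 64L, nKz = 4L, durationS = 2), 0)
  coils <- makeCoils(smallGrid, smallVox, 1)
  expect_error(simulateFreeRunning(ph, sch, coils), "grid mismatch")
})
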
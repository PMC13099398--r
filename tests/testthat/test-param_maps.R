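test_that("T2* fit recovers noiseless decays exactly and flags degenerates", {
  te <- c(1.47, 3.38, 5.39, 7.4, 9.41, 11.42)
  y <- 2.5 * exp(-outer(rep(1, 4), te) / c(10, 20, 30, 60))
  fit <- fitT2star(y, te)
  expect_lt(max(abs(fit$t2starMs - c(10, 20, 30, 60))), 1e-6)
  expect_true(all(fit$validMask))
  ## constant signal: clipped at the 200 ms bound, invalid
  fc <- fitT2star(matrix(1, 1, 6), te)
  expect_identical(fc$t2starMs[1], 200)
  expect_false(fc$validMask[1])
  ## all-nonpositive signal: invalid voxel
  fz <- fitT2star(matrix(0, 1, 6), te)
  expect_false(fz$validMask[1])
})

test_that("T2* monotone identifiability and Monte-Carlo recovery at SNR 30", {
  te <- c(1.47, 3.38, 5.39, 7.4, 9.41, 11.42)
  tTrue <- seq(8, 60, by = 4)
  est <- fitT2star(exp(-outer(1 / tTrue, te)), te)$t2starMs
  expect_true(all(diff(as.numeric(est)) > 0))
  ## IMH-like voxels, T2* = 10 ms, SNR 30 on the first echo
  lrtcmr:::withSeed(0, {
    s0 <- exp(-outer(rep(1 / 10, 100), te))
    noisy <- abs(s0 + matrix(rnorm(600, sd = s0[1, 1] / 30), 100))
    mc <- fitT2star(noisy, te)
    medErr <- stats::median(abs(mc$t2starMs - 10) / 10)
    expect_lt(medErr, 0.05)
  })
})

test_that("T1 fit inverts the IR-FLASH model (noise-free, within 3 percent)", {
  p <- seqParams()
  decim <- 6L
  tauIdx <- seq(0, 191, by = decim) + (decim - 1) / 2
  tauMs <- p@ti0Ms + tauIdx * p@trMs
  t1True <- c(300, 600, 900, 1200, 1800)
  tr <- irFlashTrain(t1True, 1, p)
  ## grouped-tau signals: average over each group of 6 segments
  grp <- rep(seq_len(32), each = 6)
  Y <- t(apply(abs(tr$s), 1, function(r) tapply(r, grp, mean)))
  fit <- fitT1IR(Y, tauMs, alphaDeg = 5, trMs = 13.2)
  expect_lt(max(abs(fit$t1Ms - t1True) / t1True), 0.03)
  expect_true(all(fit$validMask))
})

test_that("classic Look-Locker correction holds in its small-flip limit", {
  ## exact A - B exp(-tau/T1) with B = 2A (full recovery, perfect inversion)
  tau <- seq(50, 3000, length.out = 24)
  t1 <- 800
  y <- abs(1 - 2 * exp(-tau / t1))
  fit <- fitT1IR(matrix(y, 1), tau, alphaDeg = 1e-6, trMs = 13.2,
                 method = "lookLocker")
  expect_lt(abs(fit$t1Ms[1] - t1) / t1, 0.02)
  ## correction factor B/A - 1 = 1 here, so T1* = T1
  fitSeq <- fitT1IR(matrix(y, 1), tau, alphaDeg = 1e-6, trMs = 13.2)
  expect_lt(abs(fitSeq$t1Ms[1] - t1) / t1, 0.02)
})

test_that("post-contrast T1 recovery at SNR 30 and estimator bias/SD bounds", {
  p <- seqParams()
  tauMs <- p@ti0Ms + (seq(0, 191, by = 6) + 2.5) * p@trMs
  t1True <- 400
  tr <- irFlashTrain(t1True, 1, p)
  grp <- rep(seq_len(32), each = 6)
  clean <- as.numeric(tapply(abs(tr$s[1, ]), grp, mean))
  lrtcmr:::withSeed(0, {
    n <- 500
    Y <- abs(matrix(clean, n, 32, byrow = TRUE) +
               matrix(rnorm(n * 32, sd = max(clean) / 30), n))
    fit <- fitT1IR(Y, tauMs, alphaDeg = 5, trMs = 13.2)
    err <- (fit$t1Ms - t1True) / t1True
    expect_lt(stats::median(abs(err)), 0.05)
    expect_lt(abs(mean(err)), 0.02)
    expect_lt(stats::sd(err), 0.05)
  })
})

test_that("dictionary mode cross-checks the exponential-fit estimator", {
  p <- seqParams()
  tauMs <- p@ti0Ms + (seq(0, 191, by = 6) + 2.5) * p@trMs
  t1True <- c(350, 700, 1100, 1600)
  tr <- irFlashTrain(t1True, 1, p)
  grp <- rep(seq_len(32), each = 6)
  Y <- t(apply(abs(tr$s), 1, function(r) tapply(r, grp, mean)))
  fSeq <- fitT1IR(Y, tauMs, alphaDeg = 5, trMs = 13.2, method = "sequence")
  fDict <- fitT1IR(Y, tauMs, alphaDeg = 5, trMs = 13.2,
                   method = "dictionary", params = p)
  expect_lt(max(abs(fSeq$t1Ms - fDict$t1Ms) / fDict$t1Ms), 0.06)
})
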
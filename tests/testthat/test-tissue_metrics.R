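## quantification on conventional-study renderings of the default phantom
## (96 x 96 x 6 grid, the cohort resolution)
localPhantom <- function(seed = 3, ...) {
  buildPhantom(phantomConfig(grid = c(96L, 96L, 6L),
                             voxelMm = c(270 / 96, 270 / 96, 6), ...),
               seed = seed)
}

test_that("oracle ROIs equal the rendered labels", {
  ph <- localPhantom()
  roi <- segmentLV(mode = "oracle", phantom = ph)
  lab0 <- renderLabels(ph, 0, 0, dispMm = 0)
  labS <- renderLabels(ph, 0.35, 0, dispMm = 0)
  expect_identical(roi@ed$endo, lab0 == 1L)
  expect_identical(roi@ed$myo, array(lab0 %in% 2:5, dim(lab0)))
  expect_identical(roi@es$endo, labS == 1L)
  expect_true(all(lab0[roi@remote] == 2L))
  expect_false(any(roi@remote & (lab0 %in% 3:5)))
})

test_that("threshold segmentation matches the oracle on noise-free frames", {
  ph <- localPhantom()
  conv <- simulateConventional(ph, noiseSigma = 0, seed = 0)
  pick <- pickEdEs(conv@cine, c(270/96, 270/96, 6))
  roi <- segmentLV(conv@cine[, , , pick$ed], conv@cine[, , , pick$es],
                   mode = "threshold", lgeFrame = conv@lge,
                   voxelMm = c(270/96, 270/96, 6))
  roiO <- segmentLV(mode = "oracle", phantom = ph)
  expect_gte(diceCoef(roi@ed$endo, roiO@ed$endo), 0.95)
  expect_gte(diceCoef(roi@ed$myo, roiO@ed$myo), 0.85)
})

test_that("degenerate segmentation inputs raise errors", {
  ph <- localPhantom()
  g <- c(96L, 96L, 6L)
  ## no cavity: uniform frame has no blood pool at the seed
  expect_error(segmentLV(array(0.01, g), array(0.01, g), mode = "threshold",
                         voxelMm = c(270/96, 270/96, 6)),
               "segmentation error")
})

test_that("LVEF from ROI masks: definitional bounds and phantom recovery", {
  ph <- localPhantom()
  roiO <- segmentLV(mode = "oracle", phantom = ph)
  vox <- c(270/96, 270/96, 6)
  tru <- trueMetrics(ph, "discrete")
  lv <- computeLVEF(roiO, vox)
  expect_equal(lv$lvefPct, tru$lvefPct, tolerance = 1e-9)
  roiSame <- new("RoiSet", ed = roiO@ed, es = roiO@ed, remote = roiO@remote,
                 mode = "oracle")
  expect_equal(computeLVEF(roiSame, vox)$lvefPct, 0)
  esEmpty <- roiO@es
  esEmpty$endo <- esEmpty$endo & FALSE
  roiMax <- new("RoiSet", ed = roiO@ed, es = esEmpty, remote = roiO@remote,
                mode = "oracle")
  expect_equal(computeLVEF(roiMax, vox)$lvefPct, 100)
  roiNone <- new("RoiSet", ed = esEmpty, es = esEmpty, remote = roiO@remote,
                 mode = "oracle")
  expect_error(computeLVEF(roiNone, vox), "EDV is zero")
})

test_that("infarct sizing: uniform myocardium, threshold monotonicity, recovery", {
  ph <- localPhantom()
  vox <- c(270/96, 270/96, 6)
  roiO <- segmentLV(mode = "oracle", phantom = ph)
  ## uniform myocardium (lesion-free phantom): zero infarct, flagged fallback
  ph0 <- localPhantom(miSpanDeg = 0)
  conv0 <- simulateConventional(ph0, noiseSigma = 0, seed = 0)
  roi0 <- segmentLV(mode = "oracle", phantom = ph0)
  mi0 <- quantifyMI(conv0@lge, roi0, voxelMm = vox)
  expect_lt(mi0$miPctLv, 1)              # lesion-free: nothing detected
  ## a strictly constant volume exercises the zero-variance fallback
  miFlat <- quantifyMI(array(1, dim(conv0@lge)), roi0, voxelMm = vox)
  expect_true(miFlat$flagged)
  ## noisy default phantom: recovery within 2 points of LV
  sigma <- noiseSigmaForSnr(ph, seqParams(nKy = 96L, nKz = 6L), 30)
  conv <- simulateConventional(ph, noiseSigma = sigma, seed = 1)
  mi <- quantifyMI(conv@lge, roiO, voxelMm = vox)
  tru <- trueMetrics(ph, "discrete")
  expect_lt(abs(mi$miPctLv - tru$miPctLv), 2)
  ## monotone in the threshold multiplier
  m2 <- quantifyMI(conv@lge, roiO, nSd = 2, voxelMm = vox)$miPctLv
  m8 <- quantifyMI(conv@lge, roiO, nSd = 8, voxelMm = vox)$miPctLv
  expect_gte(m2, mi$miPctLv)
  expect_gte(mi$miPctLv, m8)
})

test_that("transmural extent: full and half thickness, chord refinement", {
  ## acquisition-matched grid: chord quantization error scales with voxel
  vox <- c(270/192, 270/192, 6)
  mk <- function(tm) buildPhantom(phantomConfig(miTransmural = tm,
                                                mvoSpanFrac = 0,
                                                mvoRadialFrac = 0,
                                                imhSpanFrac = 0,
                                                imhRadialFrac = 0), seed = 3)
  phFull <- mk(1)
  roiF <- segmentLV(mode = "oracle", phantom = phFull)
  labF <- renderLabels(phFull, 0, 0, dispMm = 0)
  trF <- computeTransmurality(array(labF %in% 3:5, dim(labF)), roiF,
                              voxelMm = vox)
  expect_gt(trF$transmuralityPct, 97)
  phHalf <- mk(0.5)
  roiH <- segmentLV(mode = "oracle", phantom = phHalf)
  labH <- renderLabels(phHalf, 0, 0, dispMm = 0)
  miH <- array(labH %in% 3:5, dim(labH))
  trH <- computeTransmurality(miH, roiH, voxelMm = vox)
  expect_lt(abs(trH$transmuralityPct - 50), 2)
  tr400 <- computeTransmurality(miH, roiH, chordsPerSlice = 400L,
                                voxelMm = vox)
  expect_lt(abs(trH$transmuralityPct - tr400$transmuralityPct), 1.5)
  ## empty infarct: flagged missing value
  trE <- computeTransmurality(miH & FALSE, roiH, voxelMm = vox)
  expect_true(is.na(trE$transmuralityPct))
})

test_that("MVO sizing: absence, early >= late, recovery", {
  vox <- c(270/96, 270/96, 6)
  ph <- localPhantom()
  sigma <- noiseSigmaForSnr(ph, seqParams(nKy = 96L, nKz = 6L), 30)
  conv <- simulateConventional(ph, noiseSigma = sigma, seed = 2)
  roiO <- segmentLV(mode = "oracle", phantom = ph)
  lab <- renderLabels(ph, 0, 0, dispMm = 0)
  miMask <- array(lab %in% 3:5, dim(lab))
  tru <- trueMetrics(ph, "discrete")
  late <- quantifyMVO(conv@lgeT1w, miMask, roiO)
  early <- quantifyMVO(conv@egeT1w, miMask, roiO)
  ## fill-in makes the late core smaller; fraction-weighted sizing can
  ## wobble by a fraction of a percent
  expect_gte(early$mvoPctLv, late$mvoPctLv - 0.75)
  expect_lt(abs(late$mvoPctLv - tru$mvoPctLv), 2)
  expect_true(all(miMask[late$mask]))           # nesting by construction
  ## no-MVO phantom
  phN <- localPhantom(mvoSpanFrac = 0, mvoRadialFrac = 0)
  convN <- simulateConventional(phN, noiseSigma = sigma, seed = 2)
  roiN <- segmentLV(mode = "oracle", phantom = phN)
  labN <- renderLabels(phN, 0, 0, dispMm = 0)
  lateN <- quantifyMVO(convN@lgeT1w, array(labN %in% 3:5, dim(labN)), roiN)
  expect_lt(lateN$mvoPctLv, 0.5)
})

test_that("IMH sizing: absence, rule stability, recovery within 1 point", {
  vox <- c(270/96, 270/96, 6)
  ph <- localPhantom()
  sigma <- noiseSigmaForSnr(ph, seqParams(nKy = 96L, nKz = 6L), 30)
  conv <- simulateConventional(ph, noiseSigma = sigma, seed = 4)
  roiO <- segmentLV(mode = "oracle", phantom = ph)
  lab <- renderLabels(ph, 0, 0, dispMm = 0)
  miMask <- array(lab %in% 3:5, dim(lab))
  myoIdx <- which(roiO@ed$myo)
  ef <- matrix(conv@t2starEchoes, prod(dim(lab)), length(conv@teMs))
  fit <- fitT2star(ef[myoIdx, ], conv@teMs)
  t2 <- array(NA_real_, dim(lab)); t2[myoIdx] <- fit$t2starMs
  tru <- trueMetrics(ph, "discrete")
  i20 <- quantifyIMH(t2, miMask, roiO, rule = "fixed20")
  i2sd <- quantifyIMH(t2, miMask, roiO, rule = "remote_minus_2sd")
  expect_lt(abs(i20$imhPctLv - tru$imhPctLv), 1)
  expect_gte(diceCoef(i20$mask, i2sd$mask), 0.8)
  expect_true(all(miMask[i20$mask]))
  phN <- localPhantom(imhSpanFrac = 0, imhRadialFrac = 0)
  convN <- simulateConventional(phN, noiseSigma = sigma, seed = 4)
  roiN <- segmentLV(mode = "oracle", phantom = phN)
  labN <- renderLabels(phN, 0, 0, dispMm = 0)
  efN <- matrix(convN@t2starEchoes, prod(dim(labN)), length(convN@teMs))
  myoN <- which(roiN@ed$myo)
  fitN <- fitT2star(efN[myoN, ], convN@teMs)
  t2N <- array(NA_real_, dim(labN)); t2N[myoN] <- fitN$t2starMs
  iN <- quantifyIMH(t2N, array(labN %in% 3:5, dim(labN)), roiN)
  expect_lt(iN$imhPctLv, 0.5)
})
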
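test_that("Bland-Altman identities and hand-computed values", {
  p <- pairedMeasurements(x = c(1, 2, 3, 4), y = c(1, 2, 3, 4))
  ba <- blandAltman(p)
  expect_identical(ba$bias, 0); expect_identical(ba$rpc, 0)
  p2 <- pairedMeasurements(x = c(0, 0), y = c(-1, 1))
  ba2 <- blandAltman(p2)
  expect_equal(ba2$bias, 0)
  expect_equal(ba2$sd, sqrt(2), tolerance = 1e-12)
  expect_equal(ba2$rpc, 1.96 * sqrt(2), tolerance = 1e-12)
  expect_equal(round(ba2$rpc, 4), 2.7719)
  ## LoA width identity on arbitrary data
  set.seed(1)
  p3 <- pairedMeasurements(rnorm(20), rnorm(20))
  ba3 <- blandAltman(p3)
  expect_equal(ba3$loaHigh - ba3$loaLow, 2 * ba3$rpc, tolerance = 1e-12)
  expect_error(blandAltman(pairedMeasurements(1, 1)))
})

test_that("printed LoA internally consistent with RPC = half-width, bias = midpoint", {
  ## published summaries: MI volume, early MVO, IMH
  mi <- rpcFromLoA(-2.9, 3.3)
  expect_equal(mi$rpc, 3.1, tolerance = 1e-9)
  expect_equal(mi$bias, 0.2, tolerance = 1e-9)
  mvoE <- rpcFromLoA(-6.6, 8.2)
  expect_equal(mvoE$rpc, 7.4, tolerance = 1e-9)
  expect_lt(abs(mvoE$bias - 0.82), 0.05)       # printed to 1 decimal in LoA
  imh <- rpcFromLoA(-1.5, 1.5)
  expect_equal(imh$rpc, 1.5, tolerance = 1e-9)
  expect_lt(abs(imh$bias - (-0.01)), 0.05)
})

test_that("linear regression: exact lines and lm cross-check", {
  x <- c(1, 2, 3, 5, 8)
  r <- linReg(x, 2 * x + 1)
  expect_equal(r$slope, 2, tolerance = 1e-12)
  expect_equal(r$intercept, 1, tolerance = 1e-12)
  expect_equal(r$r2, 1, tolerance = 1e-12)
  rneg <- linReg(x, -3 * x + 4)
  expect_equal(rneg$r2, 1, tolerance = 1e-12)
  expect_lt(rneg$slope, 0)
  set.seed(4)
  xx <- rnorm(24); yy <- 0.9 * xx + rnorm(24, sd = 0.3)
  mine <- linReg(xx, yy)
  ref <- stats::lm(yy ~ xx)
  expect_equal(mine$slope, unname(coef(ref)[2]), tolerance = 1e-12)
  expect_equal(mine$intercept, unname(coef(ref)[1]), tolerance = 1e-12)
  ci <- stats::confint(ref)
  expect_equal(mine$slopeCi, unname(ci[2, ]), tolerance = 1e-10)
  expect_equal(mine$interceptCi, unname(ci[1, ]), tolerance = 1e-10)
  expect_equal(mine$r2, summary(ref)$r.squared, tolerance = 1e-12)
  expect_error(linReg(rep(1, 5), rnorm(5)), "var")
})

test_that("paired t-test: degenerate and symmetric cases, t.test cross-check", {
  pz <- pairedMeasurements(x = c(1, 2, 3), y = c(3, 4, 5))
  rz <- pairedT(pz)
  expect_identical(rz$flag, "zero-variance")
  expect_true(is.na(rz$p))
  ps <- pairedMeasurements(x = rep(0, 4), y = c(1, -1, 2, -2))
  expect_equal(pairedT(ps)$t, 0, tolerance = 1e-12)
  set.seed(2)
  a <- rnorm(12); b <- a + rnorm(12, 0.3)
  mine <- pairedT(pairedMeasurements(a, b))
  ref <- stats::t.test(b, a, paired = TRUE)
  expect_equal(mine$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(mine$p, ref$p.value, tolerance = 1e-12)
})

test_that("AUC: separation, dual-algorithm identity, invariance, pROC oracle", {
  lab <- c(rep(0, 10), rep(1, 10))
  sc <- c(rnorm(10), rnorm(10) + 100)
  expect_identical(rocAuc(lab, sc, nBoot = 0)$auc, 1)
  set.seed(3)
  lab2 <- rbinom(60, 1, 0.4); sc2 <- rnorm(60) + lab2 * 0.8
  a1 <- rocAuc(lab2, sc2, nBoot = 0)$auc
  expect_equal(a1, rocCurve(lab2, sc2)$aucTrapezoid, tolerance = 1e-12)
  ## strictly monotone transform leaves the AUC unchanged
  expect_identical(a1, rocAuc(lab2, exp(sc2 / 2), nBoot = 0)$auc)
  ## independent oracle
  pr <- suppressMessages(pROC::auc(pROC::roc(lab2, sc2, quiet = TRUE)))
  expect_equal(a1, as.numeric(pr), tolerance = 1e-12)
  expect_error(rocAuc(rep(1, 5), rnorm(5), 0), "both classes")
  ## bootstrap CI is seeded and sane
  ci <- rocAuc(lab2, sc2, nBoot = 300, seed = 7)$ci
  ci2 <- rocAuc(lab2, sc2, nBoot = 300, seed = 7)$ci
  expect_identical(ci, ci2)
  expect_true(ci[1] <= a1 && a1 <= ci[2])
})

test_that("agreement table aggregates per metric", {
  set.seed(5)
  df <- do.call(rbind, lapply(c("lvef", "mi"), function(m)
    data.frame(subject = 1:10, metric = m,
               conventional = rnorm(10, 30, 5),
               proposed = rnorm(10, 30, 5))))
  tab <- agreementTable(df)
  expect_identical(nrow(tab), 2L)
  expect_true(all(c("bias", "rpc", "slope", "r2") %in% names(tab)))
  expect_equal(tab$loaHigh - tab$loaLow, 2 * tab$rpc, tolerance = 1e-12)
})

test_that("sector scores give clean detection data on oracle masks", {
  g <- c(48L, 48L, 4L)
  ph <- buildPhantom(phantomConfig(grid = g, voxelMm = c(270/48, 270/48, 6)), 1)
  lab <- renderLabels(ph, 0, 0, dispMm = 0)
  myo <- array(lab %in% 2:5, dim(lab))
  miTruth <- array(lab %in% 3:5, dim(lab))
  score <- array(0, g); score[miTruth] <- 1    # perfect enhancement contrast
  sd <- sectorScores(score, myo, miTruth, voxelMm = c(270/48, 270/48, 6))
  expect_true(all(c("label", "score") %in% names(sd)))
  expect_identical(rocAuc(sd$label, sd$score, nBoot = 0)$auc, 1)
})
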
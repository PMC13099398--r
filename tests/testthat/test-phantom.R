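test_that("default phantom matches the acquisition geometry", {
  ph <- buildPhantom(phantomConfig(), seed = 0)
  expect_identical(ph@grid[3], 14L)
  expect_equal(ph@voxelMm[3], 6)
  expect_equal(prod(ph@grid[1:2] * ph@voxelMm[1:2])^0.5, 270, tolerance = 1e-9)
})

test_that("wedge extent zero gives a lesion-free phantom; seeds only move the wedge", {
  ph0 <- buildPhantom(phantomConfig(miSpanDeg = 0), seed = 0)
  tm <- trueMetrics(ph0)
  expect_identical(tm$miPctLv, 0)
  expect_identical(tm$mvoPctLv, 0)
  lab <- renderLabels(ph0, 0.2, 0.3)
  expect_false(any(lab %in% 3:5))
  p1 <- buildPhantom(phantomConfig(), seed = 1)
  p2 <- buildPhantom(phantomConfig(), seed = 2)
  expect_false(isTRUE(all.equal(p1@miWedge$theta0, p2@miWedge$theta0)))
  expect_identical(p1@tissues, p2@tissues)
})

test_that("invalid geometry raises a configuration error", {
  expect_error(buildPhantom(phantomConfig(rEndoMm = 25, rEpiMm = 24)),
               "invalid geometry")
})

test_that("label rendering: partition, nesting, phase identities", {
  ph <- buildPhantom(phantomConfig(grid = c(96L, 96L, 4L),
                                   voxelMm = c(270 / 96, 270 / 96, 6)),
                     seed = 3)
  ## cores are strict subsets of the infarct wedge: removing them turns
  ## every core voxel into plain MI at every phase
  cfgNoCores <- phantomConfig(grid = c(96L, 96L, 4L),
                              voxelMm = c(270 / 96, 270 / 96, 6),
                              mvoSpanFrac = 0, mvoRadialFrac = 0,
                              imhSpanFrac = 0, imhRadialFrac = 0)
  phNoCores <- buildPhantom(cfgNoCores, seed = 3)
  for (pair in list(c(0, 0), c(0.35, 0.25), c(0.6, 0.8))) {
    lab <- renderLabels(ph, pair[1], pair[2])
    expect_true(all(lab %in% 0:6))               # exactly one label per voxel
    labWedge <- renderLabels(phNoCores, pair[1], pair[2])
    expect_true(all(labWedge[lab %in% 4:5] == 3L))
  }
  ## end-diastole: maximum blood radius equals rEndo within a voxel
  lab0 <- renderLabels(ph, 0, 0)
  xs <- lrtcmr:::axisCoords(96L, 270 / 96)
  R <- sqrt(outer(xs^2, xs^2, "+"))
  expect_lt(abs(max(R[lab0[, , 1] == 1L]) - ph@rEndoMm), 270 / 96)
  ## peak systole: strictly fewer blood voxels
  labS <- renderLabels(ph, 0.35, 0)
  expect_lt(sum(labS == 1L), sum(lab0 == 1L))
})

test_that("myocardial volume is conserved across the cycle within 2 percent", {
  ph <- buildPhantom(phantomConfig(), seed = 0)
  ## the analytic shell conserves its cross-section exactly
  areas <- vapply(seq(0, 0.95, by = 0.05), function(p) {
    re <- lrtcmr:::endoRadiusAt(ph, p)
    pi * (lrtcmr:::epiRadiusAt(ph, p)^2 - re^2)
  }, numeric(1))
  expect_lt(max(areas) - min(areas), 1e-9)
  ## voxel counting adds only discretization wiggle (fractions of a percent
  ## beyond the 2 percent incompressibility budget)
  counts <- vapply(seq(0, 0.95, by = 0.05), function(p)
    sum(renderLabels(ph, p, 0) %in% 2:5), numeric(1))
  expect_lt((max(counts) - min(counts)) / max(counts), 0.025)
})

test_that("respiration is a rigid translation (cross-correlation oracle)", {
  cfg <- phantomConfig()
  cfg$motion <- motionModel(respAmpMm = 10)
  ph <- buildPhantom(cfg, 0)
  m0 <- matrix(as.numeric(renderLabels(ph, 0, 0)[, , 1] %in% 1:5), 192)
  m5 <- matrix(as.numeric(renderLabels(ph, 0, 0.5)[, , 1] %in% 1:5), 192)
  cc <- Re(stats::fft(stats::fft(m0) * Conj(stats::fft(m5)), inverse = TRUE))
  sh <- which(cc == max(cc), arr.ind = TRUE)[1, ] - 1
  shx <- ifelse(sh[1] > 96, sh[1] - 192, sh[1])
  expect_lt(abs(shx - (-10 / (270 / 192))), 1)   # one-voxel rounding
  expect_equal(unname(sh[2]), 0)                  # no in-plane y shift
})

test_that("property maps follow the kinetics", {
  ph <- buildPhantom(phantomConfig(grid = c(64L, 64L, 2L),
                                   voxelMm = c(270 / 64, 270 / 64, 6)), 1)
  mp0 <- renderPropertyMaps(ph, 0, 0, 0)
  lut <- vapply(names(tissueClassCodes), function(nm) ph@tissues[[nm]]@t1_0,
                numeric(1))
  expect_equal(mp0$t1Ms, array(lut[mp0$labels + 1L], dim(mp0$labels)),
               tolerance = 1e-12)
  mp120 <- renderPropertyMaps(ph, 120, 0, 0)
  remote <- mp120$labels == 2L
  mvo <- mp120$labels == 4L
  expect_lt(max(mp120$t1Ms[remote]), ph@tissues$myocardium@t1_0)
  expect_equal(mean(mp120$t1Ms[mvo]), ph@tissues$mvo@t1_0, tolerance = 1e-6)
  for (t in c(0, 120, 900)) {
    mp <- renderPropertyMaps(ph, t, 0, 0)
    expect_lt(max(mp$t2starMs[mp$labels == 5L]),
              min(mp$t2starMs[mp$labels == 2L]))
  }
})

test_that("analytic truth: definitional cases", {
  cfg <- phantomConfig()
  cfg$motion <- motionModel(contractionFrac = 1 - sqrt(0.5))
  tm <- trueMetrics(buildPhantom(cfg, 0))
  expect_equal(tm$lvefPct, 50, tolerance = 1e-9)
  expect_equal(tm$esvMl, tm$edvMl / 2, tolerance = 1e-9)
  cfg2 <- phantomConfig(miSpanDeg = 60, miTransmural = 1,
                        mvoSpanFrac = 0, mvoRadialFrac = 0,
                        imhSpanFrac = 0, imhRadialFrac = 0)
  tm2 <- trueMetrics(buildPhantom(cfg2, 0))
  expect_equal(tm2$miPctLv, 100 * 60 / 360, tolerance = 1e-9)
  expect_equal(tm2$transmuralityPct, 100)
  cfg3 <- phantomConfig()
  cfg3$motion <- motionModel(contractionFrac = 0)
  expect_equal(trueMetrics(buildPhantom(cfg3, 0))$lvefPct, 0)
})

test_that("analytic and voxel-counted truth agree at the acquisition grid", {
  ph <- buildPhantom(phantomConfig(), seed = 0)
  ta <- trueMetrics(ph, "analytic")
  td <- trueMetrics(ph, "discrete")
  expect_lt(abs(ta$lvefPct - td$lvefPct), 1)
  expect_lt(abs(ta$miPctLv - td$miPctLv), 1)
  expect_lt(abs(ta$mvoPctLv - td$mvoPctLv), 0.5)
  expect_lt(abs(ta$imhPctLv - td$imhPctLv), 0.5)
  expect_lt(abs(ta$edvMl - td$edvMl) / ta$edvMl, 0.02)
})

test_that("cohort generator jitters lesion sizes deterministically", {
  coh1 <- phantomCohort(4, phantomConfig(grid = c(48L, 48L, 4L),
                                         voxelMm = c(270/48, 270/48, 6)),
                        seed = 9)
  coh2 <- phantomCohort(4, phantomConfig(grid = c(48L, 48L, 4L),
                                         voxelMm = c(270/48, 270/48, 6)),
                        seed = 9)
  mi1 <- vapply(coh1, function(p) trueMetrics(p)$miPctLv, numeric(1))
  mi2 <- vapply(coh2, function(p) trueMetrics(p)$miPctLv, numeric(1))
  expect_identical(mi1, mi2)
  expect_gt(stats::sd(mi1), 1)       # a real spread of infarct sizes
  for (p in coh1) {
    tm <- trueMetrics(p)
    expect_lte(tm$mvoPctLv, tm$miPctLv)
    expect_lte(tm$imhPctLv, tm$miPctLv)
  }
})
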
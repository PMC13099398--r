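## Deformable digital left-ventricle phantom. Geometry is an analytic
## annulus stack so that every ground-truth metric has a closed form; the
## infarct is an angular wedge with nested MVO and IMH cores defined in
## wall-fraction coordinates, which makes the nesting and the myocardial
## volume conservation exact at every cardiac phase.

#' Tissue class codes
#'
#' Integer voxel labels: 0 background, 1 blood, 2 remote myocardium, 3 MI
#' (necrotic, enhancing), 4 MVO, 5 IMH, 6 liver (static reference).
#' @export
tissueClassCodes <- c(background = 0L, blood = 1L, myocardium = 2L,
                      mi = 3L, mvo = 4L, imh = 5L, liver = 6L)

#' @rdname MotionModel-class
#' @param rrMs,respMs,contractionFrac,respAmpMm see slots
#' @export
motionModel <- function(rrMs = 603, respMs = 4000, contractionFrac = 0.18,
                        respAmpMm = 8) {
  ## wall thickening implied by cross-section conservation at peak systole
  ## (for the default 15/24 mm radii); stored for reference
  new("MotionModel", rrMs = rrMs, respMs = respMs,
      contractionFrac = contractionFrac,
      wallThickeningFrac = NA_real_, respAmpMm = respAmpMm)
}

#' Default tissue property table (3 T)
#'
#' Native relaxation values and gadolinium kinetics for the seven tissue
#' classes. Values are literature-typical at 3 T; all are user-overridable.
#' MVO arrival is strongly delayed relative to remote and infarcted
#' myocardium (hypo-enhancement early, slow fill-in late).
#' @return named list of \linkS4class{TissueProperties}
#' @export
defaultTissues <- function() {
  ## peak concentrations scale with the accessible extracellular space:
  ## remote myocardium (ECV ~ 0.3) sees far less gadolinium than blood,
  ## necrotic infarct (expanded interstitium) enhances slowly and retains
  ## contrast, MVO receives contrast only by delayed diffusion
  noGd <- gdKinetics(0, 0, 1, 1)
  list(
    background  = tissueProperties(1000, 50, 0.0, 0, noGd),
    blood       = tissueProperties(1800, 25, 1.0, 4.5,
                                   gdKinetics(0.9, 5, 12, 900)),
    myocardium  = tissueProperties(1200, 30, 0.8, 4.5,
                                   gdKinetics(0.35, 10, 25, 700)),
    mi          = tissueProperties(1400, 28, 0.8, 4.5,
                                   gdKinetics(0.7, 15, 90, 3000)),
    mvo         = tissueProperties(1400, 25, 0.8, 4.5,
                                   gdKinetics(0.5, 400, 3000, 5000)),
    imh         = tissueProperties(1400, 10, 0.8, 4.5,
                                   gdKinetics(0.7, 15, 90, 3000)),
    liver       = tissueProperties(800, 20, 0.9, 4.5,
                                   gdKinetics(0.4, 12, 40, 1200)))
}

#' Phantom configuration
#'
#' Parameter set consumed by \code{\link{buildPhantom}}. The default grid is
#' the acquisition-matched 192 x 192 x 14 at 270 mm field of view and 6 mm
#' partitions; radii approximate a 25 kg canine left ventricle. Default
#' wedge extent and core fractions give an infarct of about 16 percent of
#' LV myocardium with about 6 percent MVO and 4.5 percent IMH.
#'
#' @param grid,voxelMm,lvCenterMm,rEndoMm,rEpiMm geometry
#' @param miSpanDeg,miTransmural infarct wedge angular span (degrees) and
#'   transmural depth fraction
#' @param mvoSpanFrac,mvoRadialFrac MVO core: fraction of the wedge span and
#'   of the transmural depth (band starts at the endocardium)
#' @param imhSpanFrac,imhRadialFrac IMH band, radially outside the MVO band
#' @param liverCenterMm,liverHalfSizeMm static reference block
#' @param tissues named \linkS4class{TissueProperties} list
#' @param motion a \linkS4class{MotionModel}
#' @param jitterWedgeCenter randomize the wedge center angle from the build
#'   seed (subject-to-subject variation)
#' @return a plain list; pass to \code{\link{buildPhantom}}
#' @export
phantomConfig <- function(grid = c(192L, 192L, 14L),
                          voxelMm = c(270 / grid[1], 270 / grid[2], 6),
                          lvCenterMm = c(0, 0, 0),
                          rEndoMm = 15, rEpiMm = 24,
                          miSpanDeg = 100, miTransmural = 0.65,
                          mvoSpanFrac = 0.7, mvoRadialFrac = 0.55,
                          imhSpanFrac = 0.55, imhRadialFrac = 0.45,
                          liverCenterMm = c(55, 55),
                          liverHalfSizeMm = c(30, 25),
                          tissues = defaultTissues(),
                          motion = motionModel(),
                          jitterWedgeCenter = TRUE) {
  as.list(environment())
}

#' Build a digital phantom
#'
#' Deterministic for fixed (config, seed): the seed only drives the wedge
#' placement jitter, emulating subject-to-subject infarct location.
#'
#' @param config list from \code{\link{phantomConfig}}
#' @param seed integer
#' @return a \linkS4class{DigitalPhantom}
#' @examples
#' ph <- buildPhantom(phantomConfig(), seed = 0)
#' @export
buildPhantom <- function(config = phantomConfig(), seed = 0) {
  cfg <- config
  if (cfg$rEndoMm >= cfg$rEpiMm)
    stopf("invalid geometry: rEndoMm (%.1f) must be < rEpiMm (%.1f)",
          cfg$rEndoMm, cfg$rEpiMm)
  center <- if (isTRUE(cfg$jitterWedgeCenter))
    withSeed(seed, stats::runif(1, 0, 360)) else 0
  theta0 <- center - cfg$miSpanDeg / 2
  kMvo <- cfg$tissues$mvo@kinetics
  if (cfg$miTransmural > 0 && cfg$mvoRadialFrac > 0 && kMvo@A > 0 &&
      kMvo@tArr <= max(cfg$tissues$myocardium@kinetics@tArr,
                       cfg$tissues$mi@kinetics@tArr))
    stopf("MVO arrival must be later than remote and MI arrival")
  new("DigitalPhantom",
      grid = as.integer(cfg$grid), voxelMm = cfg$voxelMm,
      lvCenterMm = cfg$lvCenterMm,
      rEndoMm = cfg$rEndoMm, rEpiMm = cfg$rEpiMm,
      miWedge = list(theta0 = theta0 %% 360,
                     theta1 = (theta0 + cfg$miSpanDeg) %% 360,
                     span = cfg$miSpanDeg, transmural = cfg$miTransmural),
      mvoCore = list(spanFrac = cfg$mvoSpanFrac,
                     radialFrac = cfg$mvoRadialFrac),
      imhCore = list(spanFrac = cfg$imhSpanFrac,
                     radialFrac = cfg$imhRadialFrac),
      liver = list(centerMm = cfg$liverCenterMm,
                   halfSizeMm = cfg$liverHalfSizeMm),
      tissues = cfg$tissues, motion = cfg$motion, seed = seed)
}

#' Synthetic cohort generator
#'
#' Emits \code{n} phantoms ("subjects") with jittered infarct, MVO, IMH and
#' contraction parameters, mirroring the between-subject spread of a small
#' pre-clinical cohort so that regression and Bland-Altman comparisons see a
#' range of lesion sizes.
#'
#' @param n number of subjects
#' @param config base configuration (grid, tissues, motion are shared)
#' @param seed cohort seed
#' @return list of \linkS4class{DigitalPhantom}
#' @export
phantomCohort <- function(n = 12, config = phantomConfig(), seed = 0) {
  draws <- withSeed(seed, {
    lapply(seq_len(n), function(i) {
      mvoR <- stats::runif(1, 0.3, 0.7)
      list(miSpanDeg = stats::runif(1, 60, 140),
           miTransmural = stats::runif(1, 0.45, 0.85),
           mvoSpanFrac = stats::runif(1, 0.5, 0.85),
           mvoRadialFrac = mvoR,
           imhSpanFrac = stats::runif(1, 0.4, 0.7),
           imhRadialFrac = stats::runif(1, 0.25, min(0.55, 1 - mvoR)),
           contractionFrac = stats::runif(1, 0.14, 0.22))
    })
  })
  lapply(seq_len(n), function(i) {
    cfg <- config
    d <- draws[[i]]
    cfg[c("miSpanDeg", "miTransmural", "mvoSpanFrac", "mvoRadialFrac",
          "imhSpanFrac", "imhRadialFrac")] <-
      d[c("miSpanDeg", "miTransmural", "mvoSpanFrac", "mvoRadialFrac",
          "imhSpanFrac", "imhRadialFrac")]
    cfg$motion <- motionModel(rrMs = cfg$motion@rrMs,
                              respMs = cfg$motion@respMs,
                              contractionFrac = d$contractionFrac,
                              respAmpMm = cfg$motion@respAmpMm)
    buildPhantom(cfg, seed = deriveSeed(seed, i))
  })
}

## systolic raised-cosine contraction window: 0 at end-diastole (phase 0),
## 1 at peak systole (phase 0.35), occupying 35 percent of the cycle
contractionWindow <- function(phase, peak = 0.35, width = 0.35) {
  d <- abs(phase - peak)
  d <- pmin(d, 1 - d)                 # circular distance
  ifelse(d < width / 2, cos(pi * d / width)^2, 0)
}

endoRadiusAt <- function(phantom, cardiacPhase) {
  phantom@rEndoMm *
    (1 - phantom@motion@contractionFrac * contractionWindow(cardiacPhase))
}

## epicardial radius from exact conservation of myocardial cross-section
epiRadiusAt <- function(phantom, cardiacPhase) {
  re <- endoRadiusAt(phantom, cardiacPhase)
  sqrt(re^2 + phantom@rEpiMm^2 - phantom@rEndoMm^2)
}

respDisplacementAt <- function(phantom, respPhase) {
  phantom@motion@respAmpMm * (1 - cos(2 * pi * respPhase)) / 2
}

## signed angular difference in degrees, result in [-180, 180)
angDiff <- function(theta, ref) ((theta - ref + 180) %% 360) - 180

## 2-D heart label field at arbitrary coordinate grids (heart-centered,
## respiration already subtracted); liver handled separately
heartLabels2d <- function(phantom, cardiacPhase, X, Y) {
  r <- sqrt(X^2 + Y^2)
  theta <- (atan2(Y, X) * 180 / pi) %% 360
  rEndo <- endoRadiusAt(phantom, cardiacPhase)
  rEpi <- epiRadiusAt(phantom, cardiacPhase)
  wall <- rEpi - rEndo
  lab <- matrix(tissueClassCodes[["background"]], nrow(X), ncol(X))
  lab[r < rEndo] <- tissueClassCodes[["blood"]]
  inWall <- r >= rEndo & r < rEpi
  lab[inWall] <- tissueClassCodes[["myocardium"]]
  w <- phantom@miWedge
  if (w$span > 0 && w$transmural > 0) {
    ctr <- (w$theta0 + w$span / 2) %% 360
    fr <- (r - rEndo) / wall                       # wall-fraction coordinate
    inAng <- abs(angDiff(theta, ctr)) <= w$span / 2
    mi <- inWall & inAng & fr < w$transmural
    lab[mi] <- tissueClassCodes[["mi"]]
    mvoOut <- phantom@mvoCore$radialFrac * w$transmural
    mvoAng <- abs(angDiff(theta, ctr)) <= phantom@mvoCore$spanFrac * w$span / 2
    mvo <- mi & mvoAng & fr < mvoOut
    lab[mvo] <- tissueClassCodes[["mvo"]]
    imhOut <- mvoOut + phantom@imhCore$radialFrac * w$transmural
    imhAng <- abs(angDiff(theta, ctr)) <= phantom@imhCore$spanFrac * w$span / 2
    imh <- mi & imhAng & fr >= mvoOut & fr < imhOut
    lab[imh] <- tissueClassCodes[["imh"]]
  }
  lab
}

#' Render the tissue-label volume at a motion state
#'
#' Cardiac deformation is applied analytically to the radii (volume of the
#' myocardial shell conserved exactly); respiration translates the heart
#' rigidly along the first axis. The liver block is static.
#'
#' @param phantom a \linkS4class{DigitalPhantom}
#' @param cardiacPhase,respPhase fractions in [0, 1)
#' @param dispMm optional explicit respiratory displacement (mm), overriding
#'   the phase-derived value
#' @return integer array (nx, ny, nz) of \code{\link{tissueClassCodes}}
#' @export
renderLabels <- function(phantom, cardiacPhase = 0, respPhase = 0,
                         dispMm = NULL) {
  stopifnot(cardiacPhase >= 0, cardiacPhase < 1, respPhase >= 0, respPhase < 1)
  g <- phantom@grid; vx <- phantom@voxelMm
  if (is.null(dispMm)) dispMm <- respDisplacementAt(phantom, respPhase)
  xs <- axisCoords(g[1], vx[1]) - phantom@lvCenterMm[1] - dispMm
  ys <- axisCoords(g[2], vx[2]) - phantom@lvCenterMm[2]
  X <- matrix(xs, g[1], g[2])
  Y <- matrix(ys, g[1], g[2], byrow = TRUE)
  lab <- heartLabels2d(phantom, cardiacPhase, X, Y)
  ## static liver block (lab coordinates, no respiratory shift)
  lx <- axisCoords(g[1], vx[1]) - phantom@liver$centerMm[1]
  ly <- axisCoords(g[2], vx[2]) - phantom@liver$centerMm[2]
  LX <- matrix(lx, g[1], g[2]); LY <- matrix(ly, g[1], g[2], byrow = TRUE)
  inLiver <- abs(LX) <= phantom@liver$halfSizeMm[1] &
    abs(LY) <= phantom@liver$halfSizeMm[2] &
    lab == tissueClassCodes[["background"]]
  lab[inLiver] <- tissueClassCodes[["liver"]]
  array(rep(as.integer(lab), g[3]), dim = g)
}

#' Fractional tissue occupancy at a motion state (partial volume)
#'
#' In-plane supersampling of the analytic geometry: each voxel's class
#' fractions are the area fractions of the tissue classes it covers, so
#' boundary voxels mix signals the way finite MRI voxels do. Fractions sum
#' to one per voxel.
#'
#' @inheritParams renderLabels
#' @param superSample in-plane supersampling factor per axis (default 3)
#' @return named list of (nx, ny) fraction matrices, one per tissue class
#'   (slices are identical; see \code{\link{renderLabels}})
#' @export
classFractions <- function(phantom, cardiacPhase = 0, respPhase = 0,
                           dispMm = NULL, superSample = 3L) {
  g <- phantom@grid; vx <- phantom@voxelMm
  if (is.null(dispMm)) dispMm <- respDisplacementAt(phantom, respPhase)
  offs <- ((seq_len(superSample) - (superSample + 1) / 2) / superSample)
  frac <- setNames(rep(list(matrix(0, g[1], g[2])),
                       length(tissueClassCodes)), names(tissueClassCodes))
  xs0 <- axisCoords(g[1], vx[1])
  ys0 <- axisCoords(g[2], vx[2])
  for (ox in offs) for (oy in offs) {
    xs <- xs0 + ox * vx[1] - phantom@lvCenterMm[1] - dispMm
    ys <- ys0 + oy * vx[2] - phantom@lvCenterMm[2]
    X <- matrix(xs, g[1], g[2]); Y <- matrix(ys, g[1], g[2], byrow = TRUE)
    lab <- heartLabels2d(phantom, cardiacPhase, X, Y)
    lx <- xs0 + ox * vx[1] - phantom@liver$centerMm[1]
    ly <- ys0 + oy * vx[2] - phantom@liver$centerMm[2]
    LX <- matrix(lx, g[1], g[2]); LY <- matrix(ly, g[1], g[2], byrow = TRUE)
    inLiver <- abs(LX) <= phantom@liver$halfSizeMm[1] &
      abs(LY) <= phantom@liver$halfSizeMm[2] &
      lab == tissueClassCodes[["background"]]
    lab[inLiver] <- tissueClassCodes[["liver"]]
    for (nm in names(tissueClassCodes))
      frac[[nm]] <- frac[[nm]] + (lab == tissueClassCodes[[nm]])
  }
  lapply(frac, function(f) f / superSample^2)
}

#' Render proton-density, T1(t) and T2* volumes
#'
#' T1 is shortened per voxel by the tissue's gadolinium concentration at
#' \code{tS} through \code{\link{effectiveT1}}; maps are co-registered with
#' \code{\link{renderLabels}} at the same motion state.
#'
#' @inheritParams renderLabels
#' @param tS time since injection (s)
#' @return list(pd, t1Ms, t2starMs, labels)
#' @export
renderPropertyMaps <- function(phantom, tS, cardiacPhase = 0, respPhase = 0,
                               dispMm = NULL) {
  stopifnot(tS >= 0)
  lab <- renderLabels(phantom, cardiacPhase, respPhase, dispMm)
  ts <- phantom@tissues
  ord <- names(tissueClassCodes)
  pdLut <- vapply(ord, function(nm) ts[[nm]]@pd, numeric(1))
  t2Lut <- vapply(ord, function(nm) ts[[nm]]@t2star, numeric(1))
  t1Lut <- vapply(ord, function(nm) {
    effectiveT1(ts[[nm]]@t1_0, ts[[nm]]@r1,
                gdConcentration(tS, ts[[nm]]@kinetics))
  }, numeric(1))
  code <- as.integer(lab) + 1L
  list(pd = array(pdLut[code], dim = dim(lab)),
       t1Ms = array(t1Lut[code], dim = dim(lab)),
       t2starMs = array(t2Lut[code], dim = dim(lab)),
       labels = lab)
}

#' Ground-truth tissue metrics
#'
#' Closed-form metrics from the analytic geometry (\code{mode = "analytic"})
#' or voxel-counted metrics on labels rendered at end-diastole and
#' end-systole at the phantom grid (\code{mode = "discrete"}, the truth at
#' acquisition resolution).
#'
#' @param phantom a \linkS4class{DigitalPhantom}
#' @param mode "analytic" or "discrete"
#' @return list with lvefPct, edvMl, esvMl, miPctLv, transmuralityPct,
#'   mvoPctLv, imhPctLv
#' @export
trueMetrics <- function(phantom, mode = c("analytic", "discrete")) {
  mode <- match.arg(mode)
  w <- phantom@miWedge
  f <- w$transmural
  if (mode == "analytic") {
    H <- phantom@grid[3] * phantom@voxelMm[3]
    c0 <- phantom@motion@contractionFrac
    edv <- pi * phantom@rEndoMm^2 * H / 1000
    esv <- pi * (phantom@rEndoMm * (1 - c0))^2 * H / 1000
    wall <- phantom@rEpiMm - phantom@rEndoMm
    myoA <- pi * (phantom@rEpiMm^2 - phantom@rEndoMm^2)
    ring <- function(frOut, frIn = 0) {
      pi * ((phantom@rEndoMm + frOut * wall)^2 -
              (phantom@rEndoMm + frIn * wall)^2)
    }
    mvoOut <- phantom@mvoCore$radialFrac * f
    imhOut <- mvoOut + phantom@imhCore$radialFrac * f
    miA <- w$span / 360 * ring(f)
    mvoA <- phantom@mvoCore$spanFrac * w$span / 360 * ring(mvoOut)
    imhA <- phantom@imhCore$spanFrac * w$span / 360 * ring(imhOut, mvoOut)
    list(lvefPct = 100 * (1 - (1 - c0)^2),
         edvMl = edv, esvMl = esv,
         miPctLv = 100 * miA / myoA,
         transmuralityPct = 100 * f * (w$span > 0),
         mvoPctLv = 100 * mvoA / myoA,
         imhPctLv = 100 * imhA / myoA)
  } else {
    vox <- prod(phantom@voxelMm) / 1000   # mL
    ed <- renderLabels(phantom, 0, 0)
    es <- renderLabels(phantom, 0.35, 0)
    cnt <- function(lab, codes) sum(lab %in% codes)
    edv <- cnt(ed, 1L) * vox
    esv <- cnt(es, 1L) * vox
    myo <- cnt(ed, 2:5)
    list(lvefPct = if (edv > 0) 100 * (edv - esv) / edv else NA_real_,
         edvMl = edv, esvMl = esv,
         miPctLv = 100 * cnt(ed, 3:5) / myo,
         transmuralityPct = 100 * f * (w$span > 0),
         mvoPctLv = 100 * cnt(ed, 4L) / myo,
         imhPctLv = 100 * cnt(ed, 5L) / myo)
  }
}

setMethod("show", "DigitalPhantom", function(object) {
  tm <- trueMetrics(object)
  cat(sprintf("DigitalPhantom %dx%dx%d @ %.2fx%.2fx%.1f mm\n",
              object@grid[1], object@grid[2], object@grid[3],
              object@voxelMm[1], object@voxelMm[2], object@voxelMm[3]))
  cat(sprintf("  LV radii %.1f/%.1f mm; MI wedge %.0f deg, transmural %.0f%%\n",
              object@rEndoMm, object@rEpiMm, object@miWedge$span,
              100 * object@miWedge$transmural))
  cat(sprintf("  truth: LVEF %.1f%%, MI %.1f%%, MVO %.1f%%, IMH %.1f%% of LV\n",
              tm$lvefPct, tm$miPctLv, tm$mvoPctLv, tm$imhPctLv))
})
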
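## Central S4 classes. Validity checks enforce the geometric and physical
## invariants; accessors live next to the modules that use them.

#' Gadolinium wash-in/wash-out kinetics
#'
#' Bolus kinetics for one tissue compartment. Concentration follows
#' \code{A * (1 - exp(-(t - tArr)/tauIn)) * exp(-(t - tArr)/tauOut)} for
#' \code{t >= tArr} and 0 before arrival, so it is continuous at arrival.
#'
#' @slot A peak concentration scale (mM)
#' @slot tArr arrival delay after injection (s)
#' @slot tauIn wash-in time constant (s)
#' @slot tauOut wash-out time constant (s)
#' @export
setClass("GdKinetics",
  representation(A = "numeric", tArr = "numeric",
                 tauIn = "numeric", tauOut = "numeric"),
  validity = function(object) {
    v <- c(object@A, object@tArr, object@tauIn, object@tauOut)
    if (any(!is.finite(v)) || any(v < 0)) return("kinetic parameters must be finite and >= 0")
    TRUE
  })

#' @rdname GdKinetics-class
#' @param A,tArr,tauIn,tauOut see slots
#' @export
gdKinetics <- function(A, tArr, tauIn, tauOut) {
  new("GdKinetics", A = A, tArr = tArr, tauIn = tauIn, tauOut = tauOut)
}

#' Relaxation and density properties of one tissue compartment
#'
#' @slot t1_0 native longitudinal relaxation time (ms)
#' @slot t2star effective transverse relaxation time (ms)
#' @slot pd proton density (arbitrary units, >= 0)
#' @slot r1 gadolinium relaxivity (1/(mM*s))
#' @slot kinetics a \linkS4class{GdKinetics}
#' @export
setClass("TissueProperties",
  representation(t1_0 = "numeric", t2star = "numeric", pd = "numeric",
                 r1 = "numeric", kinetics = "GdKinetics"),
  validity = function(object) {
    if (object@t1_0 <= 0) return("t1_0 must be > 0")
    if (object@t2star <= 0) return("t2star must be > 0")
    if (object@pd < 0) return("pd must be >= 0")
    if (object@r1 < 0) return("r1 must be >= 0")
    TRUE
  })

#' @rdname TissueProperties-class
#' @param t1_0,t2star,pd,r1,kinetics see slots
#' @export
tissueProperties <- function(t1_0, t2star, pd, r1, kinetics) {
  new("TissueProperties", t1_0 = t1_0, t2star = t2star, pd = pd, r1 = r1,
      kinetics = kinetics)
}

#' Cardiac and respiratory motion model
#'
#' Cardiac contraction is a raised-cosine systolic window applied to the
#' endocardial radius with myocardial cross-section conserved; respiration is
#' a rigid translation of the heart along the first (head-foot) axis.
#'
#' @slot rrMs cardiac period (ms)
#' @slot respMs respiratory period (ms)
#' @slot contractionFrac peak systolic endocardial radius reduction, in [0, 0.6]
#' @slot wallThickeningFrac peak systolic wall thickening fraction (derived
#'   from volume conservation at construction; informational)
#' @slot respAmpMm head-foot translation amplitude (mm)
#' @export
setClass("MotionModel",
  representation(rrMs = "numeric", respMs = "numeric",
                 contractionFrac = "numeric", wallThickeningFrac = "numeric",
                 respAmpMm = "numeric"),
  validity = function(object) {
    if (object@rrMs <= 0 || object@respMs <= 0) return("periods must be > 0")
    if (object@contractionFrac < 0 || object@contractionFrac > 0.6)
      return("contractionFrac must lie in [0, 0.6]")
    TRUE
  })

#' Deformable digital left-ventricle phantom
#'
#' An analytic annulus stack: blood pool of radius \code{rEndoMm} inside a
#' myocardial annulus out to \code{rEpiMm}, with an infarct wedge holding
#' nested microvascular-obstruction (MVO) and intramyocardial-hemorrhage
#' (IMH) cores, plus a static liver reference block. Tissue classes are coded
#' 0 background, 1 blood, 2 remote myocardium, 3 MI, 4 MVO, 5 IMH, 6 liver.
#'
#' @slot grid voxel counts (nx, ny, nz)
#' @slot voxelMm voxel size (dx, dy, dz) in mm
#' @slot lvCenterMm LV axis position (mm, centered coordinates)
#' @slot rEndoMm,rEpiMm end-diastolic endo/epicardial radii (mm)
#' @slot miWedge list(theta0, theta1, transmural): angular extent (deg) and
#'   transmural fraction in (0, 1]
#' @slot mvoCore list(spanFrac, radialFrac): MVO sub-wedge, as fractions of
#'   the MI wedge span and of its transmural depth (band starts at the
#'   endocardium)
#' @slot imhCore list(spanFrac, radialFrac): IMH band, radially just outside
#'   the MVO band, inside the MI wedge
#' @slot liver list(centerMm, halfSizeMm) static reference block
#' @slot tissues named list of \linkS4class{TissueProperties} with names
#'   background, blood, myocardium, mi, mvo, imh, liver
#' @slot motion a \linkS4class{MotionModel}
#' @slot seed integer used for subject-level jitter
#' @export
setClass("DigitalPhantom",
  representation(grid = "integer", voxelMm = "numeric", lvCenterMm = "numeric",
                 rEndoMm = "numeric", rEpiMm = "numeric", miWedge = "list",
                 mvoCore = "list", imhCore = "list", liver = "list",
                 tissues = "list", motion = "MotionModel", seed = "numeric"),
  validity = function(object) {
    if (length(object@grid) != 3L) return("grid must have length 3")
    if (object@rEndoMm >= object@rEpiMm) return("invalid geometry: rEndoMm must be < rEpiMm")
    w <- object@miWedge
    if (w$transmural < 0 || w$transmural > 1) return("transmural fraction must lie in (0,1]")
    need <- c("background", "blood", "myocardium", "mi", "mvo", "imh", "liver")
    if (!all(need %in% names(object@tissues))) return("tissues must name all 7 classes")
    f <- w$transmural
    if (f > 0) {
      mvoOut <- object@mvoCore$radialFrac
      imhOut <- mvoOut + object@imhCore$radialFrac
      if (mvoOut > 1 + 1e-9 || imhOut > 1 + 1e-9)
        return("mvo/imh radial bands must lie inside the MI transmural depth")
    }
    TRUE
  })

#' Free-running IR-mGRE sequence parameters
#'
#' Defaults reproduce the proposed protocol: TR 13.2 ms, six echoes
#' 1.47-11.42 ms, 5 degree excitation, 10 ms from inversion to the first
#' excitation, 192 segments per inversion block, one training (k-space
#' center) line every 6 readouts, 860 s total, 192 x 14 phase encodes over a
#' 270 mm field of view with 6 mm partitions.
#'
#' @slot trMs repetition time (ms)
#' @slot teMs echo times (ms), strictly increasing, max < trMs
#' @slot flipDeg excitation flip angle (degrees)
#' @slot ti0Ms delay from inversion to first excitation (ms)
#' @slot segmentsPerIR excitations per inversion block
#' @slot trainingEvery one training readout per this many readouts
#' @slot durationS total scan duration (s)
#' @slot nKy,nKz phase-encode counts
#' @slot fovMm in-plane field of view (mm, length 2)
#' @slot sliceMm partition thickness (mm)
#' @slot invEfficiency inversion efficiency in (0, 1]
#' @slot deadTimeMs extra delay appended to each inversion block (ms)
#' @export
setClass("SequenceParams",
  representation(trMs = "numeric", teMs = "numeric", flipDeg = "numeric",
                 ti0Ms = "numeric", segmentsPerIR = "integer",
                 trainingEvery = "integer", durationS = "numeric",
                 nKy = "integer", nKz = "integer", fovMm = "numeric",
                 sliceMm = "numeric", invEfficiency = "numeric",
                 deadTimeMs = "numeric"),
  validity = function(object) {
    if (any(diff(object@teMs) <= 0)) return("teMs must be strictly increasing")
    if (max(object@teMs) >= object@trMs) return("max(teMs) must be < trMs")
    if (object@segmentsPerIR < 1L) return("segmentsPerIR must be >= 1")
    if (object@trainingEvery < 2L) return("trainingEvery must be >= 2")
    if (object@invEfficiency <= 0 || object@invEfficiency > 1)
      return("invEfficiency must lie in (0, 1]")
    TRUE
  })

#' Time-ordered free-running sampling schedule
#'
#' One row of \code{events} per readout: global index \code{idx} (0-based),
#' excitation time \code{tMs}, inversion-block index \code{irBlock}, segment
#' \code{seg} within the block, time since inversion \code{tauMs}, integer
#' phase encodes \code{ky}, \code{kz} in [-N/2, N/2-1], and \code{isTraining}.
#' Event times are exact on a 0.1 ms tick grid (\code{tTicks}).
#'
#' @slot params a \linkS4class{SequenceParams}
#' @slot events data.frame of readout events, strictly ordered in time
#' @slot seed integer seed that generated the Gaussian phase-encode draws
#' @export
setClass("SamplingSchedule",
  representation(params = "SequenceParams", events = "data.frame",
                 seed = "numeric"),
  validity = function(object) {
    ev <- object@events
    need <- c("idx", "tMs", "irBlock", "seg", "tauMs", "ky", "kz", "isTraining")
    if (!all(need %in% names(ev))) return("events missing required columns")
    if (is.unsorted(ev$tMs, strictly = TRUE)) return("events must be strictly ordered in time")
    TRUE
  })

#' Coil sensitivity set
#'
#' @slot maps complex array (nx, ny, nz, nCoils); smooth Gaussian-lobe
#'   profiles normalized to unit sum-of-squares magnitude at the heart center
#' @export
setClass("CoilSet", representation(maps = "array"),
  validity = function(object) {
    if (length(dim(object@maps)) != 4L) return("maps must be (nx, ny, nz, nCoils)")
    if (any(!is.finite(Mod(object@maps)))) return("maps must be finite")
    TRUE
  })

#' Simulated multi-coil, multi-echo k-space data
#'
#' Samples are stored per coil as a complex matrix with one column per
#' readout event and rows running over (kx within echo, echo), matching the
#' event order of the generating \linkS4class{SamplingSchedule}.
#'
#' @slot samples list (length nCoils) of complex matrices (nKx*nEcho, nEvents)
#' @slot nKx readout points per line
#' @slot nEcho echoes per readout
#' @slot noiseSigma per-sample complex noise SD used in simulation
#' @slot truth list of per-event ground-truth motion/contrast state (cardiac
#'   phase, respiratory displacement, Gd time), for navigator bypass mode
#' @export
setClass("KSpaceData",
  representation(samples = "list", nKx = "integer", nEcho = "integer",
                 noiseSigma = "numeric", truth = "list"),
  validity = function(object) {
    if (length(object@samples) < 1L) return("need at least one coil")
    d <- dim(object@samples[[1]])
    if (d[1] != object@nKx * object@nEcho) return("sample rows inconsistent with nKx*nEcho")
    TRUE
  })

#' Idealized conventional (gated, breath-held) comparator study
#'
#' @slot cine magnitude cine frames (nx, ny, nz, nPhases), breath-held at
#'   end-expiration
#' @slot t2starEchoes pre-contrast multi-echo magnitude volumes (nx,ny,nz,nTE)
#' @slot teMs conventional echo times (ms)
#' @slot ege,lge inversion-prepared magnitude volumes with remote myocardium
#'   nulled, at the early and late enhancement times
#' @slot egeT1w,lgeT1w T1-weighted spoiled-GRE enhancement volumes at the
#'   same times (inputs for MVO sizing)
#' @slot times list(egeS, lgeS, tiEgeMs, tiLgeMs)
#' @export
setClass("ConventionalStudy",
  representation(cine = "array", t2starEchoes = "array", teMs = "numeric",
                 ege = "array", lge = "array", egeT1w = "array",
                 lgeT1w = "array", times = "list"))

#' Bin configuration for the five temporal dimensions
#'
#' @slot nCardiac cardiac phases (default 24)
#' @slot nResp respiratory positions (default 4)
#' @slot nGd gadolinium-dynamics bins (default 16)
#' @slot tauDecim inversion-time grouping: 1 keeps all segments as distinct
#'   tau points, k groups k consecutive segments (default 6, the training
#'   interleave, giving 32 tau points per block)
#' @export
setClass("BinConfig",
  representation(nCardiac = "integer", nResp = "integer", nGd = "integer",
                 tauDecim = "integer"),
  validity = function(object) {
    if (any(c(object@nCardiac, object@nResp, object@nGd, object@tauDecim) < 1L))
      return("all bin counts must be >= 1")
    TRUE
  })

#' Self-navigation signals
#'
#' @slot cardiacWave,respWave band-passed waveforms at the training-readout rate
#' @slot trainTimesMs training readout times
#' @slot rrMsEst,respMsEst estimated cardiac / respiratory periods (ms)
#' @slot cardiacPhase per-readout cardiac phase in [0, 1)
#' @slot respAmp per-readout respiratory amplitude (arbitrary units; signed)
#' @slot triggersMs detected cardiac trigger times
#' @slot mode "selfnav" or "bypass"
#' @export
setClass("NavSignals",
  representation(cardiacWave = "numeric", respWave = "numeric",
                 trainTimesMs = "numeric", rrMsEst = "numeric",
                 respMsEst = "numeric", cardiacPhase = "numeric",
                 respAmp = "numeric", triggersMs = "numeric", mode = "character"),
  validity = function(object) {
    p <- object@cardiacPhase
    if (length(p) && (min(p) < 0 || max(p) >= 1)) return("phases must lie in [0,1)")
    TRUE
  })

#' Per-readout bin assignment
#'
#' @slot cardiacBin,respBin,gdBin,tauIndex 0-based integer assignment per event
#' @slot bins the \linkS4class{BinConfig} used
#' @slot nTau number of tau points after grouping
#' @slot occupancy counts over (cardiac, resp, gd) cells
#' @slot gdEdgesS gd bin boundaries (injection-relative seconds)
#' @export
setClass("BinningResult",
  representation(cardiacBin = "integer", respBin = "integer", gdBin = "integer",
                 tauIndex = "integer", bins = "BinConfig", nTau = "integer",
                 occupancy = "array", gdEdgesS = "numeric"))

#' Factored temporal subspace of the 6-D low-rank tensor model
#'
#' Orthonormal per-dimension factor bases from the training tensor plus the
#' combined (joint) temporal basis \code{phi} mapping the spatial
#' coefficients to any (cardiac, resp, tau, echo, gd) cell.
#'
#' @slot Uc,Ur,Utau,Ue,Ug orthonormal-column factor bases
#' @slot core Tucker core coefficient tensor (feature x temporal ranks)
#' @slot Uf feature-mode basis (k-space-profile space; diagnostic)
#' @slot phi joint temporal basis, L x (nCardiac*nResp*nTau*nEcho*nGd),
#'   orthonormal rows; column order has cardiac fastest, then resp, tau,
#'   echo, gd
#' @slot dims named integer vector of temporal dimension sizes
#' @slot singularValues singular values of the joint (spatial-unfolding)
#'   decomposition, for rank diagnostics
#' @export
setClass("TemporalSubspace",
  representation(Uc = "matrix", Ur = "matrix", Utau = "matrix", Ue = "matrix",
                 Ug = "matrix", core = "array", Uf = "matrix", phi = "matrix",
                 dims = "integer", singularValues = "numeric"),
  validity = function(object) {
    gram <- function(U) max(Mod(crossprod(Conj(U), U) - diag(ncol(U))))
    for (U in list(object@Uc, object@Ur, object@Utau, object@Ue, object@Ug))
      if (gram(U) > 1e-8) return("factor bases must have orthonormal columns")
    TRUE
  })

#' Reconstructed 6-D image set (factored form)
#'
#' Lazy container: image at any (cardiac, resp, tau, echo, gd) cell is
#' \code{Ux \%*\% phi[, cell]} reshaped to the grid. Use
#' \code{\link{composeImages}} to materialize frames.
#'
#' @slot Ux complex spatial factor (nVoxels x L)
#' @slot subspace the \linkS4class{TemporalSubspace}
#' @slot grid image grid (nx, ny, nz)
#' @slot voxelMm voxel size
#' @slot residuals conjugate-gradient residual history
#' @export
setClass("ReconImage6D",
  representation(Ux = "matrix", subspace = "TemporalSubspace",
                 grid = "integer", voxelMm = "numeric", residuals = "numeric"))

#' Voxel-wise parameter maps
#'
#' @slot t1Ms,t2starMs,m0 parameter volumes
#' @slot fitError per-voxel residual norm
#' @slot validMask FALSE wherever bounds were hit or the fit failed
#' @export
setClass("ParameterMaps",
  representation(t1Ms = "array", t2starMs = "array", m0 = "array",
                 fitError = "array", validMask = "array"))

#' Region-of-interest set for quantification
#'
#' @slot ed,es lists with logical masks endo, epi, myo at end-diastole /
#'   end-systole
#' @slot remote logical mask of reference (remote) myocardium
#' @slot mode "oracle" or "threshold"
#' @export
setClass("RoiSet", representation(ed = "list", es = "list",
                                  remote = "array", mode = "character"))

#' Agreement statistics between two measurement arms
#'
#' Bland-Altman bias and limits of agreement with the reproducibility
#' coefficient RPC = 1.96 * SD of paired differences (so LoA = bias +/- RPC),
#' ordinary least-squares regression with 95 percent t-based confidence
#' intervals, and the paired t-test. Differences are proposed - conventional.
#'
#' @slot n number of pairs
#' @slot bias,loaLow,loaHigh,rpc Bland-Altman summary
#' @slot slope,intercept,slopeCi,interceptCi,r2,pRegression regression summary
#' @slot tPaired,dfPaired,pPairedT paired t-test
#' @slot flags character vector of degeneracy flags
#' @export
setClass("AgreementStats",
  representation(n = "integer", bias = "numeric", loaLow = "numeric",
                 loaHigh = "numeric", rpc = "numeric", slope = "numeric",
                 intercept = "numeric", slopeCi = "numeric",
                 interceptCi = "numeric", r2 = "numeric",
                 pRegression = "numeric", tPaired = "numeric",
                 dfPaired = "numeric", pPairedT = "numeric",
                 flags = "character"))
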
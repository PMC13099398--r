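## Closed-form IR-prepared spoiled-gradient-echo (FLASH) signal evolution.
##
## Perfect spoiling is assumed (no transverse coherence history), which is
## benign at the 5 degree excitation used here. Within an inversion block the
## longitudinal magnetization just before excitation n obeys the affine
## recursion L[n+1] = M0*(1 - E1) + a*L[n] with E1 = exp(-TR/T1) and
## a = E1*cos(alpha); across blocks the magnetization recovers over the tail
## of the block (plus any dead time), is inverted with efficiency eta, and
## relaxes for ti0 before the first excitation. The block-to-block map is
## affine, so its unique fixed point gives the cyclic steady state in closed
## form.

#' IR-FLASH segment train in cyclic steady state
#'
#' Longitudinal magnetization just before each excitation of an
#' inversion-recovery FLASH block, and the corresponding transverse signal
#' \code{s = L * sin(alpha)}, either in closed form (the cyclic steady
#' state) or by explicit block-by-block Bloch recursion.
#'
#' @param t1Ms longitudinal relaxation time(s), ms; vectorized
#' @param m0 equilibrium magnetization (single value)
#' @param params a \linkS4class{SequenceParams}
#' @param nBlocksToSteady \code{"closed-form"} (default) or an integer number
#'   of blocks to iterate explicitly from thermal equilibrium
#' @return list with matrices \code{L} and \code{s} (length(t1Ms) x
#'   segmentsPerIR), and vectors \code{L1} (pre-excitation-1 value),
#'   \code{LpreInv} (value just before the inversion pulse), \code{Mss}
#'   (within-block FLASH steady state)
#' @examples
#' p <- seqParams()
#' tr <- irFlashTrain(1200, 1, p)
#' @export
irFlashTrain <- function(t1Ms, m0 = 1, params = seqParams(),
                         nBlocksToSteady = "closed-form") {
  stopifnot(all(t1Ms > 0), params@flipDeg > 0, params@flipDeg < 90)
  alpha <- params@flipDeg * pi / 180
  ca <- cos(alpha); sa <- sin(alpha)
  tr <- params@trMs; ti0 <- params@ti0Ms
  nSeg <- params@segmentsPerIR
  eta <- params@invEfficiency
  ex <- function(dt) ifelse(is.finite(t1Ms), exp(-dt / t1Ms), 1)
  E1 <- ex(tr)
  a <- E1 * ca
  rec <- m0 * (1 - E1)                      # per-TR recovery increment
  Mss <- ifelse(abs(1 - a) < 1e-300, m0, rec / (1 - a))
  # tail from last excitation to the next inversion
  tTail <- tr + params@deadTimeMs - ti0
  if (tTail < 0) stopf("ti0Ms exceeds trMs + deadTimeMs: no room before next inversion")
  Etail <- ex(tTail); Eti0 <- ex(ti0)
  aN1 <- a^(nSeg - 1)

  blockMap <- function(L1) {
    LN <- Mss + (L1 - Mss) * aN1          # before excitation nSeg
    LpreInv <- m0 + (LN * ca - m0) * Etail
    Lpost <- -eta * LpreInv
    list(L1 = m0 + (Lpost - m0) * Eti0, LpreInv = LpreInv)
  }

  if (identical(nBlocksToSteady, "closed-form")) {
    # compose the affine map L1 -> c0 + c1*L1 and take its fixed point
    z <- blockMap(rep(0, length(t1Ms)))
    o <- blockMap(rep(1, length(t1Ms)))
    c0 <- z$L1; c1 <- o$L1 - z$L1
    L1 <- c0 / (1 - c1)
  } else {
    L1 <- rep(m0, length(t1Ms))
    for (b in seq_len(nBlocksToSteady)) L1 <- blockMap(L1)$L1
  }
  n <- seq_len(nSeg)
  L <- matrix(Mss, length(t1Ms), nSeg) +
    matrix(L1 - Mss, length(t1Ms), nSeg) *
      exp(outer(log(pmax(a, 1e-300)), n - 1))
  list(L = L, s = L * sa, L1 = L1, LpreInv = blockMap(L1)$LpreInv,
       Mss = Mss, E1 = E1, a = a)
}

#' T2*-weighted echo signal
#'
#' @param s transverse signal at echo time zero
#' @param t2starMs effective transverse relaxation time (ms)
#' @param teMs echo time(s), ms
#' @return \code{s * exp(-teMs / t2starMs)}; if \code{teMs} has length > 1
#'   and \code{s} is a vector, an outer product (length(s) x length(teMs))
#' @export
echoSignal <- function(s, t2starMs, teMs) {
  stopifnot(all(t2starMs > 0), all(teMs >= 0))
  if (length(teMs) > 1L && length(s) > 1L)
    return(outer(s, exp(-teMs / t2starMs)))
  s * exp(-teMs / t2starMs)
}

#' Gadolinium concentration after bolus injection
#'
#' Zero before arrival, then a wash-in saturation multiplied by exponential
#' wash-out; continuous at arrival.
#'
#' @param tS time since injection (s), vectorized
#' @param k a \linkS4class{GdKinetics}
#' @return concentration in mM
#' @export
gdConcentration <- function(tS, k) {
  stopifnot(all(tS >= 0))
  dt <- tS - k@tArr
  out <- numeric(length(tS))
  pos <- dt > 0
  if (any(pos))
    out[pos] <- k@A * (1 - exp(-dt[pos] / k@tauIn)) * exp(-dt[pos] / k@tauOut)
  out
}

#' Gadolinium-shortened T1 via the fast-exchange relaxivity model
#'
#' \code{1/T1 = 1/T1_0 + r1 * C}, with unit care: T1 in ms, r1 in
#' 1/(mM*s), so the concentration term is scaled by 1e-3.
#'
#' @param t1_0Ms native T1 (ms)
#' @param r1 relaxivity, 1/(mM*s)
#' @param C concentration (mM), vectorized
#' @return T1 in ms; equals \code{t1_0Ms} when \code{C = 0}
#' @export
effectiveT1 <- function(t1_0Ms, r1, C) {
  stopifnot(all(t1_0Ms > 0), all(r1 >= 0), all(C >= 0))
  1 / (1 / t1_0Ms + r1 * C * 1e-3)
}
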
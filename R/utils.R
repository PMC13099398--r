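#' @import methods
#' @importFrom stats fft rnorm runif quantile median sd var qt pt coef lm
#'   approx optimize setNames
#' @importFrom utils head tail write.csv read.csv
NULL

## Centered k-space index convention: integer phase-encode indices live in
## [-N/2, N/2 - 1]; slot i of R's fft() output holds wavenumber (i-1) mod N.
kIndexToSlot <- function(k, n) ((k %% n) + 1L)

fft3 <- function(x) stats::fft(x)
ifft3 <- function(x) stats::fft(x, inverse = TRUE) / length(x)

## Run expr with a temporarily-seeded RNG, restoring the caller's stream.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

## Derive a stage seed from a master seed; kept below 2^31.
deriveSeed <- function(seed, stage) {
  (as.numeric(seed) * 1000003 + stage * 7919) %% 2147483647
}

complexNoise <- function(n, sigma) {
  complex(real = stats::rnorm(n, sd = sigma),
          imaginary = stats::rnorm(n, sd = sigma))
}

nrmse <- function(x, ref) {
  sqrt(sum(Mod(x - ref)^2)) / sqrt(sum(Mod(ref)^2))
}

## Voxel-center coordinates (mm), centered on the grid midpoint.
axisCoords <- function(n, d) (seq_len(n) - 1 - n / 2) * d

stopf <- function(...) stop(sprintf(...), call. = FALSE)

## Connected-component labels of a 3-D logical array (26-connectivity by
## default, so diagonal contact keeps thin oblique structures together).
## Iterative label propagation on the voxel lattice; fast enough for the
## myocardial masks this package labels (thousands of voxels).
labelComponents3d <- function(mask, connectivity = 26L) {
  dims <- dim(mask)
  nvox <- prod(dims)
  lab <- integer(nvox)
  lab[mask] <- seq_len(sum(mask))  # provisional labels
  idx <- which(mask)
  if (length(idx) == 0L) return(array(0L, dims))
  ci <- arrayInd(idx, dims)
  offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  offs <- offs[!(offs$dx == 0 & offs$dy == 0 & offs$dz == 0), ]
  if (connectivity == 6L)
    offs <- offs[abs(offs$dx) + abs(offs$dy) + abs(offs$dz) == 1L, ]
  nb <- list()
  strides <- c(1L, dims[1], dims[1] * dims[2])
  for (k in seq_len(nrow(offs))) {
    cj <- ci
    cj[, 1] <- cj[, 1] + offs$dx[k]
    cj[, 2] <- cj[, 2] + offs$dy[k]
    cj[, 3] <- cj[, 3] + offs$dz[k]
    ok <- cj[, 1] >= 1L & cj[, 1] <= dims[1] &
      cj[, 2] >= 1L & cj[, 2] <= dims[2] &
      cj[, 3] >= 1L & cj[, 3] <= dims[3]
    w <- rep(NA_integer_, length(idx))
    w[ok] <- 1L + (cj[ok, , drop = FALSE] - 1L) %*% strides
    w[!is.na(w) & lab[w] == 0L] <- NA_integer_
    nb[[length(nb) + 1L]] <- w
  }
  repeat {
    changed <- FALSE
    cur <- lab[idx]
    for (w in nb) {
      ok <- !is.na(w)
      if (!any(ok)) next
      nl <- lab[w[ok]]
      sel <- nl < cur[ok]
      if (any(sel)) {
        j <- which(ok)[sel]
        cur[j] <- nl[sel]
        changed <- TRUE
      }
    }
    lab[idx] <- cur
    if (!changed) break
  }
  out <- array(0L, dims)
  out[idx] <- match(lab[idx], sort(unique(lab[idx])))
  out
}

## Largest connected component of a 3-D logical array (6-connectivity).
largestComponent3d <- function(mask) {
  lab <- labelComponents3d(mask)
  if (max(lab) == 0L) return(mask & FALSE)
  sizes <- tabulate(lab[lab > 0L])
  lab == which.max(sizes)
}
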
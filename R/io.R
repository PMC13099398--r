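## Standard-format export: NIfTI-1 volumes (via RNifti), YAML configs,
## CSV metric tables.

#' Write a volume (or frame stack) as NIfTI-1
#'
#' @param vol numeric array (nx, ny, nz) or (nx, ny, nz, nFrames)
#' @param file output path (.nii or .nii.gz)
#' @param voxelMm voxel size written to the header
#' @return the path, invisibly
#' @export
writeNiftiVolume <- function(vol, file, voxelMm = c(1, 1, 1)) {
  img <- RNifti::asNifti(vol)
  RNifti::pixdim(img) <- rep_len(voxelMm, length(dim(vol)))
  RNifti::writeNifti(img, file)
  invisible(file)
}

#' Read a NIfTI-1 volume as a plain array
#'
#' @param file path
#' @return numeric array
#' @export
readNiftiVolume <- function(file) {
  img <- RNifti::readNifti(file)
  array(as.numeric(img), dim = dim(img))
}

#' Save / load a phantom configuration as YAML
#'
#' Round-trips every scalar field of \code{\link{phantomConfig}} plus the
#' tissue table and motion model.
#'
#' @param config list from \code{\link{phantomConfig}}
#' @param file path
#' @export
writePhantomConfig <- function(config, file) {
  ser <- config
  ser$tissues <- lapply(config$tissues, function(tp) {
    k <- tp@kinetics
    list(t1_0 = tp@t1_0, t2star = tp@t2star, pd = tp@pd, r1 = tp@r1,
         kinetics = list(A = k@A, tArr = k@tArr, tauIn = k@tauIn,
                         tauOut = k@tauOut))
  })
  mo <- config$motion
  ser$motion <- list(rrMs = mo@rrMs, respMs = mo@respMs,
                     contractionFrac = mo@contractionFrac,
                     respAmpMm = mo@respAmpMm)
  yaml::write_yaml(ser, file)
  invisible(file)
}

#' @rdname writePhantomConfig
#' @export
readPhantomConfig <- function(file) {
  raw <- yaml::read_yaml(file)
  raw$tissues <- lapply(raw$tissues, function(tp) {
    k <- tp$kinetics
    tissueProperties(tp$t1_0, tp$t2star, tp$pd, tp$r1,
                     gdKinetics(k$A, k$tArr, k$tauIn, k$tauOut))
  })
  raw$motion <- motionModel(rrMs = raw$motion$rrMs, respMs = raw$motion$respMs,
                            contractionFrac = raw$motion$contractionFrac,
                            respAmpMm = raw$motion$respAmpMm)
  for (nm in c("grid")) raw[[nm]] <- as.integer(unlist(raw[[nm]]))
  for (nm in c("voxelMm", "lvCenterMm", "liverCenterMm", "liverHalfSizeMm"))
    raw[[nm]] <- as.numeric(unlist(raw[[nm]]))
  raw
}
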
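#' @include AllClasses.R
NULL

## NIfTI + JSON-sidecar IO. Complex CSI raw data is split into a
## real/imaginary NIfTI pair because NIfTI-1 via RNifti carries real
## volumes; the sidecar records the acquisition parameters.

paramsToList <- function(p) {
  list(csiMatrix = p@csiMatrix, spectralPoints = p@spectralPoints,
       spectralWidth = p@spectralWidth, fieldStrength = p@fieldStrength,
       csiFov = p@csiFov, csiSliceThickness = p@csiSliceThickness,
       tipCO2 = p@tipCO2, tipBic = p@tipBic, bValues = p@bValues,
       graseMatrix = p@graseMatrix, graseFov = p@graseFov,
       dwiMatrix = p@dwiMatrix, refOffsetBic = p@refOffsetBic,
       refOffsetCO2 = p@refOffsetCO2, t2star = p@t2star,
       noiseSigma = p@noiseSigma, seed = p@seed)
}

paramsFromList <- function(x) {
  acquisitionParams(
    csiMatrix = x$csiMatrix, spectralPoints = x$spectralPoints,
    spectralWidth = x$spectralWidth, fieldStrength = x$fieldStrength,
    csiFov = x$csiFov, csiSliceThickness = x$csiSliceThickness,
    tipCO2 = x$tipCO2, tipBic = x$tipBic, bValues = x$bValues,
    graseMatrix = x$graseMatrix, graseFov = x$graseFov,
    dwiMatrix = x$dwiMatrix, refOffsetBic = x$refOffsetBic,
    refOffsetCO2 = x$refOffsetCO2, t2star = x$t2star,
    noiseSigma = x$noiseSigma, seed = x$seed)
}

#' Write and read raw CSI data on disk
#'
#' The FidGrid container on disk is a directory holding `real.nii.gz`
#' and `imag.nii.gz` (the complex (kx, ky, t) array split by component)
#' plus `fidgrid.json` with the acquisition parameters and resonance
#' offsets.
#'
#' @param fid a [FidGrid-class].
#' @param dir directory to create/use.
#' @return `writeFidGrid`: the directory, invisibly. `readFidGrid`: a
#'   [FidGrid-class].
#' @export
writeFidGrid <- function(fid, dir) {
  stopifnot(is(fid, "FidGrid"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  RNifti::writeNifti(Re(fid@data), file.path(dir, "real.nii.gz"))
  RNifti::writeNifti(Im(fid@data), file.path(dir, "imag.nii.gz"))
  side <- c(paramsToList(fid@params),
            list(refFreqs = as.list(fid@refFreqs)))
  jsonlite::write_json(side, file.path(dir, "fidgrid.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @rdname writeFidGrid
#' @export
readFidGrid <- function(dir) {
  side <- jsonlite::read_json(file.path(dir, "fidgrid.json"),
                              simplifyVector = TRUE)
  re <- as.array(RNifti::readNifti(file.path(dir, "real.nii.gz")))
  im <- as.array(RNifti::readNifti(file.path(dir, "imag.nii.gz")))
  p <- paramsFromList(side)
  new("FidGrid", data = array(complex(real = re, imaginary = im), dim(re)),
      params = p,
      refFreqs = c(bic = side$refFreqs$bic, co2 = side$refFreqs$co2))
}

#' Write a metabolite map (or pH map) to NIfTI with a JSON sidecar
#'
#' Invalid voxels are written as NA; the sidecar records the noise level,
#' the validity count, and any extra metadata supplied.
#'
#' @param map a [MetaboliteMap-class] or [PhMap-class].
#' @param path output path ending in `.nii` or `.nii.gz`; the sidecar
#'   replaces the extension with `.json`.
#' @param extra named list merged into the sidecar.
#' @return the path, invisibly.
#' @export
writeMapNifti <- function(map, path, extra = list()) {
  vals <- mapValues(map)
  vals[!validMask(map)] <- NA_real_
  RNifti::writeNifti(vals, path)
  side <- c(list(nValid = sum(validMask(map))), extra)
  if (is(map, "MetaboliteMap"))
    side$noiseSigma <- map@noiseSigma
  if (is(map, "PhMap")) {
    side$calibration <- map@calibration
    side$qcCounts <- as.list(table(map@qc))
  }
  jsonlite::write_json(side, sub("\\.nii(\\.gz)?$", ".json", path),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write the ground-truth tables of a digital cohort to CSV
#'
#' One row per lesion: identifiers, grade, histology composition and
#' index, expression levels, and the ground-truth ROI statistics.
#'
#' @param lesions list of [GroundTruthLesion-class].
#' @param file output CSV path.
#' @return the table, invisibly.
#' @export
writeGroundTruthCSV <- function(lesions, file) {
  rows <- lapply(lesions, function(l) {
    comp <- l@histologyComposition
    rec <- data.frame(
      lesion = l@lesionId, mouse = l@mouseId, grade = l@grade,
      histologyIndex = histologyIndex(comp),
      fNormal = comp[["normal"]], fWell = comp[["well"]],
      fModerate = comp[["moderate"]], fPoor = comp[["poor"]],
      meanPH = l@truth$meanPH, minPH = l@truth$minPH,
      meanLacPyr = l@truth$meanLacPyr, maxLacPyr = l@truth$maxLacPyr,
      meanADC = l@truth$meanADC, nVoxels = l@truth$nVoxels,
      stringsAsFactors = FALSE)
    for (g in names(l@expression)) rec[[g]] <- unname(l@expression[[g]])
    rec
  })
  out <- do.call(rbind, rows)
  utils::write.csv(out, file, row.names = FALSE)
  invisible(out)
}
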
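#' @include AllClasses.R AllGenerics.R
NULL

#' @rdname mapValues
#' @export
setMethod("mapValues", "MetaboliteMap", function(x) x@values)

#' @rdname mapValues
#' @export
setMethod("mapValues", "PhMap", function(x) x@ph)

#' @rdname mapValues
#' @export
setMethod("mapValues", "LacPyrMap", function(x) x@ratio)

#' @rdname mapValues
#' @export
setMethod("mapValues", "AdcMap", function(x) x@adc)

#' @rdname mapValues
#' @export
setMethod("validMask", "MetaboliteMap", function(x) x@valid)

#' @rdname mapValues
#' @export
setMethod("validMask", "PhMap", function(x) x@valid)

#' @rdname mapValues
#' @export
setMethod("validMask", "LacPyrMap", function(x) x@valid)

#' @rdname mapValues
#' @export
setMethod("validMask", "AdcMap", function(x) x@valid)

#' @rdname mapValues
#' @export
setMethod("snrMap", "MetaboliteMap", function(x) x@snr)

#' @rdname mapValues
#' @export
setMethod("snrMap", "PhMap", function(x) list(bic = x@snrBic, co2 = x@snrCO2))

#' @rdname mapValues
#' @export
setMethod("snrMap", "LacPyrMap", function(x) list(lac = x@snrLac, pyr = x@snrPyr))

#' @rdname mapValues
#' @export
setMethod("noiseSigma", "MetaboliteMap", function(x) x@noiseSigma)

setMethod("show", "AcquisitionParams", function(object) {
  cat("AcquisitionParams\n")
  cat(sprintf("  CSI: %d x %d x %d over %g x %g mm^2, %g Hz, slab %g mm\n",
              object@csiMatrix[1], object@csiMatrix[2],
              object@spectralPoints, object@csiFov[1], object@csiFov[2],
              object@spectralWidth, object@csiSliceThickness))
  cat(sprintf("  tips: CO2 %g deg / bicarbonate %g deg\n",
              object@tipCO2, object@tipBic))
  cat(sprintf("  metabolite volume: %s over %s mm^3\n",
              paste(object@graseMatrix, collapse = " x "),
              paste(object@graseFov, collapse = " x ")))
  cat(sprintf("  b-values: %s s/mm^2\n",
              paste(object@bValues, collapse = ", ")))
  invisible(object)
})

setMethod("show", "GroundTruthLesion", function(object) {
  cat(sprintf("GroundTruthLesion %s (mouse %s, %s grade)\n",
              object@lesionId, object@mouseId, object@grade))
  cat(sprintf("  ROI: %d CSI voxels; truth mean/min pH %.3f/%.3f\n",
              sum(object@roiMask), object@truth$meanPH, object@truth$minPH))
  cat(sprintf("  truth mean Lac/Pyr %.2f (max %.2f), mean ADC %.2e mm^2/s\n",
              object@truth$meanLacPyr, object@truth$maxLacPyr,
              object@truth$meanADC))
  cat(sprintf("  histology index %.2f\n",
              histologyIndex(object@histologyComposition)))
  invisible(object)
})

setMethod("show", "FidGrid", function(object) {
  d <- dim(object@data)
  cat(sprintf("FidGrid: %d x %d spatial, %d time points (%g Hz)\n",
              d[1], d[2], d[3], object@params@spectralWidth))
  cat(sprintf("  resonances: bic %+g Hz, co2 %+g Hz\n",
              object@refFreqs[["bic"]], object@refFreqs[["co2"]]))
  invisible(object)
})

setMethod("show", "SpectralImage", function(object) {
  d <- dim(object@data)
  cat(sprintf("SpectralImage: %d x %d voxels, %d spectral points (%g to %g Hz)\n",
              d[1], d[2], d[3], min(object@freq), max(object@freq)))
  invisible(object)
})

setMethod("show", "MetaboliteMap", function(object) {
  cat(sprintf("MetaboliteMap: %d x %d, noise sigma %.4g, %d/%d valid\n",
              nrow(object@values), ncol(object@values), object@noiseSigma,
              sum(object@valid), length(object@valid)))
  invisible(object)
})

setMethod("show", "PhMap", function(object) {
  v <- object@ph[object@valid]
  cat(sprintf("PhMap: %d x %d, %d valid voxels (pKa %.2f, kappa %.3f, SNR >= %g)\n",
              nrow(object@ph), ncol(object@ph), sum(object@valid),
              object@calibration$pKa, object@calibration$kappa,
              object@calibration$snrMin))
  if (length(v))
    cat(sprintf("  pH range %.3f .. %.3f (mean %.3f)\n",
                min(v), max(v), mean(v)))
  invisible(object)
})

setMethod("show", "LacPyrMap", function(object) {
  cat(sprintf("LacPyrMap: %d x %d, %d valid voxels, pyruvate floor %.4g\n",
              nrow(object@ratio), ncol(object@ratio), sum(object@valid),
              object@pyrFloor))
  invisible(object)
})

setMethod("show", "AdcMap", function(object) {
  cat(sprintf("AdcMap: %d x %d, %d valid voxels\n",
              nrow(object@adc), ncol(object@adc), sum(object@valid)))
  if (length(object@exclusions))
    cat("  exclusions:",
        paste(names(object@exclusions), object@exclusions,
              sep = "=", collapse = ", "), "\n")
  invisible(object)
})

setMethod("show", "DwiStack", function(object) {
  d <- dim(object@signal)
  cat(sprintf("DwiStack: %d x %d voxels at b = %s s/mm^2\n",
              d[1], d[2], paste(object@bValues, collapse = ", ")))
  invisible(object)
})

setMethod("show", "CohortTable", function(object) {
  cat(sprintf("CohortTable: %d lesions (%d low / %d high), %d voxels\n",
              nrow(object@lesions),
              sum(object@lesions$grade == "low"),
              sum(object@lesions$grade == "high"),
              nrow(object@voxels)))
  invisible(object)
})

setMethod("show", "MixedModelFit", function(object) {
  cat(sprintf("MixedModelFit (%s): pH = %.3f %+.4f * LacPyr\n",
              object@method, object@intercept, object@slope))
  cat(sprintf("  slope SE %.4g, p = %.3g; var(mouse) %.3g, var(lesion) %.3g, var(resid) %.3g\n",
              object@slopeSE, object@pValue, object@varMouse,
              object@varLesion, object@varResidual))
  if (!object@converged) cat("  NOTE: fit flagged as singular/non-converged\n")
  invisible(object)
})

#' Lesion-level tables of a cohort
#'
#' @param x a [CohortTable-class].
#' @return `cohortLesions()`: the lesion-level data.frame;
#'   `cohortVoxels()`: the voxel-level long data.frame.
#' @export
cohortLesions <- function(x) {
  stopifnot(is(x, "CohortTable"))
  x@lesions
}

#' @rdname cohortLesions
#' @export
cohortVoxels <- function(x) {
  stopifnot(is(x, "CohortTable"))
  x@voxels
}
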
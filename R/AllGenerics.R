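#' @include AllClasses.R
NULL

#' Per-voxel values of a map
#'
#' Accessors for the map-like S4 containers ([MetaboliteMap-class],
#' [PhMap-class], [LacPyrMap-class], [AdcMap-class]). `mapValues()` returns
#' the per-voxel quantity (peak integral, pH, ratio or ADC), `validMask()`
#' the logical QC mask, `snrMap()` per-voxel signal-to-noise where defined,
#' and `noiseSigma()` the scalar noise level stored with the map.
#'
#' @param x a map object.
#' @return `mapValues`: numeric matrix; `validMask`: logical matrix;
#'   `snrMap`: numeric matrix or list of matrices; `noiseSigma`: numeric
#'   scalar.
#' @aliases mapValues validMask snrMap noiseSigma
#' @export
setGeneric("mapValues", function(x) standardGeneric("mapValues"))

#' @rdname mapValues
#' @export
setGeneric("validMask", function(x) standardGeneric("validMask"))

#' @rdname mapValues
#' @export
setGeneric("snrMap", function(x) standardGeneric("snrMap"))

#' @rdname mapValues
#' @export
setGeneric("noiseSigma", function(x) standardGeneric("noiseSigma"))
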
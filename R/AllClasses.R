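#' @import methods
NULL

## Central S4 containers for the hyperpolarized 13C pipeline. All spatial
## arrays are stored voxel-major (x, y[, z]) in scanner millimetre
## coordinates with the origin at the inferior/left corner of the FOV;
## voxel centers sit at origin + (i - 0.5) * spacing.

#' Acquisition parameters for the simulated multiparametric exam
#'
#' Geometry, excitation and noise settings shared by the CSI, metabolite
#' volume and diffusion simulators. Defaults reproduce the preclinical
#' protocol the pipeline targets: an 8x8x256 2D CSI matrix over a
#' 32x32 mm^2 FOV with 8013 Hz spectral width and two-band excitation
#' (25 deg on CO2, 2.78 deg on bicarbonate); a 12x12x16 metabolite volume
#' over 40x40x40 mm^3; and four b-values between 0 and 515 s/mm^2.
#'
#' @slot csiMatrix integer(2), in-plane CSI matrix size.
#' @slot spectralPoints integer(1), FID length.
#' @slot spectralWidth numeric(1), spectral width in Hz.
#' @slot fieldStrength numeric(1), 13C frequency in MHz (metadata only).
#' @slot csiFov numeric(2), CSI field of view in mm.
#' @slot csiSliceThickness numeric(1), CSI slab thickness in mm.
#' @slot tipCO2,tipBic numeric(1), nominal tip angles in degrees.
#' @slot bValues numeric, diffusion b-values in s/mm^2 (ascending, first 0).
#' @slot graseMatrix integer(3), metabolite volume matrix size.
#' @slot graseFov numeric(3), metabolite volume FOV in mm.
#' @slot dwiMatrix integer(2), in-plane diffusion matrix size.
#' @slot refOffsetBic,refOffsetCO2 numeric(1), resonance offsets in Hz.
#' @slot t2star numeric(1), apparent transverse decay constant in seconds.
#' @slot noiseSigma numeric(1), default noise level in signal units.
#' @slot seed integer(1), base seed recorded with the acquisition.
#' @seealso [acquisitionParams()] for the user-facing constructor.
#' @export
setClass("AcquisitionParams", representation(
  csiMatrix = "integer",
  spectralPoints = "integer",
  spectralWidth = "numeric",
  fieldStrength = "numeric",
  csiFov = "numeric",
  csiSliceThickness = "numeric",
  tipCO2 = "numeric",
  tipBic = "numeric",
  bValues = "numeric",
  graseMatrix = "integer",
  graseFov = "numeric",
  dwiMatrix = "integer",
  refOffsetBic = "numeric",
  refOffsetCO2 = "numeric",
  t2star = "numeric",
  noiseSigma = "numeric",
  seed = "integer"
))

setValidity("AcquisitionParams", function(object) {
  msg <- character()
  if (length(object@csiMatrix) != 2L || any(object@csiMatrix < 1L))
    msg <- c(msg, "csiMatrix must be two positive integers")
  if (object@spectralPoints < 2L)
    msg <- c(msg, "spectralPoints must be >= 2")
  if (object@spectralWidth <= 0)
    msg <- c(msg, "spectralWidth must be positive")
  for (tip in c(object@tipCO2, object@tipBic))
    if (!is.finite(tip) || tip <= 0 || tip >= 90)
      msg <- c(msg, "tip angles must lie in (0, 90) degrees")
  b <- object@bValues
  if (length(b) < 1L || b[1] != 0 || any(diff(b) <= 0) || any(b < 0))
    msg <- c(msg, "bValues must be strictly increasing with first value 0")
  if (length(object@graseMatrix) != 3L || any(object@graseMatrix < 1L))
    msg <- c(msg, "graseMatrix must be three positive integers")
  if (any(object@csiFov <= 0) || any(object@graseFov <= 0))
    msg <- c(msg, "fields of view must be positive")
  if (object@t2star <= 0)
    msg <- c(msg, "t2star must be positive")
  if (object@noiseSigma < 0)
    msg <- c(msg, "noiseSigma must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Ground-truth digital lesion
#'
#' One simulated tumor region with known per-voxel extracellular pH,
#' lactate-to-pyruvate ratio and apparent diffusion coefficient fields,
#' plus histology composition and (optionally) gene expression. The `truth`
#' slot caches the ROI summary statistics implied by the fields so tests
#' and acceptance runs can compare pipeline output against construction.
#'
#' @slot lesionId,mouseId character identifiers.
#' @slot grade character, "low" or "high".
#' @slot phField numeric matrix on the CSI grid, pH units.
#' @slot roiMask logical matrix on the CSI grid.
#' @slot tumorFraction numeric matrix on the CSI grid, fraction in [0, 1].
#' @slot lacPyrField numeric array on the metabolite grid, unitless ratio.
#' @slot graseMask logical array on the metabolite grid.
#' @slot adcField numeric matrix on the diffusion grid, mm^2/s.
#' @slot dwiMask logical matrix on the diffusion grid.
#' @slot histologyComposition named numeric(4) over
#'   normal/well/moderate/poor, summing to 1.
#' @slot expression named numeric, mRNA levels normalized to housekeeping
#'   (empty until [simulateExpression()] fills it).
#' @slot truth list of ground-truth ROI statistics.
#' @export
setClass("GroundTruthLesion", representation(
  lesionId = "character",
  mouseId = "character",
  grade = "character",
  phField = "matrix",
  roiMask = "matrix",
  tumorFraction = "matrix",
  lacPyrField = "array",
  graseMask = "array",
  adcField = "matrix",
  dwiMask = "matrix",
  histologyComposition = "numeric",
  expression = "numeric",
  truth = "list"
))

setValidity("GroundTruthLesion", function(object) {
  msg <- character()
  if (!object@grade %in% c("low", "high"))
    msg <- c(msg, "grade must be 'low' or 'high'")
  ph <- object@phField[object@roiMask]
  if (length(ph) && (any(ph < 6) || any(ph > 8)))
    msg <- c(msg, "ROI pH field must lie in [6, 8]")
  adc <- object@adcField[object@dwiMask]
  if (length(adc) && (any(adc <= 0) || any(adc > 3.0e-3)))
    msg <- c(msg, "ROI ADC field must lie in (0, 3.0e-3] mm^2/s")
  comp <- object@histologyComposition
  cls <- c("normal", "well", "moderate", "poor")
  if (!all(cls %in% names(comp)))
    msg <- c(msg, "histologyComposition must name normal/well/moderate/poor")
  else {
    if (abs(sum(comp[cls]) - 1) > 1e-9)
      msg <- c(msg, "histology fractions must sum to 1 (1e-9 tolerance)")
    if (any(comp[cls] < -1e-12) || any(comp[cls] > 1 + 1e-12))
      msg <- c(msg, "histology fractions must lie in [0, 1]")
  }
  if (any(object@tumorFraction < 0) || any(object@tumorFraction > 1))
    msg <- c(msg, "tumorFraction must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Raw chemical shift imaging data
#'
#' Complex free-induction decays over the phase-encode plane: a
#' (kx, ky, t) array together with the acquisition parameters and the
#' resonance offsets of bicarbonate and CO2.
#'
#' @slot data complex array (kx, ky, t).
#' @slot params an [AcquisitionParams-class].
#' @slot refFreqs named numeric(2) with elements `bic` and `co2`, Hz.
#' @export
setClass("FidGrid", representation(
  data = "array",
  params = "AcquisitionParams",
  refFreqs = "numeric"
))

setValidity("FidGrid", function(object) {
  msg <- character()
  d <- dim(object@data)
  p <- object@params
  if (length(d) != 3L ||
      !all(d == c(p@csiMatrix, p@spectralPoints)))
    msg <- c(msg, "data dimensions must match csiMatrix x spectralPoints")
  if (!all(is.finite(Re(object@data))) || !all(is.finite(Im(object@data))))
    msg <- c(msg, "data must be finite")
  if (!all(c("bic", "co2") %in% names(object@refFreqs)))
    msg <- c(msg, "refFreqs must name 'bic' and 'co2'")
  if (length(msg)) msg else TRUE
})

#' Reconstructed spatial-spectral image
#'
#' Magnitude spectra per voxel with the Hz frequency axis (ascending,
#' centered on 0) and the provenance acquisition parameters.
#'
#' @slot data numeric array (x, y, frequency), non-negative magnitudes.
#' @slot freq numeric frequency axis in Hz, length `spectralPoints`.
#' @slot params an [AcquisitionParams-class].
#' @export
setClass("SpectralImage", representation(
  data = "array",
  freq = "numeric",
  params = "AcquisitionParams"
))

setValidity("SpectralImage", function(object) {
  msg <- character()
  d <- dim(object@data)
  if (length(d) != 3L || d[3] != length(object@freq))
    msg <- c(msg, "third dimension must match the frequency axis")
  if (d[3] != object@params@spectralPoints)
    msg <- c(msg, "frequency axis length must equal spectralPoints")
  if (any(object@data < 0))
    msg <- c(msg, "magnitudes must be non-negative")
  if (is.unsorted(object@freq, strictly = TRUE))
    msg <- c(msg, "frequency axis must be strictly increasing")
  if (length(msg)) msg else TRUE
})

#' Scalar per-voxel metabolite map
#'
#' Peak-integral (or magnitude) values on a 2D grid with the noise level
#' used for SNR, the per-voxel SNR, a validity mask and the in-plane voxel
#' spacing in mm.
#'
#' @slot values numeric matrix, map values in peak-integral units.
#' @slot noiseSigma numeric(1), noise scale in the same units.
#' @slot snr numeric matrix, `values / noiseSigma` (Inf when noiseless).
#' @slot valid logical matrix.
#' @slot spacing numeric(2), voxel spacing in mm.
#' @export
setClass("MetaboliteMap", representation(
  values = "matrix",
  noiseSigma = "numeric",
  snr = "matrix",
  valid = "matrix",
  spacing = "numeric"
))

setValidity("MetaboliteMap", function(object) {
  msg <- character()
  if (!all(dim(object@snr) == dim(object@values)) ||
      !all(dim(object@valid) == dim(object@values)))
    msg <- c(msg, "values, snr and valid must share dimensions")
  if (object@noiseSigma < 0)
    msg <- c(msg, "noiseSigma must be non-negative")
  v <- object@values[object@valid]
  if (length(v) && !all(is.finite(v)))
    msg <- c(msg, "valid voxels must carry finite values")
  if (length(msg)) msg else TRUE
})

#' Extracellular pH map
#'
#' Per-voxel pH with a validity mask, per-voxel source SNRs and QC reason
#' codes ("ok", "low_snr_bic", "low_snr_co2", "low_snr_both",
#' "nonpositive_co2"). Valid voxels always carry finite pH.
#'
#' @slot ph numeric matrix, pH units (NA where invalid).
#' @slot valid logical matrix.
#' @slot snrBic,snrCO2 numeric matrices.
#' @slot qc character matrix of reason codes.
#' @slot calibration list with elements `pKa`, `kappa`, `snrMin`.
#' @export
setClass("PhMap", representation(
  ph = "matrix",
  valid = "matrix",
  snrBic = "matrix",
  snrCO2 = "matrix",
  qc = "matrix",
  calibration = "list"
))

setValidity("PhMap", function(object) {
  msg <- character()
  if (!all(dim(object@valid) == dim(object@ph)) ||
      !all(dim(object@qc) == dim(object@ph)))
    msg <- c(msg, "ph, valid and qc must share dimensions")
  v <- object@ph[object@valid]
  if (length(v) && !all(is.finite(v)))
    msg <- c(msg, "valid voxels must hold finite pH")
  if (length(msg)) msg else TRUE
})

#' Lactate-to-pyruvate ratio map
#'
#' @slot ratio numeric matrix, unitless (NA where invalid).
#' @slot valid logical matrix.
#' @slot snrLac,snrPyr numeric matrices.
#' @slot pyrFloor numeric(1), mean-noise-magnitude floor substituted for
#'   low-SNR pyruvate voxels.
#' @export
setClass("LacPyrMap", representation(
  ratio = "matrix",
  valid = "matrix",
  snrLac = "matrix",
  snrPyr = "matrix",
  pyrFloor = "numeric"
))

setValidity("LacPyrMap", function(object) {
  msg <- character()
  r <- object@ratio[object@valid]
  if (length(r) && (!all(is.finite(r)) || any(r < 0)))
    msg <- c(msg, "valid ratios must be finite and non-negative")
  if (length(msg)) msg else TRUE
})

#' Apparent diffusion coefficient map
#'
#' Mono-exponential fit results per voxel: ADC, fitted S0, the RMS residual
#' in the signal domain, a validity mask, per-voxel QC flags ("ok",
#' "unfittable", "high_residual", "high_adc") and exclusion counts by
#' reason.
#'
#' @slot adc numeric matrix, mm^2/s.
#' @slot s0 numeric matrix, signal units.
#' @slot rmsResidual numeric matrix, signal units.
#' @slot valid logical matrix.
#' @slot flags character matrix.
#' @slot exclusions named integer vector of per-reason counts.
#' @export
setClass("AdcMap", representation(
  adc = "matrix",
  s0 = "matrix",
  rmsResidual = "matrix",
  valid = "matrix",
  flags = "matrix",
  exclusions = "integer"
))

setValidity("AdcMap", function(object) {
  msg <- character()
  a <- object@adc[object@valid]
  if (length(a) && !all(is.finite(a)))
    msg <- c(msg, "valid voxels must hold finite ADC")
  if (length(msg)) msg else TRUE
})

#' Multi-b-value diffusion stack
#'
#' @slot signal numeric array (x, y, b), magnitude signal, non-negative.
#' @slot bValues numeric, s/mm^2, ascending with first value 0.
#' @export
setClass("DwiStack", representation(
  signal = "array",
  bValues = "numeric"
))

setValidity("DwiStack", function(object) {
  msg <- character()
  d <- dim(object@signal)
  if (length(d) != 3L || d[3] != length(object@bValues))
    msg <- c(msg, "third dimension must index b-values")
  if (any(object@signal < 0))
    msg <- c(msg, "signal must be non-negative")
  if (object@bValues[1] != 0 || any(diff(object@bValues) <= 0))
    msg <- c(msg, "bValues must be ascending with first value 0")
  if (length(msg)) msg else TRUE
})

#' Cohort tables for the statistics stage
#'
#' A lesion-level table (one row per lesion: grade, histology index, ROI
#' summaries, expression) and a voxel-level long table (mouse, lesion, pH,
#' Lac/Pyr) feeding the mixed-effects model.
#'
#' @slot lesions data.frame, one row per lesion.
#' @slot voxels data.frame with columns mouse, lesion, ph, lacpyr.
#' @export
setClass("CohortTable", representation(
  lesions = "data.frame",
  voxels = "data.frame"
))

setValidity("CohortTable", function(object) {
  msg <- character()
  if (nrow(object@lesions) &&
      anyDuplicated(object@lesions$lesion))
    msg <- c(msg, "duplicated lesion ids in lesion table")
  if (nrow(object@voxels)) {
    need <- c("mouse", "lesion", "ph", "lacpyr")
    if (!all(need %in% names(object@voxels)))
      msg <- c(msg, "voxel table must have mouse, lesion, ph, lacpyr")
    else if (nrow(object@lesions) &&
             !all(object@voxels$lesion %in% object@lesions$lesion))
      msg <- c(msg, "voxel table references unknown lesions")
    if (!is.null(object@voxels$voxel) &&
        anyDuplicated(object@voxels[c("lesion", "voxel")]))
      msg <- c(msg, "duplicated voxel keys")
  }
  if (length(msg)) msg else TRUE
})

#' Mixed-effects model fit summary
#'
#' Fixed intercept/slope of voxelwise pH on Lac/Pyr with nested
#' random-intercept variance components and the slope's standard error and
#' p-value.
#'
#' @slot slope,intercept numeric(1), fixed effects (pH units per unit
#'   Lac/Pyr; pH units).
#' @slot slopeSE numeric(1), standard error of the slope.
#' @slot pValue numeric(1), two-sided p-value for the slope.
#' @slot varMouse,varLesion,varResidual numeric(1), variance components
#'   (>= 0; may be exactly 0 for degenerate fits).
#' @slot converged logical(1), FALSE for singular/non-converged fits.
#' @slot method character(1), "reml" or "ols".
#' @export
setClass("MixedModelFit", representation(
  slope = "numeric",
  intercept = "numeric",
  slopeSE = "numeric",
  pValue = "numeric",
  varMouse = "numeric",
  varLesion = "numeric",
  varResidual = "numeric",
  converged = "logical",
  method = "character"
))

setValidity("MixedModelFit", function(object) {
  msg <- character()
  if (any(c(object@varMouse, object@varLesion, object@varResidual) < 0))
    msg <- c(msg, "variance components must be non-negative")
  if (length(msg)) msg else TRUE
})
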
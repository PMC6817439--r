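#' @include AllClasses.R
NULL

#' Histologic index from a differentiation composition
#'
#' Weighted sum of differentiation-class fractions with weights 0
#' (normal), 1 (well-differentiated), 2 (moderately differentiated) and
#' 3 (poorly differentiated): 0 means 100% normal tissue, 3 means 100%
#' poorly differentiated. The index is linear in the composition.
#'
#' @param composition named numeric over
#'   `normal`/`well`/`moderate`/`poor`; fractions in `[0, 1]` summing to
#'   1 (1e-9 tolerance).
#' @return numeric(1) index in `[0, 3]`.
#' @examples
#' histologyIndex(c(normal = 0, well = 0.3, moderate = 0.7, poor = 0))
#' @export
histologyIndex <- function(composition) {
  cls <- c("normal", "well", "moderate", "poor")
  if (!all(cls %in% names(composition)))
    stop("composition must name normal, well, moderate, poor")
  f <- composition[cls]
  if (any(f < 0) || any(f > 1))
    stop("fractions must lie in [0, 1]")
  if (abs(sum(f) - 1) > 1e-9)
    stop("fractions must sum to 1")
  unname(sum(f * 0:3))
}

#' Dichotomize a histologic index into a grade label
#'
#' Low grade for index <= 2, high grade for index > 2, mirroring the
#' clinical dichotomization of Gleason <= 3+3 versus >= 3+4.
#'
#' @param index numeric in `[0, 3]`.
#' @return `"low"` or `"high"` (vectorized).
#' @export
dichotomizeGrade <- function(index) {
  if (any(index < 0) || any(index > 3))
    stop("index must lie in [0, 3]")
  ifelse(index <= 2, "low", "high")
}

#' Select analyzable voxels by tumor content
#'
#' Voxels inside the ROI mask whose tumor fraction is at least
#' `threshold` (inclusive, "at least 50% tumor" at the default).
#' An empty result is allowed and flagged with a warning.
#'
#' @param roiMask logical matrix of ROI membership.
#' @param tumorFraction numeric matrix of per-voxel tumor fractions.
#' @param threshold fraction in (0, 1], default 0.5.
#' @return logical matrix of selected voxels.
#' @export
selectVoxels <- function(roiMask, tumorFraction, threshold = 0.5) {
  stopifnot(threshold > 0, threshold <= 1,
            all(dim(roiMask) == dim(tumorFraction)))
  sel <- roiMask & tumorFraction >= threshold
  if (!any(sel))
    warning("no voxels selected: empty ROI after tumor-fraction threshold")
  sel
}

#' Summarize a lesion's maps into a LesionRecord row
#'
#' Computes the mean and minimum pH, mean and maximum Lac/Pyr, and mean
#' ADC over the intersection of the selected voxels and each modality's
#' validity mask. Modalities with no contributing voxels yield NA.
#' `voxels` may be a single logical matrix (used for every modality whose
#' grid matches) or a named list with elements `ph`, `lacpyr`, `adc`.
#'
#' @param ph a [PhMap-class] or NULL.
#' @param lacpyr a [LacPyrMap-class] or NULL.
#' @param adc an [AdcMap-class] or NULL.
#' @param voxels logical matrix or named list of logical matrices.
#' @param lesionId,mouseId,grade,histologyIndex optional identifiers
#'   carried into the record.
#' @param expression optional named numeric of expression levels.
#' @return one-row data.frame (the LesionRecord).
#' @export
roiSummary <- function(ph = NULL, lacpyr = NULL, adc = NULL, voxels,
                       lesionId = NA_character_, mouseId = NA_character_,
                       grade = NA_character_,
                       histologyIndex = NA_real_, expression = NULL) {
  maskFor <- function(modality, mapDim) {
    m <- if (is.list(voxels)) voxels[[modality]] else voxels
    if (is.null(m)) return(NULL)
    if (!all(dim(m) == mapDim))
      stop(sprintf("voxel mask for %s does not match the map grid", modality))
    m
  }
  pull <- function(map, modality) {
    if (is.null(map)) return(numeric(0))
    sel <- maskFor(modality, dim(map@valid))
    if (is.null(sel)) return(numeric(0))
    mapValues(map)[map@valid & sel]
  }
  phv <- pull(ph, "ph")
  lpv <- pull(lacpyr, "lacpyr")
  adv <- pull(adc, "adc")
  rec <- data.frame(
    lesion = lesionId, mouse = mouseId, grade = grade,
    histologyIndex = histologyIndex,
    meanPH = if (length(phv)) mean(phv) else NA_real_,
    minPH = if (length(phv)) min(phv) else NA_real_,
    meanLacPyr = if (length(lpv)) mean(lpv) else NA_real_,
    maxLacPyr = if (length(lpv)) max(lpv) else NA_real_,
    meanADC = if (length(adv)) mean(adv) else NA_real_,
    nVoxPH = length(phv), nVoxLacPyr = length(lpv), nVoxADC = length(adv),
    stringsAsFactors = FALSE
  )
  if (!is.null(expression))
    for (g in names(expression)) rec[[g]] <- unname(expression[[g]])
  rec
}

#' Assemble a CohortTable from lesion records and a voxel table
#'
#' @param lesions data.frame of one-row lesion records (see
#'   [roiSummary()]).
#' @param voxels data.frame with columns `mouse`, `lesion`, `ph`,
#'   `lacpyr` (and optionally `voxel`); may be empty.
#' @return a [CohortTable-class].
#' @export
cohortTable <- function(lesions,
                        voxels = data.frame(mouse = character(),
                                            lesion = character(),
                                            ph = numeric(),
                                            lacpyr = numeric())) {
  new("CohortTable", lesions = lesions, voxels = voxels)
}
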
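#' @include AllClasses.R synthetic-cohort.R csi-recon.R ph-mapping.R
#' @include metabolite-mapping.R adc-mapping.R roi-analysis.R stats-report.R
NULL

#' Process one digital lesion through the full imaging pipeline
#'
#' Runs the three simulated acquisitions and their reconstructions:
#' CSI at the requested peak SNR through [csiToPhMap()]; metabolite
#' volumes through slab matching and the asymmetric SNR rules of
#' [graseToLacPyrMap()]; the diffusion stack through [fitADC()] and
#' [filterADC()] (residual limit scaled to the synthetic signal level as
#' `0.5 * s0`, i.e. 500 at the scanner-like s0 of 1000). Voxels are
#' selected at the tumor-fraction threshold and summarized into a
#' LesionRecord row.
#'
#' @param lesion a [GroundTruthLesion-class].
#' @param params an [AcquisitionParams-class].
#' @param seed integer seed; sub-seeds for the three acquisitions are
#'   derived deterministically.
#' @param peakSNR CSI spectral peak SNR of the weaker resonance
#'   (`Inf` for a noiseless acquisition).
#' @param cal a [phCalibration()] list.
#' @param graseSNR pyruvate amplitude over Gaussian noise sd in the
#'   metabolite volumes (`Inf` for noiseless).
#' @param dwiSNR b = 0 signal over noise sd in the diffusion stack
#'   (`Inf` for noiseless).
#' @param s0Dwi b = 0 signal amplitude.
#' @param tumorThreshold minimum tumor fraction for voxel selection.
#' @return list with elements `phMap`, `lacPyrMap`, `adcMap`, `record`
#'   (one-row data.frame) and `voxels` (per-voxel pH/LacPyr pairs on the
#'   CSI grid for the mixed-model table).
#' @export
processLesion <- function(lesion, params = acquisitionParams(), seed = 1L,
                          peakSNR = 30, cal = phCalibration(),
                          graseSNR = 30, dwiSNR = 50, s0Dwi = 1000,
                          tumorThreshold = 0.5) {
  sigmaCsi <- if (is.finite(peakSNR))
    csiNoiseForPeakSNR(lesion, params, peakSNR = peakSNR) else 0
  fid <- simulateCSI(lesion, params, noiseSigma = sigmaCsi,
                     seed = deriveSeed(seed, 1L), pKa = cal$pKa)
  phMap <- csiToPhMap(fid, cal = cal)

  s0Grase <- 100
  sigmaGrase <- if (is.finite(graseSNR)) s0Grase / graseSNR else 0
  vols <- simulateGRASE(lesion, params, s0 = s0Grase,
                        noiseSigma = sigmaGrase,
                        seed = deriveSeed(seed, 2L))
  lacPyrMap <- graseToLacPyrMap(vols$pyruvate, vols$lactate, params)

  sigmaDwi <- if (is.finite(dwiSNR)) s0Dwi / dwiSNR else 0
  stack <- simulateDWI(lesion, s0 = s0Dwi, params = params,
                       noiseSigma = sigmaDwi, seed = deriveSeed(seed, 3L))
  adcMap <- filterADC(fitADC(stack), residualLimit = 0.5 * s0Dwi)

  sel <- selectVoxels(lesion@roiMask, lesion@tumorFraction,
                      threshold = tumorThreshold)
  lacSel <- apply(lesion@graseMask, c(1, 2), any)
  record <- roiSummary(
    ph = phMap, lacpyr = lacPyrMap, adc = adcMap,
    voxels = list(ph = sel, lacpyr = lacSel, adc = lesion@dwiMask),
    lesionId = lesion@lesionId, mouseId = lesion@mouseId,
    grade = lesion@grade,
    histologyIndex = histologyIndex(lesion@histologyComposition),
    expression = if (length(lesion@expression)) lesion@expression else NULL)

  voxels <- lesionVoxelTable(lesion, phMap, lacPyrMap, params, sel)
  list(phMap = phMap, lacPyrMap = lacPyrMap, adcMap = adcMap,
       record = record, voxels = voxels)
}

## Pair each selected, valid CSI pH voxel with the Lac/Pyr signal over
## its footprint. Both FOVs are centered at isocenter; the Lac/Pyr map is
## averaged over the metabolite voxels whose in-plane centers fall inside
## the (coarser) CSI voxel (half-open boundaries, voxel-center
## coordinates).
lesionVoxelTable <- function(lesion, phMap, lacPyrMap, params, sel) {
  nxC <- params@csiMatrix[1]; nyC <- params@csiMatrix[2]
  fovC <- params@csiFov
  fovG <- params@graseFov[1:2]
  nG <- dim(lacPyrMap@ratio)
  off <- (fovG - fovC) / 2  # CSI FOV centered inside the metabolite FOV
  gx <- (seq_len(nG[1]) - 0.5) * fovG[1] / nG[1]
  gy <- (seq_len(nG[2]) - 0.5) * fovG[2] / nG[2]
  rows <- list()
  for (i in seq_len(nxC)) for (j in seq_len(nyC)) {
    if (!sel[i, j] || !phMap@valid[i, j]) next
    x0 <- off[1] + (i - 1) * fovC[1] / nxC
    x1 <- off[1] + i * fovC[1] / nxC
    y0 <- off[2] + (j - 1) * fovC[2] / nyC
    y1 <- off[2] + j * fovC[2] / nyC
    inX <- gx >= x0 & gx < x1
    inY <- gy >= y0 & gy < y1
    vals <- lacPyrMap@ratio[inX, inY, drop = FALSE]
    ok <- lacPyrMap@valid[inX, inY, drop = FALSE]
    if (!any(ok)) next
    rows[[length(rows) + 1L]] <- data.frame(
      mouse = lesion@mouseId, lesion = lesion@lesionId,
      voxel = sprintf("%d_%d", i, j),
      ph = phMap@ph[i, j], lacpyr = mean(vals[ok]),
      stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(mouse = character(), lesion = character(),
                      voxel = character(), ph = numeric(),
                      lacpyr = numeric(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Run a whole digital cohort through the pipeline
#'
#' Applies [processLesion()] to every lesion (per-lesion sub-seeds are
#' derived from `seed`) and assembles the lesion-level and voxel-level
#' tables into a [CohortTable-class].
#'
#' @param lesions list of [GroundTruthLesion-class], e.g. from
#'   [generateCohort()].
#' @param params an [AcquisitionParams-class].
#' @param seed integer seed.
#' @param ... further arguments passed to [processLesion()].
#' @return a [CohortTable-class].
#' @export
processCohort <- function(lesions, params = acquisitionParams(),
                          seed = 1L, ...) {
  recs <- list(); voxs <- list()
  for (k in seq_along(lesions)) {
    out <- processLesion(lesions[[k]], params,
                         seed = deriveSeed(seed, 100L + k), ...)
    recs[[k]] <- out$record
    voxs[[k]] <- out$voxels
  }
  lesTab <- if (length(recs)) do.call(rbind, recs) else
    data.frame(lesion = character(), mouse = character(),
               grade = character(), stringsAsFactors = FALSE)
  voxTab <- do.call(rbind, voxs)
  if (is.null(voxTab))
    voxTab <- data.frame(mouse = character(), lesion = character(),
                         ph = numeric(), lacpyr = numeric(),
                         stringsAsFactors = FALSE)
  cohortTable(lesTab, voxTab)
}
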
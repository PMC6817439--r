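#' @include AllClasses.R acquisition.R utils.R
NULL

#' Default group-level ground-truth statistics
#'
#' Lesion-level means and standard deviations used by [generateCohort()]
#' to draw ground-truth fields for the two histological grades. The pH
#' entries are the published group statistics for this model (ROI-mean pH
#' 7.53 +/- 0.17 low grade, 7.22 +/- 0.14 high grade; ROI-minimum pH
#' 7.43 +/- 0.19 and 7.06 +/- 0.12, encoded here as the mean-to-minimum
#' drop per grade). Lac/Pyr and ADC group parameters are typical
#' preclinical prostate-tumor values (high grade: higher Lac/Pyr, lower
#' ADC). All entries are overridable.
#'
#' @return nested list with elements `low` and `high`, each holding
#'   `meanPH`, `sdPH`, `minDrop` (pH units), `meanLacPyr`, `sdLacPyr`
#'   (unitless), `meanADC`, `sdADC` (mm^2/s).
#' @export
defaultGroupStats <- function() {
  list(
    low = list(meanPH = 7.53, sdPH = 0.17, minDrop = 0.10,
               meanLacPyr = 0.8, sdLacPyr = 0.25,
               meanADC = 1.6e-3, sdADC = 2.0e-4),
    high = list(meanPH = 7.22, sdPH = 0.14, minDrop = 0.16,
                meanLacPyr = 1.8, sdLacPyr = 0.40,
                meanADC = 1.0e-3, sdADC = 1.5e-4)
  )
}

## Histology composition realizing a target index as a mixture of the two
## adjacent differentiation classes (class scores 0,1,2,3).
compositionForIndex <- function(index) {
  stopifnot(index >= 0, index <= 3)
  cls <- c("normal", "well", "moderate", "poor")
  comp <- stats::setNames(numeric(4), cls)
  k <- min(floor(index), 2)
  frac <- index - k
  comp[k + 1L] <- 1 - frac
  comp[k + 2L] <- frac
  comp
}

## Within-lesion heterogeneity is driven by one shared spatial
## "aggressiveness" gradient A(x, y) in scanner mm coordinates (all FOVs
## centered at isocenter of the widest FOV): pH falls, Lac/Pyr rises and
## ADC falls where A is high, so voxelwise pH-Lac/Pyr coupling is
## negative within lesions as well as across grades.
aggressivenessAt <- function(x, y) outer(x, y, `+`)

## center/scale a field over a mask: result has mean 0 and max +1 on the
## mask (so `mean + amp * s` has exact ROI mean and max mean + amp)
unitScale <- function(A, mask) {
  v <- A[mask]
  if (max(v) - mean(v) < 1e-12) return(A * 0)
  (A - mean(v)) / (max(v) - mean(v))
}

buildLesion <- function(lesionId, mouseId, grade, meanPH, minDrop,
                        meanLacPyr, meanADC, histIndex, params) {
  nx <- params@csiMatrix[1]; ny <- params@csiMatrix[2]
  wide <- max(params@graseFov[1:2], params@csiFov)
  ## central ROI block on the CSI grid
  rows <- seq(max(1, nx %/% 2 - 1), min(nx, nx %/% 2 + 2))
  cols <- seq(max(1, ny %/% 2 - 1), min(ny, ny %/% 2 + 2))
  roi <- matrix(FALSE, nx, ny); roi[rows, cols] <- TRUE

  csiOff <- (wide - params@csiFov) / 2
  cx <- csiOff[1] + (seq_len(nx) - 0.5) * params@csiFov[1] / nx
  cy <- csiOff[2] + (seq_len(ny) - 0.5) * params@csiFov[2] / ny
  Acsi <- aggressivenessAt(cx, cy)
  sCsi <- unitScale(Acsi, roi)
  rangeCsi <- max(Acsi[roi]) - mean(Acsi[roi])
  ph <- matrix(meanPH, nx, ny)
  ph[roi] <- meanPH - minDrop * sCsi[roi]   # min = mean - drop, mean exact
  tf <- matrix(0, nx, ny); tf[roi] <- 1

  ## metabolite volume: ratio constant across slices inside the lesion slab
  gm <- params@graseMatrix
  gRows <- seq(max(1, gm[1] %/% 2 - 2), min(gm[1], gm[1] %/% 2 + 3))
  gCols <- seq(max(1, gm[2] %/% 2 - 2), min(gm[2], gm[2] %/% 2 + 3))
  gSlices <- seq(max(1, gm[3] %/% 2 - 2), min(gm[3], gm[3] %/% 2 + 3))
  gMask <- array(FALSE, gm)
  gMask[gRows, gCols, gSlices] <- TRUE
  gOff <- (wide - params@graseFov[1:2]) / 2
  gx <- gOff[1] + (seq_len(gm[1]) - 0.5) * params@graseFov[1] / gm[1]
  gy <- gOff[2] + (seq_len(gm[2]) - 0.5) * params@graseFov[2] / gm[2]
  foot <- gMask[, , gSlices[1]]
  Ag <- aggressivenessAt(gx, gy)
  sG <- unitScale(Ag, foot)
  rangeG <- max(Ag[foot]) - mean(Ag[foot])
  ## modulation amplitude chosen so pH falls ~0.151 units per unit
  ## Lac/Pyr along the shared spatial gradient (the published voxelwise
  ## coupling), corrected for the different spatial extents of the two
  ## grids and capped to keep the ratio field non-negative
  ampLP <- min(minDrop * rangeG / (0.151 * rangeCsi * meanLacPyr), 0.9)
  lp2d <- pmax(meanLacPyr * (1 + ampLP * sG), 0)
  lacpyr <- array(0, gm)
  for (s in gSlices)
    lacpyr[, , s][foot] <- lp2d[foot]

  ## diffusion grid
  dm <- params@dwiMatrix
  dRows <- seq(max(1, dm[1] %/% 2 - 3), min(dm[1], dm[1] %/% 2 + 4))
  dCols <- seq(max(1, dm[2] %/% 2 - 3), min(dm[2], dm[2] %/% 2 + 4))
  dMask <- matrix(FALSE, dm[1], dm[2]); dMask[dRows, dCols] <- TRUE
  dx <- (seq_len(dm[1]) - 0.5) * wide / dm[1]
  dy <- (seq_len(dm[2]) - 0.5) * wide / dm[2]
  sD <- unitScale(aggressivenessAt(dx, dy), dMask)
  adc <- matrix(2.2e-3, dm[1], dm[2])  # peritumoral background
  adc[dMask] <- pmin(pmax(meanADC * (1 - 0.1 * sD[dMask]), 1e-5), 3e-3)

  truth <- list(
    meanPH = mean(ph[roi]), minPH = min(ph[roi]),
    meanLacPyr = mean(lacpyr[gMask]), maxLacPyr = max(lacpyr[gMask]),
    meanADC = mean(adc[dMask]), nVoxels = sum(roi)
  )

  new("GroundTruthLesion",
      lesionId = lesionId, mouseId = mouseId, grade = grade,
      phField = ph, roiMask = roi, tumorFraction = tf,
      lacPyrField = lacpyr, graseMask = gMask,
      adcField = adc, dwiMask = dMask,
      histologyComposition = compositionForIndex(histIndex),
      expression = numeric(0),
      truth = truth)
}

#' Generate a seeded digital cohort
#'
#' Creates `nLow` low-grade and `nHigh` high-grade ground-truth lesions
#' whose ROI-level pH, Lac/Pyr and ADC statistics follow the group
#' distributions in `groupStats`. Two draw schemes are available:
#'
#' * `"quantile"` (default): lesion-level means are placed at the
#'   symmetric normal quantiles `(i - 0.5)/n` of the group distribution,
#'   so the cohort's group mean equals the target exactly and its SD is
#'   close to the target. This makes a small digital cohort *embody* the
#'   group statistics it is parameterized by rather than merely sampling
#'   them (a 5-lesion i.i.d. draw would scatter the group mean with
#'   sd \eqn{\sigma/\sqrt{5}}).
#' * `"random"`: i.i.d. normal draws, for experiments where cohort-to-
#'   cohort variability is itself the object of study (e.g. effect-size
#'   distributions).
#'
#' Each lesion's within-ROI pH profile is a fixed zero-mean pattern scaled
#' so the ROI minimum sits `minDrop` pH units below the ROI mean
#' (grade-specific, matching the published mean-to-minimum gaps).
#' Histology compositions are drawn so indices fall clearly on each side
#' of the dichotomization cutoff of 2 (low-grade poor-fraction 0;
#' high-grade poor-fraction > 2/3). When `nLow` and `nHigh` are both
#' at least `nSharedMice`, that many mice carry one lesion of each grade,
#' mirroring mixed tumors.
#'
#' @param nLow,nHigh non-negative lesion counts per grade.
#' @param params an [AcquisitionParams-class].
#' @param seed integer seed; fixed seed gives bit-identical cohorts.
#' @param groupStats group parameters, see [defaultGroupStats()].
#' @param draw `"quantile"` or `"random"`, see Details.
#' @param nSharedMice mice carrying both one low- and one high-grade
#'   lesion (default 2, reduced if the cohort is too small).
#' @param fillExpression logical, run [simulateExpression()] per lesion.
#' @return list of [GroundTruthLesion-class] objects, low grade first.
#' @examples
#' cohort <- generateCohort(5, 7, acquisitionParams(), seed = 1)
#' length(cohort)
#' @export
generateCohort <- function(nLow, nHigh, params = acquisitionParams(),
                           seed = 1L, groupStats = defaultGroupStats(),
                           draw = c("quantile", "random"),
                           nSharedMice = 2L, fillExpression = TRUE) {
  stopifnot(nLow >= 0, nHigh >= 0)
  draw <- match.arg(draw)
  n <- nLow + nHigh
  if (n == 0L) return(list())

  drawMeans <- function(n, mean, sd) {
    if (n == 0L) return(numeric(0))
    if (draw == "quantile") {
      stats::qnorm((seq_len(n) - 0.5) / n, mean = mean, sd = sd)
    } else {
      stats::rnorm(n, mean = mean, sd = sd)
    }
  }

  withSeed(deriveSeed(seed, 0L), {
    gs <- groupStats
    grades <- c(rep("low", nLow), rep("high", nHigh))
    phMeans <- c(drawMeans(nLow, gs$low$meanPH, gs$low$sdPH),
                 drawMeans(nHigh, gs$high$meanPH, gs$high$sdPH))
    lpMeans <- c(drawMeans(nLow, gs$low$meanLacPyr, gs$low$sdLacPyr),
                 drawMeans(nHigh, gs$high$meanLacPyr, gs$high$sdLacPyr))
    adMeans <- c(drawMeans(nLow, gs$low$meanADC, gs$low$sdADC),
                 drawMeans(nHigh, gs$high$meanADC, gs$high$sdADC))
    lpMeans <- pmax(lpMeans, 0.05)
    adMeans <- pmin(pmax(adMeans, 2e-4), 2.7e-3)
    histIdx <- c(stats::runif(nLow, 0.9, 1.9),
                 stats::runif(nHigh, 2.7, 2.95))

    ## mouse assignment: the last `nShared` lesions of each grade pair up
    nShared <- min(nSharedMice, nLow, nHigh)
    mouse <- character(n)
    m <- 0L
    for (i in seq_len(nLow - nShared)) mouse[i] <- sprintf("M%02d", m <- m + 1L)
    for (j in seq_len(nHigh - nShared))
      mouse[nLow + j] <- sprintf("M%02d", m <- m + 1L)
    for (k in seq_len(nShared)) {
      id <- sprintf("M%02d", m <- m + 1L)
      mouse[nLow - nShared + k] <- id
      mouse[n - nShared + k] <- id
    }

    lesions <- vector("list", n)
    for (i in seq_len(n)) {
      g <- grades[i]
      lesions[[i]] <- buildLesion(
        lesionId = sprintf("L%02d", i), mouseId = mouse[i], grade = g,
        meanPH = min(max(phMeans[i], 6.3), 7.8),
        minDrop = gs[[g]]$minDrop,
        meanLacPyr = lpMeans[i], meanADC = adMeans[i],
        histIndex = histIdx[i], params = params)
    }
    if (fillExpression) {
      for (i in seq_len(n)) {
        lesions[[i]]@expression <-
          simulateExpression(lesions[[i]], seed = deriveSeed(seed, i))
      }
    }
    lesions
  })
}

## Forward CSI model shared by the lesion and phantom simulators: given
## per-voxel bicarbonate/CO2 transverse amplitudes, build the (kx, ky, t)
## k-space FID array with complex Gaussian noise of per-component sd
## noiseSigma added independently per k-space sample.
csiForward <- function(ampBic, ampCO2, params, noiseSigma, seed) {
  nt <- params@spectralPoints
  sw <- params@spectralWidth
  tAxis <- (seq_len(nt) - 1) / sw
  decay <- exp(-tAxis / params@t2star)
  eB <- decay * exp(2i * pi * params@refOffsetBic * tAxis)
  eC <- decay * exp(2i * pi * params@refOffsetCO2 * tAxis)

  nx <- nrow(ampBic); ny <- ncol(ampBic)
  fid <- array(0i, c(nx, ny, nt))
  for (tix in seq_len(nt)) {
    img <- ampBic * eB[tix] + ampCO2 * eC[tix]
    fid[, , tix] <- fft2(img)
  }
  if (noiseSigma > 0) {
    withSeed(seed, {
      fid <- fid + complex(
        real = stats::rnorm(length(fid), sd = noiseSigma),
        imaginary = stats::rnorm(length(fid), sd = noiseSigma))
    })
  }
  new("FidGrid", data = fid, params = params,
      refFreqs = c(bic = params@refOffsetBic, co2 = params@refOffsetCO2))
}

## Per-voxel pool amplitudes implied by a pH field: B/C = 10^(pH - pKa),
## with total pool proportional to the tumor amplitude map.
poolAmplitudes <- function(ph, total, pKa = 6.17) {
  r <- 10^(ph - pKa)
  list(bic = total * r / (1 + r), co2 = total / (1 + r))
}

#' Simulate a 2D CSI acquisition of the bicarbonate/CO2 pair
#'
#' Per voxel, the bicarbonate and CO2 pool amplitudes satisfy
#' \eqn{B/C = 10^{pH - pKa}} and the observed transverse signals scale as
#' \eqn{B \sin(\theta_{bic})} and \eqn{C \sin(\theta_{CO2})} (two-band
#' excitation). Each resonance rings at its Hz offset with exponential
#' T2* decay; the spatial dimensions are Fourier encoded and complex
#' Gaussian noise of per-component sd `noiseSigma` is added independently
#' to every k-space sample.
#'
#' @param lesion a [GroundTruthLesion-class]; its `phField`,
#'   `tumorFraction` and ROI mask define the object.
#' @param params an [AcquisitionParams-class].
#' @param noiseSigma k-space noise sd (per real/imaginary component).
#' @param seed integer seed for the noise stream.
#' @param pKa bicarbonate/CO2 pKa (default 6.17).
#' @param scale overall signal scale, arbitrary units.
#' @return a [FidGrid-class].
#' @export
simulateCSI <- function(lesion, params = acquisitionParams(),
                        noiseSigma = params@noiseSigma, seed = 1L,
                        pKa = 6.17, scale = 100) {
  ph <- lesion@phField
  if (any(ph[lesion@roiMask] < 5) || any(ph[lesion@roiMask] > 9))
    stop("unphysiological pH field: values outside [5, 9]")
  amp <- scale * lesion@tumorFraction
  pools <- poolAmplitudes(ph, amp, pKa)
  csiForward(pools$bic * sin(degToRad(params@tipBic)),
             pools$co2 * sin(degToRad(params@tipCO2)),
             params, noiseSigma, seed)
}

#' Simulate a urea-phantom calibration pair for the excitation ratio
#'
#' The spherical phantom holds a single pool, and the calibration
#' measures the two-band pulse's response on that one resonance: one
#' acquisition through the bicarbonate (2.78 deg) band and one through
#' the CO2 (25 deg) band, each yielding a single peak at the respective
#' band frequency. Because the same pool and lineshape underlie both
#' acquisitions, the ratio of their peak integrals isolates the
#' excitation difference. Used by [calibrateKappa()].
#'
#' @param params an [AcquisitionParams-class].
#' @param noiseSigma k-space noise sd per component.
#' @param seed integer seed (the two acquisitions draw independent
#'   noise).
#' @param scale signal scale.
#' @return list of two [FidGrid-class] objects, `bic` and `co2`.
#' @export
simulatePhantomCSI <- function(params = acquisitionParams(),
                               noiseSigma = 0, seed = 1L, scale = 100) {
  nx <- params@csiMatrix[1]; ny <- params@csiMatrix[2]
  ## disc-shaped support
  cx <- (nx + 1) / 2; cy <- (ny + 1) / 2
  d <- outer(seq_len(nx), seq_len(ny),
             function(i, j) sqrt((i - cx)^2 + (j - cy)^2))
  amp <- scale * (d <= min(nx, ny) / 2 - 0.5)
  zero <- matrix(0, nx, ny)
  list(
    bic = csiForward(amp * sin(degToRad(params@tipBic)), zero,
                     params, noiseSigma, deriveSeed(seed, 1L)),
    co2 = csiForward(zero, amp * sin(degToRad(params@tipCO2)),
                     params, noiseSigma, deriveSeed(seed, 2L))
  )
}

#' k-space noise level realizing a target spectral peak SNR
#'
#' Computes, from a noiseless forward simulation, the k-space noise sd
#' that makes the weaker of the two reconstructed peaks reach
#' `peakSNR` relative to the per-component spectral noise sd under the
#' given apodization. Deterministic (no noise is actually drawn).
#'
#' @param lesion a [GroundTruthLesion-class].
#' @param params an [AcquisitionParams-class].
#' @param peakSNR target peak-height SNR of the weaker resonance.
#' @param apodizationHz exponential line broadening used downstream.
#' @inheritParams simulateCSI
#' @return numeric(1), k-space noise sd per component.
#' @export
csiNoiseForPeakSNR <- function(lesion, params = acquisitionParams(),
                               peakSNR = 20, apodizationHz = 10,
                               pKa = 6.17, scale = 100) {
  fid <- simulateCSI(lesion, params, noiseSigma = 0, pKa = pKa,
                     scale = scale)
  spec <- reconstructCSI(fid, apodizationHz = apodizationHz)
  peak <- function(center) {
    sel <- spec@freq >= center - 150 & spec@freq < center + 150
    apply(spec@data[, , sel, drop = FALSE], c(1, 2), max)
  }
  pb <- peak(params@refOffsetBic); pc <- peak(params@refOffsetCO2)
  pmin <- min(pmin(pb, pc)[lesion@roiMask])
  nt <- params@spectralPoints
  tAxis <- (seq_len(nt) - 1) / params@spectralWidth
  w <- exp(-pi * apodizationHz * tAxis)
  gain <- sqrt(sum(w^2) / prod(params@csiMatrix))
  pmin / (peakSNR * gain)
}

#' Simulate pyruvate and lactate metabolite volumes
#'
#' Noiseless pyruvate is `s0` inside the lesion's metabolite-grid mask and
#' lactate is `lacPyrField * pyruvate`, so the noiseless voxelwise
#' lactate/pyruvate ratio equals the ground-truth field. Rician noise
#' (magnitude of the signal plus complex Gaussian noise of per-component
#' sd `noiseSigma`) is applied to both volumes.
#'
#' @param lesion a [GroundTruthLesion-class].
#' @param params an [AcquisitionParams-class].
#' @param s0 pyruvate amplitude inside the lesion, arbitrary units.
#' @param noiseSigma per-component Gaussian noise sd.
#' @param seed integer seed.
#' @return list with numeric arrays `pyruvate` and `lactate` on the
#'   metabolite grid.
#' @export
simulateGRASE <- function(lesion, params = acquisitionParams(),
                          s0 = 100, noiseSigma = 0, seed = 1L) {
  if (any(lesion@lacPyrField < 0))
    stop("lacPyrField must be non-negative")
  pyr <- s0 * (lesion@graseMask * 1)
  lac <- lesion@lacPyrField * pyr
  withSeed(seed, {
    pyrN <- array(ricianNoise(pyr, noiseSigma), dim(pyr))
    lacN <- array(ricianNoise(lac, noiseSigma), dim(lac))
  })
  list(pyruvate = pyrN, lactate = lacN)
}

#' Simulate a multi-b-value diffusion-weighted stack
#'
#' Noiseless signal is `s0 * exp(-b * ADC)` per voxel and b-value; Rician
#' noise of per-component sd `noiseSigma` is added per sample.
#'
#' @param lesion a [GroundTruthLesion-class] (its `adcField` is used).
#' @param s0 positive signal at b = 0.
#' @param params an [AcquisitionParams-class] (its `bValues` are used).
#' @param noiseSigma per-component Gaussian noise sd.
#' @param seed integer seed.
#' @return a [DwiStack-class].
#' @export
simulateDWI <- function(lesion, s0 = 1000, params = acquisitionParams(),
                        noiseSigma = 0, seed = 1L) {
  stopifnot(s0 > 0)
  if (any(params@bValues < 0)) stop("negative b-values are not allowed")
  adc <- lesion@adcField
  nb <- length(params@bValues)
  sig <- array(0, c(dim(adc), nb))
  for (k in seq_len(nb))
    sig[, , k] <- s0 * exp(-params@bValues[k] * adc)
  withSeed(seed, {
    sig <- array(ricianNoise(sig, noiseSigma), dim(sig))
  })
  new("DwiStack", signal = sig, bValues = params@bValues)
}

#' Simulate normalized gene-expression levels for a lesion
#'
#' Mct4 follows a negative monotone dependence on the lesion's
#' ground-truth mean pH (lactate export via MCT4 tracks extracellular
#' acidification); Ldha, Mct1 and Hif1a are elevated in high-grade
#' lesions. All values are expressed relative to a housekeeping level of
#' 1.0; multiplicative log-normal noise of sd `noiseSd` (log scale) is
#' applied.
#'
#' @param lesion a [GroundTruthLesion-class].
#' @param seed integer seed.
#' @param noiseSd log-scale noise sd (0 for deterministic output).
#' @param mct4Slope positive constant controlling how steeply Mct4 rises
#'   as mean pH falls.
#' @return named numeric with elements Ldha, Mct1, Mct4, Hif1a.
#' @export
simulateExpression <- function(lesion, seed = 1L, noiseSd = 0.1,
                               mct4Slope = 3) {
  meanPH <- lesion@truth$meanPH
  stopifnot(is.finite(meanPH))
  high <- lesion@grade == "high"
  base <- c(
    Ldha = if (high) 3.0 else 1.5,
    Mct1 = if (high) 2.0 else 1.0,
    Mct4 = 2^(mct4Slope * (7.4 - meanPH)),
    Hif1a = if (high) 2.5 else 1.2
  )
  withSeed(seed, {
    base * exp(stats::rnorm(4, sd = noiseSd))
  })
}
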
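#' @include AllClasses.R csi-recon.R
NULL

#' pH calibration settings
#'
#' Bundles the excitation ratio `kappa` between the CO2 (25 deg) and
#' bicarbonate (2.78 deg) pulse bands, the bicarbonate/CO2 `pKa`, and the
#' SNR threshold. With ideal small-tip physics
#' `kappa = sin(25 deg)/sin(2.78 deg) = 8.714`; when a phantom
#' acquisition is available [calibrateKappa()] should be used instead of
#' the ideal value. The pKa default of 6.17 is the physiological
#' bicarbonate/CO2 value used throughout the hyperpolarized-bicarbonate
#' literature.
#'
#' @param kappa positive excitation/signal ratio between the two bands.
#' @param pKa pH units, in `[5.5, 7.0]`.
#' @param snrMin SNR threshold below which voxels are masked (default 3).
#' @return a list of class `PhCalibration`.
#' @export
phCalibration <- function(kappa = idealKappa(), pKa = 6.17, snrMin = 3) {
  stopifnot(kappa > 0, pKa >= 5.5, pKa <= 7.0, snrMin >= 0)
  structure(list(kappa = kappa, pKa = pKa, snrMin = snrMin),
            class = "PhCalibration")
}

#' @rdname phCalibration
#' @param tipCO2,tipBic tip angles in degrees.
#' @export
idealKappa <- function(tipCO2 = 25, tipBic = 2.78) {
  sin(degToRad(tipCO2)) / sin(degToRad(tipBic))
}

#' Calibrate the two-band excitation ratio from a phantom acquisition
#'
#' In the urea-phantom acquisition both pulse bands excite a common pool
#' (true chemical ratio 1), so the ratio of band signals isolates the
#' excitation difference: `kappa` is the mean over valid voxels of the
#' 25-degree-band signal divided by the 2.78-degree-band signal. With
#' ideal small-tip physics this equals `sin(25)/sin(2.78) = 8.714`.
#'
#' @param phantomBic [MetaboliteMap-class] from the bicarbonate
#'   (2.78 deg) band.
#' @param phantomCO2 [MetaboliteMap-class] from the CO2 (25 deg) band.
#' @param snrMin minimum SNR in both maps for a voxel to enter the mean.
#' @return numeric(1) `kappa`.
#' @export
calibrateKappa <- function(phantomBic, phantomCO2, snrMin = 3) {
  stopifnot(is(phantomBic, "MetaboliteMap"), is(phantomCO2, "MetaboliteMap"))
  ok <- phantomBic@valid & phantomCO2@valid &
    phantomBic@snr >= snrMin & phantomCO2@snr >= snrMin &
    phantomBic@values > 0
  if (!any(ok))
    stop("calibration failure: no valid phantom voxels")
  mean(phantomCO2@values[ok] / phantomBic@values[ok])
}

#' Process a phantom acquisition pair into a calibrated kappa
#'
#' Reconstructs both single-band phantom acquisitions (see
#' [simulatePhantomCSI()]), integrates each band's peak at its reference
#' offset, and calls [calibrateKappa()].
#'
#' @param phantom list with [FidGrid-class] elements `bic` and `co2`.
#' @param apodizationHz exponential line broadening, Hz.
#' @param windowHz integration window width, Hz.
#' @param snrMin minimum SNR for voxels entering the calibration mean.
#' @return numeric(1) `kappa`.
#' @export
phantomKappa <- function(phantom, apodizationHz = 10, windowHz = 300,
                         snrMin = 3) {
  oneBand <- function(fid, center) {
    spec <- reconstructCSI(fid, apodizationHz = apodizationHz)
    sigma <- estimateNoise(spec)
    nBins <- sum(spec@freq >= center - windowHz / 2 &
                   spec@freq < center + windowHz / 2)
    integratePeak(spec, center, windowHz,
                  noiseSigma = max(sigma * sqrt(nBins), 1e-300))
  }
  bic <- oneBand(phantom$bic, phantom$bic@refFreqs[["bic"]])
  co2 <- oneBand(phantom$co2, phantom$co2@refFreqs[["co2"]])
  calibrateKappa(bic, co2, snrMin = snrMin)
}

#' Compute an extracellular pH map from bicarbonate and CO2 maps
#'
#' Applies the excitation-ratio-corrected Henderson-Hasselbalch equation
#' per voxel: `pH = pKa + log10((S_bic / S_CO2) * kappa)`. Voxels are
#' valid only when both the bicarbonate and the CO2 SNR reach
#' `cal$snrMin` (default 3); failures are distinguished in the QC matrix
#' ("low_snr_bic", "low_snr_co2", "low_snr_both"). A non-positive CO2
#' signal on an otherwise valid voxel is masked with reason
#' "nonpositive_co2" rather than yielding a non-finite pH.
#'
#' @param bic,co2 co-registered [MetaboliteMap-class] objects on the same
#'   grid.
#' @param cal a [phCalibration()] list.
#' @return a [PhMap-class].
#' @export
computePH <- function(bic, co2, cal = phCalibration()) {
  stopifnot(is(bic, "MetaboliteMap"), is(co2, "MetaboliteMap"))
  if (!all(dim(bic@values) == dim(co2@values)))
    stop("bicarbonate and CO2 maps must share a grid")
  d <- dim(bic@values)
  okB <- bic@snr >= cal$snrMin
  okC <- co2@snr >= cal$snrMin
  qc <- matrix("ok", d[1], d[2])
  qc[!okB & okC] <- "low_snr_bic"
  qc[okB & !okC] <- "low_snr_co2"
  qc[!okB & !okC] <- "low_snr_both"
  valid <- okB & okC
  bad <- valid & co2@values <= 0
  qc[bad] <- "nonpositive_co2"
  valid[bad] <- FALSE

  ph <- matrix(NA_real_, d[1], d[2])
  ph[valid] <- cal$pKa +
    log10((bic@values[valid] / co2@values[valid]) * cal$kappa)
  nonfinite <- valid & !is.finite(ph)
  if (any(nonfinite)) {
    valid[nonfinite] <- FALSE
    qc[nonfinite] <- "nonfinite"
    ph[nonfinite] <- NA_real_
  }
  new("PhMap", ph = ph, valid = valid, snrBic = bic@snr, snrCO2 = co2@snr,
      qc = qc, calibration = list(pKa = cal$pKa, kappa = cal$kappa,
                                  snrMin = cal$snrMin))
}

#' Time for first-order bicarbonate-CO2 exchange to approach equilibrium
#'
#' For a first-order approach to equilibrium with exchange rate constant
#' `kExchange`, the time to reach a given `fraction` of equilibrium is
#' `-log(1 - fraction) / kExchange`. At the measured tumor exchange rate
#' of 1.56 per second, 95% equilibration takes about 2 seconds, which
#' bounds how soon after agent arrival the pH measurement is meaningful.
#'
#' @param kExchange exchange rate constant, 1/s (> 0).
#' @param fraction fraction of equilibrium approached, in (0, 1).
#' @return time in seconds.
#' @examples
#' exchangeEquilibrationTime(1.56, 0.95)  # ~1.92 s
#' @export
exchangeEquilibrationTime <- function(kExchange, fraction = 0.95) {
  stopifnot(kExchange > 0)
  if (fraction <= 0 || fraction >= 1)
    stop("fraction must lie strictly between 0 and 1")
  -log(1 - fraction) / kExchange
}

#' Full CSI-to-pH processing chain
#'
#' Convenience wrapper: reconstruct the raw FID grid, estimate the
#' spectral noise level from the signal-free outer spectral region,
#' integrate the bicarbonate and CO2 peaks over `+/- windowHz/2` windows
#' at their reference offsets, and compute the pH map.
#'
#' @param fid a [FidGrid-class].
#' @param cal a [phCalibration()] list.
#' @param apodizationHz exponential line broadening, Hz.
#' @param windowHz full width of each integration window, Hz.
#' @return a [PhMap-class].
#' @export
csiToPhMap <- function(fid, cal = phCalibration(), apodizationHz = 10,
                       windowHz = 300) {
  spec <- reconstructCSI(fid, apodizationHz = apodizationHz)
  sigmaPoint <- estimateNoise(spec)
  ## scale the per-point noise estimate to peak-integral units so that
  ## snr = integral / noiseSigma (sum of n samples scales noise by sqrt(n))
  nBins <- sum(spec@freq >= fid@refFreqs[["bic"]] - windowHz / 2 &
                 spec@freq < fid@refFreqs[["bic"]] + windowHz / 2)
  sigma <- sigmaPoint * sqrt(max(nBins, 1))
  bic <- integratePeak(spec, fid@refFreqs[["bic"]], windowHz,
                       noiseSigma = sigma)
  co2 <- integratePeak(spec, fid@refFreqs[["co2"]], windowHz,
                       noiseSigma = sigma)
  computePH(bic, co2, cal)
}
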
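#' @include AllClasses.R utils.R
NULL

#' Reconstruct a spatial-spectral image from raw CSI data
#'
#' Applies the inverse 2D spatial discrete Fourier transform (with 1/N
#' normalization, so a forward-encoded unit source reconstructs to unit
#' amplitude), exponential apodization of the FIDs
#' (`exp(-pi * apodizationHz * t)`), and an unnormalized spectral DFT.
#' The spectral axis is rotated to ascending Hz centered on 0. Sampling
#' is full Cartesian, so phase-encode ordering (centric in the protocol)
#' does not affect the reconstruction.
#'
#' With `magnitude = FALSE` the complex spectra are returned as a plain
#' array (useful for linearity and Parseval checks); the default returns
#' a [SpectralImage-class] of magnitudes.
#'
#' @param fid a [FidGrid-class].
#' @param apodizationHz exponential line broadening in Hz (default 10; 0
#'   disables apodization, under which Parseval's identity
#'   \eqn{\sum|S|^2 = N_t/(N_x N_y) \sum|\mathrm{fid}|^2} holds exactly).
#' @param magnitude logical; return magnitudes (default) or the complex
#'   array.
#' @return a [SpectralImage-class], or a complex array with attribute
#'   `freq` when `magnitude = FALSE`.
#' @export
reconstructCSI <- function(fid, apodizationHz = 10, magnitude = TRUE) {
  stopifnot(is(fid, "FidGrid"))
  p <- fid@params
  d <- dim(fid@data)
  if (!all(d == c(p@csiMatrix, p@spectralPoints)))
    stop("FID dimensions do not match acquisition parameters")
  nx <- d[1]; ny <- d[2]; nt <- d[3]
  sw <- p@spectralWidth
  tAxis <- (seq_len(nt) - 1) / sw
  w <- exp(-pi * apodizationHz * tAxis)

  ## spatial inverse DFT per time point
  img <- array(0i, d)
  for (tix in seq_len(nt))
    img[, , tix] <- ifft2(fid@data[, , tix])

  ## apodize and transform the spectral dimension: reshape to (space, t)
  m <- matrix(img, nrow = nx * ny, ncol = nt)
  m <- sweep(m, 2, w, `*`)
  spec <- stats::mvfft(t(m))        # (freq bins 0..nt-1, space)

  ## rotate to an ascending axis centered on 0 Hz
  half <- nt %/% 2
  ord <- c((half + 1):nt, 1:half)   # negative frequencies first
  freq <- ((seq_len(nt) - 1 - half) * sw) / nt
  spec <- spec[ord, , drop = FALSE]
  out <- array(t(spec), c(nx, ny, nt))

  if (!magnitude) {
    attr(out, "freq") <- freq
    return(out)
  }
  new("SpectralImage", data = abs(out) * 1, freq = freq, params = p)
}

#' Integrate a spectral peak into a metabolite map
#'
#' Sums magnitude over the half-open frequency window
#' `[centerHz - windowHz/2, centerHz + windowHz/2)` per voxel. When a
#' noise level is supplied the per-voxel SNR (`value / noiseSigma`) and a
#' validity mask at `snrMin` are filled in; otherwise all voxels are
#' valid and SNR is infinite.
#'
#' @param spec a [SpectralImage-class].
#' @param centerHz window center, Hz.
#' @param windowHz window width, Hz (> 0, within the spectral axis).
#' @param noiseSigma noise scale in the same units as the integral (e.g.
#'   from [estimateNoise()]); `NA` to skip SNR bookkeeping.
#' @param snrMin SNR threshold applied to the validity mask (default 0 =
#'   keep everything; downstream consumers apply their own thresholds).
#' @return a [MetaboliteMap-class].
#' @export
integratePeak <- function(spec, centerHz, windowHz, noiseSigma = NA_real_,
                          snrMin = 0) {
  stopifnot(is(spec, "SpectralImage"))
  if (windowHz <= 0) stop("window width must be positive")
  lo <- centerHz - windowHz / 2
  hi <- centerHz + windowHz / 2
  fr <- spec@freq
  if (lo < min(fr) || hi > max(fr) + (fr[2] - fr[1]))
    stop("integration window lies outside the spectral axis")
  sel <- fr >= lo & fr < hi
  if (!any(sel)) stop("integration window captures no spectral points")
  vals <- apply(spec@data[, , sel, drop = FALSE], c(1, 2), sum)
  sigma <- if (is.na(noiseSigma)) 0 else noiseSigma
  snr <- if (sigma > 0) vals / sigma else
    matrix(Inf, nrow(vals), ncol(vals))
  valid <- snr >= snrMin
  p <- spec@params
  new("MetaboliteMap", values = vals, noiseSigma = sigma, snr = snr,
      valid = valid, spacing = p@csiFov / p@csiMatrix)
}

#' Estimate the spectral noise level from a signal-free region
#'
#' Robust scale estimate (median absolute deviation times 1.4826) of the
#' magnitude samples inside a signal-free frequency interval, pooled
#' across all voxels. The default region is the outermost 10% of the
#' spectral axis on both ends. At least 16 pooled samples are required.
#'
#' @param spec a [SpectralImage-class].
#' @param region numeric(2) Hz interval, or `NULL` for the default outer
#'   10% of the axis (both ends).
#' @param peakWindows optional list of `c(centerHz, windowHz)` pairs; an
#'   error is raised if the region overlaps any of them.
#' @return numeric(1) noise scale in magnitude units.
#' @export
estimateNoise <- function(spec, region = NULL, peakWindows = NULL) {
  stopifnot(is(spec, "SpectralImage"))
  fr <- spec@freq
  if (is.null(region)) {
    span <- diff(range(fr))
    sel <- fr <= min(fr) + 0.1 * span | fr >= max(fr) - 0.1 * span
  } else {
    stopifnot(length(region) == 2, region[1] < region[2])
    sel <- fr >= region[1] & fr <= region[2]
  }
  if (!is.null(peakWindows)) {
    for (wdef in peakWindows) {
      lo <- wdef[1] - wdef[2] / 2; hi <- wdef[1] + wdef[2] / 2
      if (any(sel & fr >= lo & fr < hi))
        stop("noise region overlaps a peak window")
    }
  }
  samples <- as.vector(spec@data[, , sel, drop = FALSE])
  if (length(samples) < 16)
    stop("noise region must contain at least 16 pooled samples")
  stats::mad(samples, constant = 1.4826)
}
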
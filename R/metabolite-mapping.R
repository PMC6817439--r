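#' @include AllClasses.R utils.R
NULL

#' Collapse a metabolite volume onto a CSI-matched slab
#'
#' Unweighted mean of all axial slices whose centers fall within the slab
#' `[slabCenter - slabThickness/2, slabCenter + slabThickness/2)`
#' (half-open on the superior edge). Slice centers sit at
#' `(k - 0.5) * fovZ / nz` from the inferior edge of the volume.
#'
#' @param volume numeric 3D array (x, y, z).
#' @param slabCenter slab center in mm from the inferior FOV edge.
#' @param slabThickness slab thickness in mm.
#' @param fovZ through-plane FOV in mm.
#' @return numeric matrix (x, y); attribute `nSlices` records how many
#'   slices were averaged.
#' @export
matchSlices <- function(volume, slabCenter, slabThickness, fovZ = 40) {
  stopifnot(length(dim(volume)) == 3, slabThickness > 0)
  nz <- dim(volume)[3]
  centers <- (seq_len(nz) - 0.5) * fovZ / nz
  lo <- slabCenter - slabThickness / 2
  hi <- slabCenter + slabThickness / 2
  sel <- centers >= lo & centers < hi
  if (!any(sel))
    stop("slab captures no slices")
  out <- apply(volume[, , sel, drop = FALSE], c(1, 2), mean)
  attr(out, "nSlices") <- sum(sel)
  out
}

#' Fourier (zero-fill) regridding of a 2D map
#'
#' Interpolates a map onto a finer in-plane grid by zero-filling its 2D
#' discrete Fourier spectrum, preserving the point-spread behavior of the
#' k-space-limited acquisition. Nyquist rows/columns of even-sized inputs
#' are split symmetrically so real inputs stay real and band-limited
#' inputs are interpolated exactly. Intensities are preserved (a constant
#' map stays constant), hence total signal times voxel area is conserved.
#'
#' @param map2d numeric matrix.
#' @param fov numeric(2) (or scalar) field of view in mm.
#' @param targetSpacing target voxel spacing in mm; must divide the FOV
#'   to within 1e-8 and not be coarser than the native spacing.
#' @return numeric matrix on the target grid.
#' @export
regridInplane <- function(map2d, fov, targetSpacing) {
  stopifnot(is.matrix(map2d), targetSpacing > 0)
  fov <- rep(fov, length.out = 2)
  nC <- dim(map2d)
  nF <- fov / targetSpacing
  if (any(abs(nF - round(nF)) > 1e-8))
    stop("target spacing does not divide the field of view")
  nF <- as.integer(round(nF))
  if (any(nF < nC)) stop("target grid must be at least as fine as native")
  if (all(nF == nC)) return(map2d)

  padAxis <- function(F, nc, nf, margin) {
    ## redistribute DFT coefficients of length nc onto length nf along
    ## `margin`, splitting the Nyquist coefficient of even nc
    idx <- function(n) c(0:(ceiling(n / 2) - 1), -(floor(n / 2)):-1)
    src <- idx(nc)
    out <- if (margin == 1) matrix(0i, nf, ncol(F)) else
      matrix(0i, nrow(F), nf)
    for (k in seq_len(nc)) {
      f <- src[k]
      targets <- f
      wgt <- 1
      if (nc %% 2 == 0 && f == -nc / 2) {
        targets <- c(-nc / 2, nc / 2); wgt <- 0.5
      }
      for (tf in targets) {
        pos <- (tf %% nf) + 1
        if (margin == 1) out[pos, ] <- out[pos, ] + wgt * F[k, ]
        else out[, pos] <- out[, pos] + wgt * F[, k]
      }
    }
    out
  }

  F <- fft2(map2d + 0i)
  F <- padAxis(F, nC[1], nF[1], margin = 1)
  F <- padAxis(F, nC[2], nF[2], margin = 2)
  fine <- Re(ifft2(F)) * (prod(nF) / prod(nC))
  fine
}

#' Lactate-to-pyruvate ratio map with asymmetric SNR rules
#'
#' Lactate voxels with SNR below `snrMinLac` (default 4) are masked
#' invalid. Pyruvate voxels with SNR below `snrMinPyr` (default 4) are
#' not masked: their value is replaced by the mean noise magnitude (the
#' Rayleigh mean `sigma * sqrt(pi/2)` of the pyruvate map's noise level)
#' before division, so the ratio is never infinite. The ratio is
#' lactate/pyruvate on valid voxels.
#'
#' @param lac,pyr [MetaboliteMap-class] objects on a common grid; their
#'   `noiseSigma` slots must hold the Gaussian per-component noise sd of
#'   the magnitude volumes (see [estimateVolumeNoise()]).
#' @param snrMinLac,snrMinPyr SNR thresholds.
#' @return a [LacPyrMap-class].
#' @export
lacPyrRatio <- function(lac, pyr, snrMinLac = 4, snrMinPyr = 4) {
  stopifnot(is(lac, "MetaboliteMap"), is(pyr, "MetaboliteMap"))
  if (!all(dim(lac@values) == dim(pyr@values)))
    stop("lactate and pyruvate maps must share a grid")
  floorVal <- rayleighMean(pyr@noiseSigma)
  lowPyr <- pyr@snr < snrMinPyr
  if (floorVal <= 0 && any(lowPyr & pyr@values <= 0))
    stop("zero noise level with non-positive pyruvate: ratio floor undefined")
  pyrAdj <- pyr@values
  pyrAdj[lowPyr] <- floorVal
  valid <- lac@valid & lac@snr >= snrMinLac & pyrAdj > 0
  ratio <- matrix(NA_real_, nrow(lac@values), ncol(lac@values))
  ratio[valid] <- lac@values[valid] / pyrAdj[valid]
  ratio[valid] <- pmax(ratio[valid], 0)
  new("LacPyrMap", ratio = ratio, valid = valid,
      snrLac = lac@snr, snrPyr = pyr@snr, pyrFloor = floorVal)
}

#' Gaussian-equivalent noise level of a magnitude volume
#'
#' Estimates the per-component Gaussian sd underlying Rician/Rayleigh
#' magnitude noise from a signal-free corner of the volume, using the
#' Rayleigh second moment `E[m^2] = 2 sigma^2`.
#'
#' @param volume numeric array of magnitudes.
#' @param corner integer edge length of the signal-free corner block
#'   sampled from the first corner of every dimension.
#' @return numeric(1) Gaussian per-component sd.
#' @export
estimateVolumeNoise <- function(volume, corner = 3L) {
  d <- dim(volume)
  idx <- lapply(d, function(n) seq_len(min(corner, n)))
  m <- do.call(`[`, c(list(volume), idx))
  sqrt(mean(m^2) / 2)
}

#' Build a MetaboliteMap from a magnitude image
#'
#' Thin constructor pairing a 2D magnitude image with a Gaussian noise
#' level; SNR is `value / noiseSigma`.
#'
#' @param values numeric matrix.
#' @param noiseSigma Gaussian per-component noise sd (0 for noiseless).
#' @param spacing numeric(2) voxel spacing in mm.
#' @return a [MetaboliteMap-class].
#' @export
metaboliteMap <- function(values, noiseSigma = 0, spacing = c(2, 2)) {
  snr <- if (noiseSigma > 0) values / noiseSigma else
    matrix(Inf, nrow(values), ncol(values))
  new("MetaboliteMap", values = values, noiseSigma = noiseSigma,
      snr = snr, valid = is.finite(values), spacing = rep(spacing, length.out = 2))
}

#' Metabolite volumes to a slab-matched Lac/Pyr map
#'
#' Pipeline wrapper: slab-match both metabolite volumes to the CSI slice,
#' optionally regrid in-plane to `targetSpacing`, estimate the noise
#' level from a signal-free corner of each raw volume, and apply the
#' asymmetric SNR rules of [lacPyrRatio()].
#'
#' @param pyruvate,lactate numeric 3D magnitude arrays.
#' @param params an [AcquisitionParams-class].
#' @param slabCenter slab center in mm (default: volume center).
#' @param targetSpacing in-plane spacing in mm, or `NULL` to stay on the
#'   native grid.
#' @inheritParams lacPyrRatio
#' @return a [LacPyrMap-class].
#' @export
graseToLacPyrMap <- function(pyruvate, lactate, params = acquisitionParams(),
                             slabCenter = params@graseFov[3] / 2,
                             targetSpacing = NULL,
                             snrMinLac = 4, snrMinPyr = 4) {
  fovZ <- params@graseFov[3]
  sigPyr <- estimateVolumeNoise(pyruvate)
  sigLac <- estimateVolumeNoise(lactate)
  pyr2d <- matchSlices(pyruvate, slabCenter, params@csiSliceThickness, fovZ)
  lac2d <- matchSlices(lactate, slabCenter, params@csiSliceThickness, fovZ)
  nAvg <- attr(pyr2d, "nSlices")
  ## averaging n slices reduces the Gaussian component sd by sqrt(n)
  sigPyr <- sigPyr / sqrt(nAvg)
  sigLac <- sigLac / sqrt(nAvg)
  spacing <- params@graseFov[1:2] / params@graseMatrix[1:2]
  if (!is.null(targetSpacing)) {
    pyr2d <- regridInplane(pyr2d, params@graseFov[1:2], targetSpacing)
    lac2d <- regridInplane(lac2d, params@graseFov[1:2], targetSpacing)
    spacing <- c(targetSpacing, targetSpacing)
  }
  lacPyrRatio(metaboliteMap(lac2d, sigLac, spacing),
              metaboliteMap(pyr2d, sigPyr, spacing),
              snrMinLac = snrMinLac, snrMinPyr = snrMinPyr)
}
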
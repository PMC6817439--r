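#' @include AllClasses.R
NULL

#' Construct acquisition parameters
#'
#' User-facing constructor for [AcquisitionParams-class]. Defaults encode
#' the multiparametric preclinical protocol: 2D CSI of the bicarbonate/CO2
#' pair (8 x 8 x 256 matrix, 32 x 32 mm^2 FOV, 8013 Hz spectral width,
#' 6.5 mm slab, two-band excitation at 25 deg for CO2 and 2.78 deg for
#' bicarbonate), a 12 x 12 x 16 pyruvate/lactate volume over
#' 40 x 40 x 40 mm^3, and diffusion imaging at b = 0, 170, 340, 515
#' s/mm^2. The bicarbonate and CO2 resonances are placed symmetrically at
#' +/- 2000 Hz: only their separation (well in excess of the linewidth)
#' matters for peak integration. The apparent transverse decay constant
#' defaults to 20 ms, which resolves both peaks at 256 points over
#' 8013 Hz.
#'
#' @param csiMatrix integer(2), CSI matrix size.
#' @param spectralPoints integer(1), FID length.
#' @param spectralWidth numeric(1), Hz.
#' @param fieldStrength numeric(1), 13C frequency in MHz.
#' @param csiFov numeric(2), mm.
#' @param csiSliceThickness numeric(1), mm (6.5 or 10 in the protocol).
#' @param tipCO2,tipBic numeric(1), degrees, in (0, 90).
#' @param bValues numeric, s/mm^2, ascending from 0.
#' @param graseMatrix integer(3).
#' @param graseFov numeric(3), mm.
#' @param dwiMatrix integer(2), in-plane diffusion matrix.
#' @param refOffsetBic,refOffsetCO2 numeric(1), Hz offsets of the two
#'   resonances.
#' @param t2star numeric(1), seconds.
#' @param noiseSigma numeric(1), default noise sd in signal units.
#' @param seed integer(1), base seed stored as acquisition metadata.
#' @return an [AcquisitionParams-class] object.
#' @examples
#' p <- acquisitionParams()
#' p
#' @export
acquisitionParams <- function(csiMatrix = c(8L, 8L),
                              spectralPoints = 256L,
                              spectralWidth = 8013,
                              fieldStrength = 150,
                              csiFov = c(32, 32),
                              csiSliceThickness = 6.5,
                              tipCO2 = 25,
                              tipBic = 2.78,
                              bValues = c(0, 170, 340, 515),
                              graseMatrix = c(12L, 12L, 16L),
                              graseFov = c(40, 40, 40),
                              dwiMatrix = c(16L, 16L),
                              refOffsetBic = 2000,
                              refOffsetCO2 = -2000,
                              t2star = 0.020,
                              noiseSigma = 0,
                              seed = 1L) {
  if (any(csiMatrix <= 0) || any(graseMatrix <= 0) || any(dwiMatrix <= 0) ||
      spectralPoints <= 0)
    stop("matrix sizes must be positive")
  new("AcquisitionParams",
      csiMatrix = as.integer(csiMatrix),
      spectralPoints = as.integer(spectralPoints),
      spectralWidth = as.numeric(spectralWidth),
      fieldStrength = as.numeric(fieldStrength),
      csiFov = as.numeric(csiFov),
      csiSliceThickness = as.numeric(csiSliceThickness),
      tipCO2 = as.numeric(tipCO2),
      tipBic = as.numeric(tipBic),
      bValues = as.numeric(bValues),
      graseMatrix = as.integer(graseMatrix),
      graseFov = as.numeric(graseFov),
      dwiMatrix = as.integer(dwiMatrix),
      refOffsetBic = as.numeric(refOffsetBic),
      refOffsetCO2 = as.numeric(refOffsetCO2),
      t2star = as.numeric(t2star),
      noiseSigma = as.numeric(noiseSigma),
      seed = as.integer(seed))
}
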
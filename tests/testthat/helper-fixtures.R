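# Shared fixtures: a small acquisition geometry for fast spectral tests
# and constructors for hand-built maps.

smallParams <- function(...) {
  acquisitionParams(csiMatrix = c(4L, 4L), spectralPoints = 128L,
                    graseMatrix = c(6L, 6L, 8L), dwiMatrix = c(8L, 8L),
                    ...)
}

# MetaboliteMap with prescribed values and SNR (noiseSigma chosen to
# realize the SNR for the given values)
mapWithSNR <- function(values, snr) {
  sig <- values[1] / snr[1]
  new("MetaboliteMap", values = values, noiseSigma = sig,
      snr = snr, valid = matrix(TRUE, nrow(values), ncol(values)),
      spacing = c(4, 4))
}

uniformMap <- function(value, snrValue, n = 2) {
  vals <- matrix(value, n, n)
  snr <- matrix(snrValue, n, n)
  mapWithSNR(vals, snr)
}

# one default-geometry lesion with overridable ROI-mean pH
testLesion <- function(meanPH = 7.4, minDrop = 0.1, grade = "low",
                       meanLacPyr = 1.0, meanADC = 1.2e-3,
                       histIndex = 1.5, params = acquisitionParams()) {
  hp13cmri:::buildLesion("L01", "M01", grade, meanPH, minDrop,
                         meanLacPyr, meanADC, histIndex, params)
}
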
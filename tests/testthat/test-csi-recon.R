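# CSI reconstruction against a brute-force DFT oracle, peak integration,
# and robust noise estimation.

# naive 3-loop discrete Fourier transform oracle: inverse 2D spatial DFT
# (1/N normalized) followed by a forward spectral DFT, then the fftshift
# reordering used by the reconstruction
naiveRecon <- function(fid) {
  d <- dim(fid@data)
  nx <- d[1]; ny <- d[2]; nt <- d[3]
  img <- array(0i, d)
  for (x in 1:nx) for (y in 1:ny) for (tt in 1:nt) {
    acc <- 0i
    for (kx in 1:nx) for (ky in 1:ny) {
      acc <- acc + fid@data[kx, ky, tt] *
        exp(2i * pi * ((kx - 1) * (x - 1) / nx + (ky - 1) * (y - 1) / ny))
    }
    img[x, y, tt] <- acc / (nx * ny)
  }
  spec <- array(0i, d)
  for (x in 1:nx) for (y in 1:ny) for (f in 1:nt) {
    acc <- 0i
    for (tt in 1:nt)
      acc <- acc + img[x, y, tt] * exp(-2i * pi * (f - 1) * (tt - 1) / nt)
    spec[x, y, f] <- acc
  }
  half <- nt %/% 2
  spec[, , c((half + 1):nt, 1:half)]
}

fidFromArray <- function(arr, params) {
  new("FidGrid", data = arr, params = params,
      refFreqs = c(bic = params@refOffsetBic, co2 = params@refOffsetCO2))
}

test_that("reconstruction matches the brute-force DFT oracle", {
  p <- acquisitionParams(csiMatrix = c(4L, 4L), spectralPoints = 32L)
  set.seed(1)
  arr <- array(complex(real = rnorm(4 * 4 * 32),
                       imaginary = rnorm(4 * 4 * 32)), c(4, 4, 32))
  fid <- fidFromArray(arr, p)
  fast <- reconstructCSI(fid, apodizationHz = 0, magnitude = FALSE)
  slow <- naiveRecon(fid)
  expect_lt(max(abs(fast - slow)) / max(abs(slow)), 1e-8)
})

test_that("point source localizes to its voxel and zero maps to zero", {
  p <- acquisitionParams(csiMatrix = c(4L, 4L), spectralPoints = 32L)
  nx <- 4; nt <- 32
  # forward-encode a delta at voxel (2, 3) carrying a pure tone
  tone <- exp(2i * pi * 3 * (0:(nt - 1)) / nt)
  arr <- array(0i, c(nx, nx, nt))
  for (kx in 1:nx) for (ky in 1:nx)
    arr[kx, ky, ] <- tone *
      exp(-2i * pi * ((kx - 1) * (2 - 1) / nx + (ky - 1) * (3 - 1) / nx))
  spec <- reconstructCSI(fidFromArray(arr, p), apodizationHz = 0)
  tot <- apply(spec@data, c(1, 2), sum)
  expect_identical(which(tot == max(tot), arr.ind = TRUE)[1, ],
                   c(row = 2L, col = 3L))
  expect_gt(max(tot), 100 * sort(tot, decreasing = TRUE)[2])
  zero <- reconstructCSI(fidFromArray(array(0i, c(nx, nx, nt)), p))
  expect_true(all(zero@data == 0))
})

test_that("reconstruction is linear before the magnitude and conserves energy", {
  p <- acquisitionParams(csiMatrix = c(4L, 4L), spectralPoints = 32L)
  set.seed(2)
  mk <- function() array(complex(real = rnorm(512), imaginary = rnorm(512)),
                         c(4, 4, 32))
  X <- mk(); Y <- mk()
  rx <- reconstructCSI(fidFromArray(X, p), 0, magnitude = FALSE)
  ry <- reconstructCSI(fidFromArray(Y, p), 0, magnitude = FALSE)
  rxy <- reconstructCSI(fidFromArray(2 * X + 3i * Y, p), 0,
                        magnitude = FALSE)
  expect_equal(rxy, 2 * rx + 3i * ry, tolerance = 1e-10,
               ignore_attr = TRUE)
  # Parseval: sum |S|^2 = Nt / (Nx Ny) * sum |fid|^2 without apodization
  expect_equal(sum(abs(rx)^2), 32 / 16 * sum(abs(X)^2), tolerance = 1e-10)
})

test_that("peak integration windows behave as half-open sums", {
  p <- smallParams()
  l <- testLesion(params = p)
  spec <- reconstructCSI(simulateCSI(l, p, noiseSigma = 0))
  sw <- p@spectralWidth
  whole <- integratePeak(spec, 0, sw)  # whole-axis window
  expect_equal(whole@values, apply(spec@data, c(1, 2), sum),
               tolerance = 1e-12)
  # additivity over disjoint windows covering the axis
  lowHalf <- integratePeak(spec, -sw / 4, sw / 2)
  highHalf <- integratePeak(spec, sw / 4, sw / 2)
  expect_equal(lowHalf@values + highHalf@values, whole@values,
               tolerance = 1e-9)
  expect_error(integratePeak(spec, 0, 0), "positive")
  expect_error(integratePeak(spec, sw, 400), "outside")
})

test_that("two-peak integrals are proportional to pool amplitude times sin(tip)", {
  p <- acquisitionParams()
  l <- testLesion(meanPH = 7.3, params = p)
  spec <- reconstructCSI(simulateCSI(l, p, noiseSigma = 0, pKa = 6.17))
  bic <- integratePeak(spec, p@refOffsetBic, 300)
  co2 <- integratePeak(spec, p@refOffsetCO2, 300)
  # forward-model oracle per ROI voxel
  pools <- hp13cmri:::poolAmplitudes(l@phField, 100 * l@tumorFraction, 6.17)
  expected <- (pools$bic * sin(2.78 * pi / 180)) /
    (pools$co2 * sin(25 * pi / 180))
  measured <- bic@values / co2@values
  rel <- abs(measured[l@roiMask] / expected[l@roiMask] - 1)
  expect_lt(max(rel), 0.01)
})

test_that("noise estimate is Rayleigh-consistent and scales linearly", {
  p <- acquisitionParams()
  nx <- p@csiMatrix[1]; nt <- p@spectralPoints
  mkNoise <- function(sigmaK, seed) {
    set.seed(seed)
    arr <- array(complex(real = rnorm(nx * nx * nt, sd = sigmaK),
                         imaginary = rnorm(nx * nx * nt, sd = sigmaK)),
                 c(nx, nx, nt))
    reconstructCSI(fidFromArray(arr, p), apodizationHz = 0)
  }
  # per-component spectral noise sd implied by the transform conventions
  sigmaF <- function(sigmaK) sigmaK * sqrt(nt / (nx * nx))
  # independent oracle: 1.4826 * MAD of a Rayleigh(sigma) variate,
  # from its quantile function
  rayleighQ <- function(p, sigma) sigma * sqrt(-2 * log(1 - p))
  med <- rayleighQ(0.5, 1)
  madR <- uniroot(function(a) {
    pr <- function(x) 1 - exp(-x^2 / 2)
    pr(med + a) - pr(max(med - a, 0)) - 0.5
  }, c(0.01, 2))$root
  oracle <- function(sigma) 1.4826 * madR * sigma

  est1 <- estimateNoise(mkNoise(1, 1))
  expect_equal(est1, oracle(sigmaF(1)), tolerance = 0.1)
  est2 <- estimateNoise(mkNoise(2, 2))
  expect_equal(est2 / est1, 2, tolerance = 0.1)
  # zero input estimates zero
  zero <- reconstructCSI(fidFromArray(array(0i, c(nx, nx, nt)), p))
  expect_identical(estimateNoise(zero), 0)
  # guard rails
  expect_error(
    estimateNoise(mkNoise(1, 3), region = c(1500, 2500),
                  peakWindows = list(c(2000, 300))),
    "overlaps")
})
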
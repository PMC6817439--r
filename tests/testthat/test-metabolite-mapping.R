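# Slab matching, Fourier regridding and the asymmetric SNR rules of the
# Lac/Pyr ratio map.

test_that("slab matching averages exactly the slices whose centers fall inside", {
  vol <- array(0, c(2, 2, 4))
  vol[, , 2] <- 4; vol[, , 3] <- 6
  # 4 slices over 40 mm: centers at 5, 15, 25, 35 mm
  out <- matchSlices(vol, slabCenter = 20, slabThickness = 20, fovZ = 40)
  expect_equal(unique(as.vector(out)), 5)
  expect_identical(attr(out, "nSlices"), 2L)
  single <- matchSlices(vol, 15, 10, fovZ = 40)
  expect_equal(unname(single[1, 1]), 4)
  expect_error(matchSlices(vol, 120, 5, fovZ = 40), "no slices")
})

test_that("slab capture count matches brute-force center enumeration", {
  nz <- 16; fovZ <- 40; thick <- 6.5
  vol <- array(1, c(2, 2, nz))
  centers <- (seq_len(nz) - 0.5) * fovZ / nz
  for (sc in seq(5, 35, by = 1.3)) {
    expected <- sum(centers >= sc - thick / 2 & centers < sc + thick / 2)
    if (expected == 0) {
      expect_error(matchSlices(vol, sc, thick, fovZ), "no slices")
    } else {
      out <- matchSlices(vol, sc, thick, fovZ)
      expect_identical(attr(out, "nSlices"), expected)
      expect_equal(expected, as.integer(expected))  # 2 or 3 in range
    }
  }
})

test_that("Fourier regridding preserves constants, identity and peaks", {
  cst <- matrix(5, 12, 12)
  out <- regridInplane(cst, 40, 2)
  expect_equal(dim(out), c(20L, 20L))
  expect_equal(range(out), c(5, 5), tolerance = 1e-10)

  set.seed(1)
  m <- matrix(rnorm(144), 12, 12)
  expect_equal(regridInplane(m, 40, 40 / 12), m, tolerance = 1e-10)

  hot <- matrix(0, 12, 12); hot[5, 8] <- 10
  fine <- regridInplane(hot, 40, 2)
  pk <- which(fine == max(fine), arr.ind = TRUE)[1, ]
  # native center (4.5, 7.5)*(40/12) mm -> fine voxel index within 1
  expect_lt(abs(pk[1] - (4.5 * 20 / 12 + 0.5)), 1.01)
  expect_lt(abs(pk[2] - (7.5 * 20 / 12 + 0.5)), 1.01)
  # total signal x voxel area conserved
  expect_equal(sum(fine) * 2^2, sum(hot) * (40 / 12)^2, tolerance = 1e-9)

  # band-limited input is interpolated exactly at coincident sample
  # positions (DFT convention: sample i sits at (i-1)/N of the period)
  ii <- (seq_len(12) - 1) / 12
  bl <- outer(ii, ii, function(x, y) 3 + cos(2 * pi * x) + sin(2 * pi * y))
  fineBl <- regridInplane(bl, 12, 0.5)  # 12 -> 24: odd fine samples coincide
  expect_equal(fineBl[seq(1, 24, by = 2), seq(1, 24, by = 2)], bl,
               tolerance = 1e-9)

  expect_error(regridInplane(m, 40, 3), "does not divide")
})

test_that("lactate SNR rule masks and pyruvate floor substitutes", {
  # lactate SNR 3.9 -> voxel invalid
  lp <- lacPyrRatio(uniformMap(39, 3.9), uniformMap(20, 10))
  expect_false(any(lp@valid))
  # plain division when both SNRs pass
  lp2 <- lacPyrRatio(uniformMap(80, 8), uniformMap(20, 10))
  expect_equal(lp2@ratio[1, 1], 4.0)
  # pyruvate SNR 2 with floor 5: sigma chosen so sigma*sqrt(pi/2) = 5
  sig <- 5 / sqrt(pi / 2)
  pyr <- new("MetaboliteMap", values = matrix(sig * 2, 2, 2),
             noiseSigma = sig, snr = matrix(2, 2, 2),
             valid = matrix(TRUE, 2, 2), spacing = c(2, 2))
  lp3 <- lacPyrRatio(uniformMap(40, 8), pyr)
  expect_equal(lp3@ratio[1, 1], 8.0, tolerance = 1e-12)
  expect_equal(lp3@pyrFloor, 5, tolerance = 1e-12)
  # never infinite or negative
  expect_true(all(is.finite(lp3@ratio[lp3@valid])))
  expect_true(all(lp3@ratio[lp3@valid] >= 0))
  # zero noise with zero pyruvate is undefined
  pyr0 <- new("MetaboliteMap", values = matrix(0, 2, 2), noiseSigma = 0,
              snr = matrix(0, 2, 2), valid = matrix(TRUE, 2, 2),
              spacing = c(2, 2))
  expect_error(lacPyrRatio(uniformMap(40, 8), pyr0), "undefined")
})

test_that("the pyruvate floor equals the Rayleigh mean by Monte Carlo", {
  set.seed(5)
  sigma <- 3
  mags <- sqrt(rnorm(1e4, sd = sigma)^2 + rnorm(1e4, sd = sigma)^2)
  expect_equal(mean(mags), sigma * sqrt(pi / 2), tolerance = 0.02)
  vol <- array(mags[1:64], c(4, 4, 4))
  expect_equal(estimateVolumeNoise(vol, corner = 4), sigma,
               tolerance = 0.2)
})

test_that("ratio map is invariant to a common positive rescaling", {
  lac <- uniformMap(60, 8); pyr <- uniformMap(20, 10)
  a <- lacPyrRatio(lac, pyr)
  scaleMap <- function(m, c) {
    new("MetaboliteMap", values = m@values * c,
        noiseSigma = m@noiseSigma * c, snr = m@snr,
        valid = m@valid, spacing = m@spacing)
  }
  b <- lacPyrRatio(scaleMap(lac, 7), scaleMap(pyr, 7))
  expect_equal(a@ratio, b@ratio, tolerance = 1e-12)
  expect_identical(a@valid, b@valid)
})

test_that("noiseless volumes recover the ratio field end to end", {
  p <- acquisitionParams()
  l <- testLesion(meanLacPyr = 1.4, params = p)
  vols <- simulateGRASE(l, p, s0 = 100, noiseSigma = 0)
  lp <- graseToLacPyrMap(vols$pyruvate, vols$lactate, p)
  foot <- apply(l@graseMask, c(1, 2), any)
  truth2d <- apply(l@lacPyrField, c(1, 2), max)  # constant across z
  err <- abs(lp@ratio[foot & lp@valid] - truth2d[foot & lp@valid])
  rel <- err / truth2d[foot & lp@valid]
  expect_lt(max(rel), 0.01)
})
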
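# Digital cohort generator: structure, determinism, and the physics of
# the three simulated acquisitions.

test_that("cohort has the requested size, labels and mouse sharing", {
  p <- acquisitionParams()
  cohort <- generateCohort(5, 7, p, seed = 1)
  expect_length(cohort, 12)
  grades <- vapply(cohort, function(l) l@grade, character(1))
  expect_identical(sum(grades == "low"), 5L)
  expect_identical(sum(grades == "high"), 7L)
  mice <- vapply(cohort, function(l) l@mouseId, character(1))
  expect_identical(length(unique(mice)), 10L)  # 2 mice carry both grades
  shared <- names(which(table(mice) == 2))
  for (m in shared)
    expect_setequal(grades[mice == m], c("low", "high"))
})

test_that("empty cohort and seed determinism", {
  expect_identical(generateCohort(0, 0, seed = 1), list())
  a <- generateCohort(2, 2, seed = 7)
  b <- generateCohort(2, 2, seed = 7)
  for (k in seq_along(a)) {
    expect_identical(a[[k]]@phField, b[[k]]@phField)
    expect_identical(a[[k]]@lacPyrField, b[[k]]@lacPyrField)
    expect_identical(a[[k]]@histologyComposition,
                     b[[k]]@histologyComposition)
    expect_identical(a[[k]]@expression, b[[k]]@expression)
  }
  expect_error(acquisitionParams(csiMatrix = c(0L, 8L)), "positive")
})

test_that("quantile draw embodies the group statistics exactly in the mean", {
  gs <- defaultGroupStats()
  cohort <- generateCohort(5, 7, seed = 3, fillExpression = FALSE)
  mPH <- vapply(cohort, function(l) l@truth$meanPH, numeric(1))
  g <- vapply(cohort, function(l) l@grade, character(1))
  expect_equal(mean(mPH[g == "low"]), gs$low$meanPH, tolerance = 1e-10)
  expect_equal(mean(mPH[g == "high"]), gs$high$meanPH, tolerance = 1e-10)
  # grade separation: low pH above high, higher ADC, lower Lac/Pyr
  mLP <- vapply(cohort, function(l) l@truth$meanLacPyr, numeric(1))
  mAD <- vapply(cohort, function(l) l@truth$meanADC, numeric(1))
  expect_gt(mean(mPH[g == "low"]), mean(mPH[g == "high"]))
  expect_lt(mean(mLP[g == "low"]), mean(mLP[g == "high"]))
  expect_gt(mean(mAD[g == "low"]), mean(mAD[g == "high"]))
})

test_that("ROI minimum sits the grade-specific drop below the mean", {
  gs <- defaultGroupStats()
  cohort <- generateCohort(3, 3, seed = 11, fillExpression = FALSE)
  for (l in cohort) {
    drop <- gs[[l@grade]]$minDrop
    expect_equal(l@truth$meanPH - l@truth$minPH, drop, tolerance = 1e-12)
    expect_equal(min(l@phField[l@roiMask]), l@truth$minPH,
                 tolerance = 1e-12)
  }
})

test_that("histology compositions close to 1 and match grade labels", {
  for (seed in 1:5) {
    cohort <- generateCohort(3, 4, seed = seed, fillExpression = FALSE)
    for (l in cohort) {
      expect_equal(sum(l@histologyComposition), 1, tolerance = 1e-9)
      idx <- histologyIndex(l@histologyComposition)
      expect_identical(dichotomizeGrade(idx), l@grade)
    }
  }
})

test_that("bicarbonate/CO2 pools follow Henderson-Hasselbalch exactly", {
  pools <- hp13cmri:::poolAmplitudes(7.0, 1, pKa = 6.17)
  expect_equal(pools$bic / pools$co2, 10^0.83, tolerance = 1e-12)
  expect_equal(10^0.83, 6.761, tolerance = 1e-3)
  atPka <- hp13cmri:::poolAmplitudes(6.17, 1, pKa = 6.17)
  expect_equal(atPka$bic / atPka$co2, 1, tolerance = 1e-12)
  # round trip of the equation itself at 1e-12 over the physiological range
  for (ph in seq(6, 8, by = 0.1)) {
    pl <- hp13cmri:::poolAmplitudes(ph, 1, pKa = 6.17)
    expect_equal(log10(pl$bic / pl$co2) + 6.17, ph, tolerance = 1e-12)
  }
})

test_that("simulateCSI rejects unphysiological pH and is seed-deterministic", {
  p <- smallParams()
  l <- testLesion(params = p)
  bad <- l
  m <- bad@phField
  m[bad@roiMask] <- 4.9
  slot(bad, "phField", check = FALSE) <- m
  expect_error(simulateCSI(bad, p), "unphysiological")
  a <- simulateCSI(l, p, noiseSigma = 2, seed = 5)
  b <- simulateCSI(l, p, noiseSigma = 2, seed = 5)
  expect_identical(a@data, b@data)
})

test_that("doubling k-space noise doubles its empirical sd", {
  p <- smallParams()
  l <- testLesion(params = p)
  clean <- simulateCSI(l, p, noiseSigma = 0)@data
  n1 <- simulateCSI(l, p, noiseSigma = 1, seed = 2)@data - clean
  n2 <- simulateCSI(l, p, noiseSigma = 2, seed = 3)@data - clean
  s1 <- sd(c(Re(n1), Im(n1)))  # 4096+ samples
  s2 <- sd(c(Re(n2), Im(n2)))
  expect_equal(s1, 1, tolerance = 0.05)
  expect_equal(s2 / s1, 2, tolerance = 0.05)
})

test_that("metabolite volumes reproduce the ratio field noiselessly", {
  p <- smallParams()
  l <- testLesion(meanLacPyr = 2, params = p)
  fld <- l@lacPyrField
  fld[l@graseMask] <- 2
  slot(l, "lacPyrField", check = FALSE) <- fld
  vols <- simulateGRASE(l, p, s0 = 50, noiseSigma = 0)
  r <- vols$lactate[l@graseMask] / vols$pyruvate[l@graseMask]
  expect_equal(unique(round(r, 12)), 2)
  # zero ratio field gives an all-zero lactate volume
  fld[] <- 0
  slot(l, "lacPyrField", check = FALSE) <- fld
  expect_true(all(simulateGRASE(l, p, noiseSigma = 0)$lactate == 0))
  # Rician support: with noise everything is strictly positive
  noisy <- simulateGRASE(l, p, s0 = 50, noiseSigma = 3, seed = 1)
  expect_true(all(noisy$pyruvate > 0))
  expect_true(all(noisy$lactate > 0))
  fld[] <- -0.1
  slot(l, "lacPyrField", check = FALSE) <- fld
  expect_error(simulateGRASE(l, p), "non-negative")
})

test_that("diffusion stack follows the mono-exponential forward model", {
  p <- smallParams()
  l <- testLesion(params = p)
  adc <- l@adcField
  adc[] <- 1.0e-3
  slot(l, "adcField", check = FALSE) <- adc
  stack <- simulateDWI(l, s0 = 1000, params = p, noiseSigma = 0)
  # independent evaluation of the exponential at b = 515
  expect_equal(stack@signal[1, 1, 4], 1000 * exp(-0.515), tolerance = 1e-10)
  expect_equal(stack@signal[1, 1, 4], 597.5, tolerance = 0.1)
  expect_true(all(stack@signal[, , 1] == 1000))  # b = 0 is exact
  adc[] <- 1e-12  # vanishing diffusivity: signal constant across b
  slot(l, "adcField", check = FALSE) <- adc
  s <- simulateDWI(l, s0 = 1000, params = p, noiseSigma = 0)@signal
  expect_lt(max(abs(s - 1000)), 1e-6)
  expect_error(simulateDWI(l, s0 = -5, params = p), "s0 > 0")
})

test_that("expression is monotone in pH and reproducible", {
  la <- testLesion(meanPH = 7.5)
  lb <- testLesion(meanPH = 7.1)
  ea <- simulateExpression(la, seed = 1, noiseSd = 0)
  eb <- simulateExpression(lb, seed = 1, noiseSd = 0)
  expect_gt(eb[["Mct4"]], ea[["Mct4"]])
  # perfect monotone rank relation over a noiseless spread of lesions
  phs <- seq(7.0, 7.6, length.out = 10)
  mct4 <- vapply(phs, function(ph)
    simulateExpression(testLesion(meanPH = ph), noiseSd = 0)[["Mct4"]],
    numeric(1))
  expect_equal(suppressWarnings(cor(phs, mct4, method = "spearman")), -1)
  expect_identical(simulateExpression(la, seed = 9),
                   simulateExpression(la, seed = 9))
})
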
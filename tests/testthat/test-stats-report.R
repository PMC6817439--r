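# The statistical battery: exact small-sample tests against enumeration
# oracles and stats:: cross-checks, effect sizes, the mixed model, and
# the report plumbing.

test_that("Mann-Whitney exact enumeration reproduces known values", {
  res <- mannWhitneyU(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$U, 0)
  expect_equal(res$p, 0.1)        # 2 of the C(6,3)=20 assignments
  expect_identical(res$method, "exact")
  expect_equal(mannWhitneyU(c(2, 2, 2), c(2, 2))$p, 1)
})

test_that("exact Mann-Whitney agrees with wilcox.test for pooled n <= 8", {
  for (seed in 1:10) {
    set.seed(seed)
    na <- sample(2:4, 1); nb <- sample(2:4, 1)
    a <- rnorm(na); b <- rnorm(nb, mean = 0.5)
    mine <- mannWhitneyU(a, b)
    ref <- wilcox.test(a, b, exact = TRUE, correct = FALSE)
    expect_equal(mine$U, unname(ref$statistic))
    expect_equal(mine$p, ref$p.value, tolerance = 1e-12)
  }
})

test_that("normal approximation tracks the exact p at n = 6 + 6", {
  for (seed in 1:5) {
    set.seed(seed + 100)
    a <- rnorm(6); b <- rnorm(6, mean = 1)
    pe <- mannWhitneyU(a, b)$p
    pa <- mannWhitneyU(a, b, exactMax = 0)$p
    expect_lt(abs(pe - pa), 0.02)
  }
})

test_that("Mann-Whitney p is invariant under monotone transforms", {
  set.seed(3)
  a <- rexp(5); b <- rexp(6) + 0.3
  p0 <- mannWhitneyU(a, b)$p
  expect_equal(mannWhitneyU(exp(a), exp(b))$p, p0)
  expect_equal(mannWhitneyU(log(a), log(b))$p, p0)
  expect_equal(mannWhitneyU(a^3, b^3)$p, p0)
})

test_that("Spearman endpoints, exact enumeration and degeneracy", {
  x <- c(1, 2, 5, 9)
  expect_equal(spearmanCorr(x, x * 2 + 1)$rho, 1)
  expect_equal(spearmanCorr(x, rev(x))$rho, -1)
  # exact permutation p matches cor.test's exact distribution (no ties)
  for (seed in 1:8) {
    set.seed(seed)
    xx <- rnorm(6); yy <- rnorm(6)
    mine <- spearmanCorr(xx, yy)
    ref <- cor.test(xx, yy, method = "spearman", exact = TRUE)
    expect_equal(mine$rho, unname(ref$estimate), tolerance = 1e-12)
    expect_equal(mine$p, ref$p.value, tolerance = 1e-12)
  }
  expect_warning(out <- spearmanCorr(rep(1, 5), rnorm(5)), "constant")
  expect_true(is.na(out$rho))
})

test_that("Cohen's d reproduces the published group contrast", {
  # groups constructed with exactly the printed means and SDs
  mk <- function(n, m, s) m + s * as.vector(scale(seq_len(n)))
  low <- mk(5, 7.53, 0.17)
  high <- mk(7, 7.22, 0.14)
  expect_equal(cohensD(low, high), 2.03, tolerance = 1e-2)
  expect_equal(cohensD(high, low), -cohensD(low, high))
  expect_equal(cohensD(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_warning(d0 <- cohensD(c(1, 1), c(1, 1)), "zero pooled SD")
  expect_true(is.na(d0))
})

test_that("noiseless mixed-model data returns the exact slope via OLS", {
  vt <- simulateVoxelTable(nVoxels = 60, nLesions = 4, nMice = 4,
                           slope = -0.15, lesionSd = 0, residSd = 0,
                           seed = 2)
  fit <- fitMixedModel(vt)
  expect_identical(fit@method, "ols")
  expect_equal(fit@slope, -0.15, tolerance = 1e-6)
})

test_that("a single lesion reduces to the ordinary least squares slope", {
  vt <- simulateVoxelTable(nVoxels = 30, nLesions = 1, nMice = 1,
                           slope = -0.2, lesionSd = 0.1, residSd = 0.05,
                           seed = 3)
  fit <- fitMixedModel(vt)
  ref <- lm(ph ~ lacpyr, data = vt)
  expect_equal(fit@slope, unname(coef(ref)[2]), tolerance = 1e-10)
})

test_that("REML recovers the slope within 2 SE in at least 90% of seeds", {
  hits <- 0L
  nSim <- 200L
  for (s in seq_len(nSim)) {
    vt <- simulateVoxelTable(nVoxels = 153, nLesions = 12, nMice = 10,
                             slope = -0.151, mouseSd = 0,
                             lesionSd = 0.10, residSd = 0.05, seed = s)
    fit <- fitMixedModel(vt)
    if (abs(fit@slope + 0.151) <= 2 * fit@slopeSE) hits <- hits + 1L
  }
  expect_gte(hits / nSim, 0.90)
})

test_that("variance components are recovered and non-negative", {
  vt <- simulateVoxelTable(nVoxels = 600, nLesions = 12, nMice = 12,
                           slope = -0.151, mouseSd = 0, lesionSd = 0.1,
                           residSd = 0.05, seed = 4)
  fit <- fitMixedModel(vt)
  expect_gte(fit@varLesion, 0)
  expect_equal(sqrt(fit@varResidual), 0.05, tolerance = 0.25)
  expect_equal(sqrt(fit@varLesion), 0.1, tolerance = 0.5)
})

test_that("per-mouse aggregation keeps the larger lesion per mouse", {
  les <- data.frame(
    lesion = c("L1", "L2", "L3", "L4"),
    mouse = c("M1", "M1", "M2", "M3"),
    grade = c("low", "high", "low", "high"),
    meanPH = c(7.5, 7.2, 7.6, 7.1),
    nVoxPH = c(4L, 9L, 5L, 6L))
  vox <- data.frame(mouse = rep(les$mouse, les$nVoxPH),
                    lesion = rep(les$lesion, les$nVoxPH),
                    ph = rnorm(24, 7.3), lacpyr = runif(24))
  agg <- perMouseAggregate(cohortTable(les, vox))
  expect_identical(sort(cohortLesions(agg)$lesion), c("L2", "L3", "L4"))
  expect_true(all(cohortVoxels(agg)$lesion %in% c("L2", "L3", "L4")))
  # brute-force rule oracle
  expected <- unlist(lapply(split(les, les$mouse), function(d)
    d$lesion[which.max(d$nVoxPH)]))
  expect_setequal(cohortLesions(agg)$lesion, expected)
  # all-singleton cohort is untouched
  single <- cohortTable(les[3:4, ], vox[vox$lesion %in% c("L3", "L4"), ])
  expect_identical(cohortLesions(perMouseAggregate(single)),
                   cohortLesions(single))
})

test_that("report is schema-stable, reproducible and self-consistent", {
  empty <- cohortTable(data.frame(lesion = character(),
                                  mouse = character(),
                                  grade = character()))
  repEmpty <- writeReport(empty)
  expect_named(repEmpty, c("nLesions", "nLow", "nHigh", "nVoxels",
                           "groupComparisons", "correlations",
                           "mixedModel", "perMouseComparisons"))
  expect_identical(repEmpty$nLesions, 0L)

  cohort <- processCohort(generateCohort(3, 4, seed = 2),
                          seed = 2, peakSNR = 25)
  d1 <- file.path(tempdir(), "rep1"); d2 <- file.path(tempdir(), "rep2")
  writeReport(cohort, d1); writeReport(cohort, d2)
  expect_identical(readLines(file.path(d1, "report.json")),
                   readLines(file.path(d2, "report.json")))
  rep <- writeReport(cohort)
  fit <- fitMixedModel(cohortVoxels(cohort))
  expect_equal(rep$mixedModel$slope, fit@slope)
  expect_true(file.exists(file.path(d1, "lesions.csv")))
})
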
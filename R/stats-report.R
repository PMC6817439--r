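#' @include AllClasses.R roi-analysis.R utils.R
NULL

## all permutations of 1..n (n! rows); used by the exact Spearman test
allPerms <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- allPerms(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  r <- 0L
  for (k in seq_len(n)) {
    rows <- r + seq_len(nrow(sub))
    out[rows, 1] <- k
    out[rows, -1] <- ifelse(sub >= k, sub + 1L, sub)
    r <- r + nrow(sub)
  }
  out
}

#' Mann-Whitney U test with small-sample exact enumeration
#'
#' Rank-sum comparison of two groups with average ranks for ties. For a
#' pooled sample size of at most `exactMax` (default 12) the two-sided
#' p-value is exact, computed by enumerating all label assignments of the
#' pooled values and counting assignments whose U deviates from its null
#' mean `n_a n_b / 2` at least as much as observed (ties handled
#' naturally by the enumeration). Larger samples use the normal
#' approximation with tie correction and continuity correction. If all
#' pooled values are identical the p-value is 1.
#'
#' @param groupA,groupB numeric vectors (each of length >= 1).
#' @param exactMax largest pooled n for which the exact enumeration is
#'   used.
#' @return list with elements `U` (statistic for `groupA`), `p`
#'   (two-sided) and `method` ("exact" or "normal").
#' @examples
#' mannWhitneyU(c(1, 2, 3), c(4, 5, 6))  # U = 0, exact p = 0.1
#' @export
mannWhitneyU <- function(groupA, groupB, exactMax = 12) {
  stopifnot(length(groupA) >= 1, length(groupB) >= 1)
  na <- length(groupA); nb <- length(groupB); n <- na + nb
  pooled <- c(groupA, groupB)
  r <- rank(pooled)
  U <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  mu <- na * nb / 2
  if (length(unique(pooled)) == 1L)
    return(list(U = U, p = 1, method = "degenerate"))

  if (n <= exactMax) {
    idx <- utils::combn(n, na)
    Us <- colSums(matrix(r[idx], nrow = na)) - na * (na + 1) / 2
    p <- mean(abs(Us - mu) >= abs(U - mu) - 1e-12)
    return(list(U = U, p = p, method = "exact"))
  }
  ties <- table(pooled)
  tieAdj <- sum(ties^3 - ties)
  sigma <- sqrt(na * nb / 12 * ((n + 1) - tieAdj / (n * (n - 1))))
  z <- (U - mu - sign(U - mu) * 0.5) / sigma
  p <- min(1, 2 * stats::pnorm(-abs(z)))
  list(U = U, p = p, method = "normal")
}

#' Spearman rank correlation with small-sample exact p-value
#'
#' Rank correlation with average ranks for ties. For n at most
#' `exactMax` (default 8) the two-sided p-value is exact, enumerating all
#' permutations of one margin's ranks; larger samples use the
#' t-approximation `t = rho * sqrt((n-2)/(1-rho^2))`. Constant input
#' yields an undefined rho (NA with a warning).
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @param exactMax largest n for which the permutation enumeration is
#'   used.
#' @return list with elements `rho`, `p` and `method`.
#' @export
spearmanCorr <- function(x, y, exactMax = 8) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  n <- length(x)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant input: Spearman rho undefined")
    return(list(rho = NA_real_, p = NA_real_, method = "degenerate"))
  }
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (n <= exactMax) {
    perms <- allPerms(n)
    rhos <- apply(perms, 1, function(p) stats::cor(rx, ry[p]))
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
    return(list(rho = rho, p = p, method = "exact"))
  }
  if (abs(rho) >= 1 - 1e-15)
    return(list(rho = rho, p = 0, method = "t"))
  tt <- rho * sqrt((n - 2) / (1 - rho^2))
  list(rho = rho, p = 2 * stats::pt(-abs(tt), n - 2), method = "t")
}

#' Cohen's d effect size with pooled standard deviation
#'
#' `(mean_a - mean_b) / s_p` with
#' `s_p = sqrt(((n_a-1) s_a^2 + (n_b-1) s_b^2) / (n_a+n_b-2))`.
#' A zero pooled SD is undefined and returns NA with a warning.
#'
#' @param groupA,groupB numeric vectors of length >= 2 each.
#' @return numeric(1).
#' @export
cohensD <- function(groupA, groupB) {
  na <- length(groupA); nb <- length(groupB)
  stopifnot(na >= 2, nb >= 2)
  sp <- sqrt(((na - 1) * stats::var(groupA) + (nb - 1) * stats::var(groupB)) /
               (na + nb - 2))
  if (sp == 0) {
    warning("zero pooled SD: Cohen's d undefined")
    return(NA_real_)
  }
  (mean(groupA) - mean(groupB)) / sp
}

#' Simulate a voxel-level table for the mixed-effects model
#'
#' Generates `nVoxels` voxels spread over `nLesions` lesions in `nMice`
#' mice with `ph = intercept + slope * lacpyr + mouse RE + lesion RE +
#' residual`, Lac/Pyr uniform on `lacpyrRange`. Lesions beyond the mouse
#' count double up on the first mice (mixed tumors).
#'
#' @param nVoxels,nLesions,nMice counts.
#' @param slope,intercept fixed effects (pH units per unit Lac/Pyr; pH).
#' @param mouseSd,lesionSd,residSd random-effect and residual sds.
#' @param lacpyrRange numeric(2) range of the uniform Lac/Pyr draw.
#' @param seed integer seed.
#' @return data.frame with columns mouse, lesion, voxel, lacpyr, ph.
#' @export
simulateVoxelTable <- function(nVoxels = 153, nLesions = 12, nMice = 10,
                               slope = -0.151, intercept = 7.6,
                               mouseSd = 0, lesionSd = 0.10,
                               residSd = 0.05, lacpyrRange = c(0, 3),
                               seed = 42L) {
  stopifnot(nLesions >= 1, nVoxels >= nLesions, nMice >= 1)
  sizes <- rep(nVoxels %/% nLesions, nLesions)
  extra <- nVoxels %% nLesions
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  mouseOf <- sprintf("M%02d", ((seq_len(nLesions) - 1L) %% nMice) + 1L)
  withSeed(seed, {
    mouseRE <- stats::setNames(stats::rnorm(nMice, sd = mouseSd),
                               sprintf("M%02d", seq_len(nMice)))
    lesionRE <- stats::rnorm(nLesions, sd = lesionSd)
    rows <- vector("list", nLesions)
    for (l in seq_len(nLesions)) {
      lp <- stats::runif(sizes[l], lacpyrRange[1], lacpyrRange[2])
      ph <- intercept + slope * lp + mouseRE[[mouseOf[l]]] + lesionRE[l] +
        stats::rnorm(sizes[l], sd = residSd)
      rows[[l]] <- data.frame(
        mouse = mouseOf[l], lesion = sprintf("L%02d", l),
        voxel = seq_len(sizes[l]), lacpyr = lp, ph = ph,
        stringsAsFactors = FALSE)
    }
    do.call(rbind, rows)
  })
}

#' Fit the voxelwise mixed-effects model of pH on Lac/Pyr
#'
#' Restricted maximum likelihood fit of
#' `ph ~ 1 + lacpyr + (1 | mouse) + (1 | mouse:lesion)` (random
#' intercepts for mouse and for lesion nested in mouse; set
#' `nested = FALSE` for crossed `(1 | lesion)`). Degenerate variance
#' components may hit zero; singular or non-converged fits are reported
#' through the `converged` flag rather than an exception. With a single
#' lesion (or residuals that are exactly linear) the model reduces to
#' ordinary least squares.
#'
#' @param voxelTable data.frame with columns mouse, lesion, lacpyr, ph
#'   (e.g. from [simulateVoxelTable()] or [cohortVoxels()]).
#' @param nested logical; nest lesion within mouse (default) or cross.
#' @return a [MixedModelFit-class].
#' @export
fitMixedModel <- function(voxelTable, nested = TRUE) {
  need <- c("mouse", "lesion", "lacpyr", "ph")
  stopifnot(all(need %in% names(voxelTable)))
  if (nrow(voxelTable) < 10) stop("at least 10 voxels are required")
  df <- voxelTable
  df$mouse <- factor(df$mouse)
  df$lesionF <- if (nested) interaction(df$mouse, df$lesion, drop = TRUE)
  else factor(df$lesion)

  olsFit <- function(method) {
    fit <- stats::lm(ph ~ lacpyr, data = df)
    ## summary.lm warns on an exactly perfect fit; that case is expected
    ## here (noiseless synthetic data)
    sm <- suppressWarnings(summary(fit))
    new("MixedModelFit",
        slope = unname(stats::coef(fit)[2]),
        intercept = unname(stats::coef(fit)[1]),
        slopeSE = sm$coefficients[2, 2],
        pValue = sm$coefficients[2, 4],
        varMouse = 0, varLesion = 0,
        varResidual = sm$sigma^2,
        converged = TRUE, method = method)
  }
  if (nlevels(df$lesionF) < 2) return(olsFit("ols"))
  ## degenerate noiseless data: exact linearity, REML has nothing to fit
  if (suppressWarnings(summary(stats::lm(ph ~ lacpyr, data = df)))$sigma < 1e-8)
    return(olsFit("ols"))

  singular <- FALSE; warned <- FALSE
  fit <- withCallingHandlers(
    lme4::lmer(ph ~ lacpyr + (1 | mouse) + (1 | lesionF),
               data = df, REML = TRUE,
               control = lme4::lmerControl(check.conv.singular = "ignore")),
    warning = function(w) {
      warned <<- TRUE
      invokeRestart("muffleWarning")
    })
  singular <- lme4::isSingular(fit, tol = 1e-5)
  vc <- as.data.frame(lme4::VarCorr(fit))
  getVar <- function(g) {
    v <- vc$vcov[vc$grp == g]
    if (length(v)) v[1] else 0
  }
  sm <- summary(fit)
  co <- sm$coefficients
  tval <- co["lacpyr", "t value"]
  ## two-sided p from the large-sample normal reference for the t ratio
  pval <- 2 * stats::pnorm(-abs(tval))
  new("MixedModelFit",
      slope = co["lacpyr", "Estimate"],
      intercept = co["(Intercept)", "Estimate"],
      slopeSE = co["lacpyr", "Std. Error"],
      pValue = pval,
      varMouse = getVar("mouse"),
      varLesion = getVar("lesionF"),
      varResidual = getVar("Residual"),
      converged = !singular && !warned,
      method = "reml")
}

#' Retain one region of interest per mouse
#'
#' For mice carrying multiple lesions, keeps the lesion with the larger
#' analyzable voxel count (column `nVoxPH`, falling back to `nVoxels` or
#' the voxel table; ties broken by table order) and drops the others from
#' both tables, so group comparisons can be rerun with one ROI per mouse.
#'
#' @param cohort a [CohortTable-class].
#' @return a filtered [CohortTable-class].
#' @export
perMouseAggregate <- function(cohort) {
  stopifnot(is(cohort, "CohortTable"))
  les <- cohort@lesions
  if (!nrow(les)) return(cohort)
  counts <- if ("nVoxPH" %in% names(les)) les$nVoxPH
  else if ("nVoxels" %in% names(les)) les$nVoxels
  else as.vector(table(cohort@voxels$lesion)[les$lesion])
  counts[is.na(counts)] <- 0
  keep <- unlist(lapply(split(seq_len(nrow(les)), les$mouse), function(ix) {
    ix[which.max(counts[ix])]
  }), use.names = FALSE)
  keep <- sort(keep)
  les2 <- les[keep, , drop = FALSE]
  vox2 <- cohort@voxels[cohort@voxels$lesion %in% les2$lesion, ,
                        drop = FALSE]
  new("CohortTable", lesions = les2, voxels = vox2)
}

#' Compute and write the cohort statistics report
#'
#' Runs the full statistical battery on a cohort: Mann-Whitney group
#' comparisons and Cohen's d (low vs high grade) for every imaging
#' metric present, Spearman correlations (minimum pH vs maximum Lac/Pyr,
#' mean pH vs mean Lac/Pyr, mean pH vs Mct4/Mct1 expression where
#' available), the voxelwise mixed-effects model, the one-ROI-per-mouse
#' sensitivity reanalysis, and QC counts. No multiple-testing correction
#' is applied; two-sided p < 0.05 is the significance convention.
#'
#' When `outDir` is given, writes `report.json` (stable key order,
#' byte-identical on rerun), `lesions.csv` and `voxels.csv`.
#'
#' @param cohort a [CohortTable-class].
#' @param outDir output directory, or NULL to skip writing.
#' @return the report as a named list, invisibly when writing.
#' @export
writeReport <- function(cohort, outDir = NULL) {
  stopifnot(is(cohort, "CohortTable"))
  les <- cohort@lesions
  metrics <- intersect(c("meanPH", "minPH", "meanLacPyr", "maxLacPyr",
                         "meanADC"), names(les))
  groupStats <- list()
  for (m in metrics) {
    a <- les[[m]][les$grade == "low"]
    b <- les[[m]][les$grade == "high"]
    a <- a[is.finite(a)]; b <- b[is.finite(b)]
    if (length(a) >= 2 && length(b) >= 2) {
      mw <- mannWhitneyU(a, b)
      groupStats[[m]] <- list(
        meanLow = mean(a), sdLow = stats::sd(a),
        meanHigh = mean(b), sdHigh = stats::sd(b),
        U = mw$U, p = mw$p, cohensD = cohensD(a, b))
    }
  }

  correlations <- list()
  addCor <- function(name, x, y) {
    ok <- is.finite(x) & is.finite(y)
    if (sum(ok) >= 3) {
      sc <- spearmanCorr(x[ok], y[ok])
      correlations[[name]] <<- list(rho = sc$rho, p = sc$p, n = sum(ok))
    }
  }
  if (all(c("minPH", "maxLacPyr") %in% names(les)))
    addCor("minPH_vs_maxLacPyr", les$minPH, les$maxLacPyr)
  if (all(c("meanPH", "meanLacPyr") %in% names(les)))
    addCor("meanPH_vs_meanLacPyr", les$meanPH, les$meanLacPyr)
  if (all(c("meanPH", "Mct4") %in% names(les)))
    addCor("meanPH_vs_Mct4", les$meanPH, les$Mct4)
  if (all(c("meanPH", "Mct1") %in% names(les)))
    addCor("meanPH_vs_Mct1", les$meanPH, les$Mct1)

  mixed <- NULL
  if (nrow(cohort@voxels) >= 10 &&
      length(unique(cohort@voxels$lesion)) >= 2) {
    fit <- fitMixedModel(cohort@voxels)
    mixed <- list(slope = fit@slope, intercept = fit@intercept,
                  slopeSE = fit@slopeSE, p = fit@pValue,
                  varMouse = fit@varMouse, varLesion = fit@varLesion,
                  varResidual = fit@varResidual,
                  converged = fit@converged, method = fit@method)
  }

  perMouse <- list()
  if (nrow(les) && length(unique(les$mouse)) < nrow(les)) {
    agg <- perMouseAggregate(cohort)
    for (m in metrics) {
      a <- agg@lesions[[m]][agg@lesions$grade == "low"]
      b <- agg@lesions[[m]][agg@lesions$grade == "high"]
      a <- a[is.finite(a)]; b <- b[is.finite(b)]
      if (length(a) >= 2 && length(b) >= 2)
        perMouse[[m]] <- list(p = mannWhitneyU(a, b)$p)
    }
  }

  report <- list(
    nLesions = nrow(les),
    nLow = sum(les$grade == "low"),
    nHigh = sum(les$grade == "high"),
    nVoxels = nrow(cohort@voxels),
    groupComparisons = groupStats,
    correlations = correlations,
    mixedModel = mixed,
    perMouseComparisons = perMouse
  )

  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(report, file.path(outDir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
    utils::write.csv(les, file.path(outDir, "lesions.csv"),
                     row.names = FALSE)
    utils::write.csv(cohort@voxels, file.path(outDir, "voxels.csv"),
                     row.names = FALSE)
    return(invisible(report))
  }
  report
}
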
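#' @include AllClasses.R
NULL

#' Fit mono-exponential diffusion decay per voxel
#'
#' Least-squares fit of `S(b) = S0 * exp(-b * ADC)` per voxel via a
#' weighted log-linear regression with weights proportional to `S^2`,
#' which emulates direct signal-domain least squares while staying
#' deterministic and closed-form. The RMS residual is computed in the
#' signal domain over all b-values. Voxels with a non-positive signal at
#' any b-value are flagged `"unfittable"` (ADC is NA and the voxel is
#' invalid).
#'
#' @param stack a [DwiStack-class] with at least 3 b-values.
#' @return an [AdcMap-class]; negative fitted decay rates are truncated
#'   at 0 (a constant signal yields ADC = 0).
#' @export
fitADC <- function(stack) {
  stopifnot(is(stack, "DwiStack"))
  b <- stack@bValues
  if (length(b) < 3) stop("at least 3 b-values are required")
  d <- dim(stack@signal)
  nvox <- d[1] * d[2]
  S <- matrix(stack@signal, nrow = nvox, ncol = d[3])

  adc <- s0 <- rms <- rep(NA_real_, nvox)
  flags <- rep("ok", nvox)
  fitOK <- rowSums(S <= 0) == 0
  flags[!fitOK] <- "unfittable"

  if (any(fitOK)) {
    Sf <- S[fitOK, , drop = FALSE]
    y <- log(Sf)
    w <- Sf^2
    sw <- rowSums(w)
    mb <- rowSums(w * rep(b, each = nrow(w))) / sw
    my <- rowSums(w * y) / sw
    bc <- sweep(matrix(b, nrow(w), length(b), byrow = TRUE), 1, mb)
    slope <- rowSums(w * bc * (y - my)) / rowSums(w * bc^2)
    a <- pmax(-slope, 0)                      # ADC >= 0
    inter <- my + a * mb
    s0f <- exp(inter)
    pred <- s0f * exp(-outer(a, b))
    rmsf <- sqrt(rowMeans((Sf - pred)^2))
    adc[fitOK] <- a; s0[fitOK] <- s0f; rms[fitOK] <- rmsf
  }

  new("AdcMap",
      adc = matrix(adc, d[1], d[2]),
      s0 = matrix(s0, d[1], d[2]),
      rmsResidual = matrix(rms, d[1], d[2]),
      valid = matrix(fitOK, d[1], d[2]),
      flags = matrix(flags, d[1], d[2]),
      exclusions = c(unfittable = sum(!fitOK)))
}

#' Apply residual and free-water exclusion rules to an ADC map
#'
#' Voxels whose signal-domain RMS residual exceeds `residualLimit`
#' (default 500, scanner arbitrary units) or whose ADC exceeds
#' `adcLimit` (default 3.0e-3 mm^2/s, free water at 37 C) are masked
#' invalid. Both comparisons are strict (a voxel exactly at a limit is
#' retained). Exclusion counts by reason are recorded; the operation is
#' idempotent.
#'
#' @param map an [AdcMap-class].
#' @param residualLimit positive RMS residual limit, signal units.
#' @param adcLimit positive ADC limit, mm^2/s.
#' @return a filtered [AdcMap-class].
#' @export
filterADC <- function(map, residualLimit = 500, adcLimit = 3.0e-3) {
  stopifnot(is(map, "AdcMap"), residualLimit > 0, adcLimit > 0)
  highRes <- map@valid & map@rmsResidual > residualLimit
  highAdc <- map@valid & !highRes & map@adc > adcLimit
  flags <- map@flags
  flags[highRes] <- "high_residual"
  flags[highAdc] <- "high_adc"
  valid <- map@valid & !highRes & !highAdc
  excl <- map@exclusions
  excl <- c(excl[setdiff(names(excl), c("high_residual", "high_adc"))],
            high_residual = sum(flags == "high_residual"),
            high_adc = sum(flags == "high_adc"))
  new("AdcMap", adc = map@adc, s0 = map@s0,
      rmsResidual = map@rmsResidual, valid = valid, flags = flags,
      exclusions = excl)
}
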
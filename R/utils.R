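## Internal helpers shared across modules.

## Deterministic seed splitting: one user-facing seed fans out to
## per-lesion / per-acquisition streams. Kept below 2^31 - 1 so the result
## is always a valid R integer seed.
deriveSeed <- function(seed, k) {
  s <- (as.numeric(seed) %% 2147483647) * 69069 + as.numeric(k) * 7919 + 1
  as.integer(s %% 2147483647)
}

## Evaluate `expr` under a local RNG state; restores the caller's stream.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

## Rician-distributed magnitude: true signal plus complex Gaussian noise
## with per-component sd sigma. sigma = 0 returns the magnitude unchanged.
ricianNoise <- function(signal, sigma) {
  if (sigma == 0) return(abs(signal))
  n <- length(signal)
  sqrt((signal + stats::rnorm(n, sd = sigma))^2 +
         stats::rnorm(n, sd = sigma)^2)
}

## Mean of the Rayleigh magnitude-noise distribution for per-component
## Gaussian sd sigma.
rayleighMean <- function(sigma) sigma * sqrt(pi / 2)

degToRad <- function(deg) deg * pi / 180

## 2D FFT helpers (dims 1:2 of a matrix), unnormalized forward,
## 1/N-normalized inverse, matching the conventions documented in
## reconstructCSI().
fft2 <- function(x) {
  t(stats::mvfft(t(stats::mvfft(x))))
}

ifft2 <- function(x) {
  out <- t(stats::mvfft(t(stats::mvfft(x, inverse = TRUE)),
                        inverse = TRUE))
  out / length(x)
}
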
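## Internal helpers: seeds, angle conversions, windows, FFT shifts.

.deg2rad <- function(x) x * pi / 180
.rad2deg <- function(x) x * 180 / pi

## Evaluate `code` under a fixed RNG seed without disturbing the caller's
## random state.  All stochastic entry points take explicit seeds; there is
## no hidden global state.
withSeed <- function(seed, code) {
  if (is.null(seed) || is.na(seed)) stop("an explicit seed is required")
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    stats::runif(1L)
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

## Deterministic sub-stream seeds (kept within 32-bit integer range).
deriveSeed <- function(seed, i) {
  as.integer((as.double(seed) * 69069 + 12345 + as.double(i)) %% 2147483647)
}

hannWindow <- function(n) {
  if (n == 1L) return(1)
  0.5 * (1 - cos(2 * pi * (seq_len(n) - 1L) / (n - 1L)))
}

## Reorder FFT output so zero frequency sits at index floor(n/2) + 1.
fftshiftIndex <- function(n) {
  k <- floor(n / 2)
  c((n - k + 1L):n, 1L:(n - k))
}

## Frequency value (cycles / pixel) of each index after fftshift.
frequencyValues <- function(n) (seq_len(n) - (floor(n / 2) + 1L)) / n
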
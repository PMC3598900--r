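#' @keywords internal
#' @import stats
#' @importFrom utils head modifyList packageVersion write.csv
"_PACKAGE"

## Numerically stable softplus log(1 + exp(x)) and its log.
softplus <- function(x) {
  out <- x
  small <- x < 30
  out[small] <- log1p(exp(x[small]))
  out
}

## log(softplus(x)), stable for very negative x where softplus(x) ~ exp(x).
log_softplus <- function(x) {
  out <- numeric(length(x))
  lo <- x < -30
  out[lo] <- x[lo]
  out[!lo] <- log(softplus(x[!lo]))
  out
}

## derivative of softplus = logistic
dsoftplus <- function(x) plogis(x)

relu <- function(x) pmax(x, 0)

## Evaluate a function with a temporary RNG state, restoring it afterwards.
## All stochastic operations in the package take an explicit seed and go
## through this helper so that callers' RNG streams are never disturbed.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(expr)
}

## Frequency grid of the discrete Fourier transform, in cycles per sample
## (same layout as the unshifted FFT output).
fft_freqs <- function(n) {
  k <- c(0:(ceiling(n / 2) - 1L), -(floor(n / 2)):-1L)
  k / n
}

cosine_similarity <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  sum(a * b) / sqrt(sum(a^2) * sum(b^2))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
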
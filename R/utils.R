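#' @importFrom Rcpp sourceCpp
#' @importFrom stats median quantile var mad rnorm runif rpois rlnorm fft
#'   mvfft sd predict setNames
#' @importFrom utils head tail write.csv read.csv
#' @useDynLib whistlevessel, .registration = TRUE
NULL

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Hann window of length n (periodic form used for STFT analysis).
hann_window <- function(n) 0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / n)

# dB helpers on power quantities
db_pow <- function(p) 10 * log10(p)

assert_scalar_num <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lo || x > hi)
    stop(sprintf("%s must be a finite scalar in [%g, %g]", name, lo, hi))
  invisible(x)
}
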
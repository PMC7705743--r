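#' @keywords internal
"_PACKAGE"

#' @useDynLib boatools, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats fft rnorm runif median sd cor quantile nlminb coef
#'   residuals simulate predict
#' @importFrom utils read.csv write.csv modifyList
NULL

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched.  `seed = NULL` uses the current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", globalenv(), inherits = FALSE)
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

stopifnot_scalar <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("`%s` must be a finite numeric scalar", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("`%s` must be > 0", name), call. = FALSE)
  if (nonneg && x < 0)
    stop(sprintf("`%s` must be >= 0", name), call. = FALSE)
  invisible(x)
}

# Periodic Hann window of length n (sum = n/2 for even n)
hann_window <- function(n) {
  0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1L) / n)
}

# FFT-ordered signed frequency indices: 0, 1, ..., -2, -1
fft_freq_index <- function(n) {
  c(0:(ceiling(n / 2) - 1L), -(floor(n / 2)):-1L)
}
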
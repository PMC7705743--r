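#' Simulate an otolith displacement trace from the oscillator model
#'
#' For each epoch of the train the otolith follows its steady-state response
#' to the drive: amplitude |x(f)| and phase arg(x(f)) from the damped,
#' stiffness-bound oscillator model at the epoch frequency.  Outside epochs
#' the trace contains only background noise.
#'
#' @param params a [mechanics_params()] (gamma >= 0, k > 0).
#' @param train a [stimulus_train()].
#' @param frame_rate sampling rate, Hz (default 1000).
#' @param noise_sd additive white background noise sd, same units as the
#'   response (default 0).
#' @param seed optional RNG seed for the noise.
#' @return A [displacement_trace()] (dx in response units, dy = 0).
#' @export
simulate_displacement_trace <- function(params, train, frame_rate = 1000,
                                        noise_sd = 0, seed = NULL) {
  if (!inherits(params, "mechanics_params"))
    params <- do.call(mechanics_params, as.list(params))
  total <- attr(train, "total_duration")
  n <- max(2L, ceiling(total * frame_rate))
  t <- (seq_len(n) - 1L) / frame_rate
  dx <- numeric(n)
  for (i in seq_len(nrow(train))) {
    ep <- train[i, ]
    x <- frequency_response(params, ep$frequency)
    sel <- t >= ep$onset & t < ep$onset + ep$duration
    dx[sel] <- Mod(x) * sin(2 * pi * ep$frequency * (t[sel] - ep$onset) +
                              Arg(x))
  }
  if (noise_sd > 0)
    dx <- dx + with_seed(seed, stats::rnorm(n, 0, noise_sd))
  displacement_trace(t, dx, 0, frame_rate = frame_rate)
}
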
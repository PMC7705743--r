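#' Spectrogram of a displacement trace
#'
#' Magnitude short-time Fourier transform of the stimulation-axis
#' displacement (`dx`), computed with a Hann window of `window_length`
#' seconds (default 1 s, giving 1 Hz frequency bins so the 10/100/1000 Hz
#' stimulation frequencies fall exactly on bins) and 50% overlap.  The
#' `per_frequency` normalization divides each frequency row by its own time
#' mean, which makes stimulus-locked spectral lines stand out against the
#' 1/f background.
#'
#' @param trace a [displacement_trace()].
#' @param window_length window length, seconds (default 1).
#' @param hop hop between window starts, seconds (default
#'   `window_length / 2`).
#' @param normalization `"raw"` or `"per_frequency"`.
#' @param detrend subtract the trace mean before the STFT (default `TRUE`;
#'   suppresses the DC step artifact left by stray trap light).
#' @return A `spectrogram`: list with `magnitude` (frequency x time),
#'   `frequencies` (0 .. Nyquist, Hz), `times` (window centres, s),
#'   `window_length`, `hop`, `normalization`, `frame_rate`.
#' @export
compute_spectrogram <- function(trace, window_length = 1, hop = window_length / 2,
                                normalization = c("raw", "per_frequency"),
                                detrend = TRUE) {
  normalization <- match.arg(normalization)
  fs <- attr(trace, "frame_rate")
  x <- trace$dx_nm
  if (detrend) x <- x - mean(x)
  L <- round(window_length * fs)
  H <- max(1L, round(hop * fs))
  if (L > length(x))
    stop("window longer than trace", call. = FALSE)
  w <- hann_window(L)
  starts <- seq(1L, length(x) - L + 1L, by = H)
  nf <- floor(L / 2) + 1L
  mag <- matrix(0, nrow = nf, ncol = length(starts))
  for (j in seq_along(starts)) {
    seg <- x[starts[j]:(starts[j] + L - 1L)] * w
    X <- stats::fft(seg)
    mag[, j] <- Mod(X[seq_len(nf)])
  }
  if (normalization == "per_frequency") {
    rm_ <- rowMeans(mag)
    nz <- rm_ > 0
    mag[nz, ] <- mag[nz, , drop = FALSE] / rm_[nz]
  }
  structure(list(magnitude = mag,
                 frequencies = (seq_len(nf) - 1L) * fs / L,
                 times = (starts - 1L + L / 2) / fs,
                 window_length = window_length, hop = hop,
                 normalization = normalization, frame_rate = fs),
            class = "spectrogram")
}

#' @export
print.spectrogram <- function(x, ...) {
  cat(sprintf("Spectrogram: %d frequency bins (0-%.4g Hz) x %d windows, %s\n",
              length(x$frequencies), max(x$frequencies), length(x$times),
              x$normalization))
  invisible(x)
}

#' @export
plot.spectrogram <- function(x, ...) {
  graphics::image(x$times, x$frequencies, t(x$magnitude),
                  xlab = "time (s)", ylab = "frequency (Hz)",
                  col = grDevices::hcl.colors(64, "viridis"), ...)
  invisible(x)
}

#' Write a spectrogram as a matrix file with axis headers
#'
#' CSV matrix: first column the frequency axis (Hz), header row the window
#' centre times (s).
#'
#' @param spec a [compute_spectrogram()] result.
#' @param path file path.
#' @export
write_spectrogram <- function(spec, path) {
  m <- as.data.frame(spec$magnitude)
  names(m) <- sprintf("t_%g", spec$times)
  m <- cbind(frequency_hz = spec$frequencies, m)
  write.csv(m, path, row.names = FALSE)
  invisible(path)
}

#' Estimate the sinusoid amplitude at a stimulation frequency
#'
#' Amplitude of the `f_stim` component of the stimulation-axis displacement
#' over one epoch, from the Hann-windowed Fourier coefficient with window
#' gain correction: A = 2 |X(f_stim)| / sum(w).  When `f_stim` falls on an
#' FFT bin the bin value is used directly; otherwise the magnitude peak is
#' interpolated from a 3-point quadratic fit around the nearest bin.  The
#' estimate is invariant to constant offsets (the epoch is mean-subtracted).
#'
#' @param trace a [displacement_trace()].
#' @param f_stim stimulation frequency, Hz (below Nyquist, and with at least
#'   two full cycles inside the epoch).
#' @param epoch `c(onset, duration)` in seconds; default the whole trace.
#' @return Amplitude in nm.
#' @export
estimate_amplitude <- function(trace, f_stim, epoch = NULL) {
  fs <- attr(trace, "frame_rate")
  if (f_stim >= fs / 2)
    stop("f_stim is at or above the Nyquist frequency", call. = FALSE)
  if (is.null(epoch)) epoch <- c(trace$time_s[1], nrow(trace) / fs)
  onset <- epoch[1]; dur <- epoch[2]
  if (dur * f_stim < 2)
    stop("epoch too short: need >= 2 cycles of f_stim", call. = FALSE)
  t_end <- trace$time_s[nrow(trace)] + 1 / fs
  if (onset < trace$time_s[1] - 1e-9 || onset + dur > t_end + 1e-9)
    stop("epoch outside trace", call. = FALSE)
  idx <- which(trace$time_s >= onset - 1e-9 &
                 trace$time_s < onset + dur - 1e-9)
  if (length(idx) < 4L)
    stop("epoch outside trace", call. = FALSE)
  x <- trace$dx_nm[idx]
  x <- x - mean(x)
  L <- length(x)
  w <- hann_window(L)
  X <- Mod(stats::fft(x * w))
  df <- fs / L
  kf <- f_stim / df                      # 0-based bin position
  k0 <- round(kf)
  if (abs(kf - k0) < 1e-6) {
    mag <- X[k0 + 1L]
  } else {
    k0 <- min(max(k0, 2L), floor(L / 2) - 1L)
    a <- X[k0]; b <- X[k0 + 1L]; cc <- X[k0 + 2L]
    den <- a - 2 * b + cc
    delta <- if (abs(den) < 1e-300) 0 else 0.5 * (a - cc) / den
    mag <- b - 0.25 * (a - cc) * delta
  }
  2 * mag / sum(w)
}
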
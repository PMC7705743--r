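#' Synthetic otolith video specification
#'
#' Describes a transillumination-style recording of a dark-field disc (the
#' otolith) vibrating along the image-column (rostro-caudal) axis at
#' 1 kHz frame rate.  Defaults follow the measured displacement scale:
#' 140 nm at 10 Hz stimulation; use 50 nm (saccule) or 15 nm (utricle) with
#' `ground_truth_frequency = 400` for the 400 Hz cases.  Rendering defaults
#' are noiseless; photon noise and heartbeat-like background drift are
#' opt-in via `photon_noise_sd` and `background_drift`.
#'
#' @param frame_rate frames per second (default 1000).
#' @param n_frames number of frames (default 5000, i.e. 5 s).
#' @param pixel_size nm per pixel (default 100).
#' @param disc_radius otolith disc radius in px (default 20).
#' @param image_size `c(rows, cols)` (default `c(64, 64)`).
#' @param disc_intensity,background_intensity 16-bit counts (defaults 10000
#'   and 1000).
#' @param psf_sigma Gaussian optical blur sigma in px (default 0.7).  A
#'   finite point-spread function is what makes the rendered scene
#'   band-limited: a hard-edged disc carries energy above the pixel Nyquist
#'   frequency, which biases cross-correlation registration of subpixel
#'   motion (set 0 to disable).
#' @param photon_noise_sd additive Gaussian noise sd in counts (default 0),
#'   applied after the optical blur, before 16-bit quantization.
#' @param background_drift list `(amplitude, frequency)`: heartbeat-like
#'   sinusoidal drift in nm at ~2 Hz plus a 1/f drift component of the same
#'   amplitude scale (default amplitude 0 = off).
#' @param ground_truth_amplitude vibration amplitude, nm (default 140).
#' @param ground_truth_frequency vibration frequency, Hz (default 10; must
#'   be below `frame_rate / 2`).
#' @param seed RNG seed used for noise and drift (explicit, never global).
#' @return A `video_spec` list.
#' @export
video_spec <- function(frame_rate = 1000, n_frames = 5000, pixel_size = 100,
                       disc_radius = 20, image_size = c(64L, 64L),
                       disc_intensity = 10000, background_intensity = 1000,
                       psf_sigma = 0.7, photon_noise_sd = 0,
                       background_drift = list(amplitude = 0, frequency = 2),
                       ground_truth_amplitude = 140,
                       ground_truth_frequency = 10,
                       seed = 1L) {
  stopifnot_scalar(frame_rate, "frame_rate", positive = TRUE)
  stopifnot_scalar(n_frames, "n_frames", positive = TRUE)
  stopifnot_scalar(pixel_size, "pixel_size", positive = TRUE)
  stopifnot_scalar(disc_radius, "disc_radius", positive = TRUE)
  stopifnot_scalar(psf_sigma, "psf_sigma", nonneg = TRUE)
  stopifnot_scalar(photon_noise_sd, "photon_noise_sd", nonneg = TRUE)
  stopifnot_scalar(ground_truth_amplitude, "ground_truth_amplitude",
                   nonneg = TRUE)
  stopifnot_scalar(ground_truth_frequency, "ground_truth_frequency",
                   positive = TRUE)
  if (ground_truth_frequency >= frame_rate / 2)
    stop("Nyquist violation: ground_truth_frequency must be < frame_rate / 2",
         call. = FALSE)
  structure(list(frame_rate = frame_rate, n_frames = as.integer(n_frames),
                 pixel_size = pixel_size, disc_radius = disc_radius,
                 image_size = as.integer(image_size),
                 disc_intensity = disc_intensity,
                 background_intensity = background_intensity,
                 psf_sigma = psf_sigma,
                 photon_noise_sd = photon_noise_sd,
                 background_drift = background_drift,
                 ground_truth_amplitude = ground_truth_amplitude,
                 ground_truth_frequency = ground_truth_frequency,
                 seed = as.integer(seed)),
            class = "video_spec")
}

# Anti-aliased disc on an nr x nc 0-based pixel grid centred at (cy, cx).
# Interior/exterior pixels are filled analytically; only the boundary band
# (|d - r| < 1 px) is supersampled ss x ss.
render_disc <- function(nr, nc, cy, cx, r, ss = 8L) {
  img <- matrix(0, nr, nc)
  r0 <- max(0L, floor(cy - r - 2)); r1 <- min(nr - 1L, ceiling(cy + r + 2))
  c0 <- max(0L, floor(cx - r - 2)); c1 <- min(nc - 1L, ceiling(cx + r + 2))
  if (r0 > r1 || c0 > c1) return(img)
  rows <- r0:r1; cols <- c0:c1
  d <- sqrt(outer((rows - cy)^2, (cols - cx)^2, `+`))
  cov <- matrix(0, length(rows), length(cols))
  cov[d <= r - 1] <- 1
  band <- which(abs(d - r) < 1)
  if (length(band)) {
    bi <- arrayInd(band, dim(d))
    off <- ((seq_len(ss) - 0.5) / ss) - 0.5
    og <- expand.grid(orow = off, ocol = off)
    py <- rows[bi[, 1]]; px <- cols[bi[, 2]]
    # length(band) x ss^2 squared distances of subpixel sample centres
    dy2 <- outer(py - cy, og$orow, `+`)^2
    dx2 <- outer(px - cx, og$ocol, `+`)^2
    cov[band] <- rowMeans((dy2 + dx2) <= r^2)
  }
  img[rows + 1L, cols + 1L] <- cov
  img
}

# Replicate-padded separable Gaussian blur as a 1-D convolution matrix;
# frame blur is then K %*% img %*% t(K).
blur_matrix <- function(n, sigma) {
  if (sigma <= 0) return(diag(n))
  r <- ceiling(3 * sigma)
  K <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- pmin(pmax((i - r):(i + r), 1L), n)   # replicate padding
    w <- stats::dnorm(-r:r, 0, sigma)
    for (m in seq_along(j)) K[i, j[m]] <- K[i, j[m]] + w[m]
    K[i, ] <- K[i, ] / sum(K[i, ])
  }
  K
}

# 1/f-shaped random drift of length n, scaled to sd `amp`.
one_over_f_drift <- function(n, amp) {
  if (amp <= 0 || n < 4) return(numeric(n))
  wn <- stats::rnorm(n)
  X <- stats::fft(wn)
  f <- abs(fft_freq_index(n))
  shape <- ifelse(f == 0, 0, 1 / sqrt(f))
  x <- Re(stats::fft(X * shape, inverse = TRUE)) / n
  x <- x - mean(x)
  s <- stats::sd(x)
  if (s == 0) numeric(n) else x * amp / s
}

#' Render a synthetic otolith video
#'
#' Draws an anti-aliased disc undergoing band-limited subpixel translation
#' along the image-column axis: sinusoidal vibration at the ground-truth
#' amplitude/frequency (confined to stimulation epochs when a `train` is
#' given, continuous otherwise), plus optional heartbeat-like background
#' drift (a sinusoid at `background_drift$frequency` and a 1/f component)
#' and additive Gaussian photon noise.  Frames are quantized to 16-bit
#' integer counts.  Identical `spec` (including `seed`) gives a bit-identical
#' stack.
#'
#' @param spec a [video_spec()].
#' @param train optional [stimulus_train()]; vibration occurs only inside
#'   its epochs, at each epoch's frequency.
#' @return An `otolith_video`: list with `stack` (rows x cols x frames
#'   array of counts), `truth` (the exact [displacement_trace()] used, nm)
#'   and `spec`.
#' @export
render_otolith_video <- function(spec, train = NULL) {
  if (!inherits(spec, "video_spec")) spec <- do.call(video_spec, spec)
  n <- spec$n_frames
  fs <- spec$frame_rate
  t <- (seq_len(n) - 1L) / fs
  A <- spec$ground_truth_amplitude
  f0 <- spec$ground_truth_frequency
  if (is.null(train)) {
    dx_sig <- A * sin(2 * pi * f0 * t)
  } else {
    dx_sig <- numeric(n)
    for (i in seq_len(nrow(train))) {
      ep <- train[i, ]
      if (ep$frequency >= fs / 2)
        stop("Nyquist violation: epoch frequency >= frame_rate / 2",
             call. = FALSE)
      sel <- t >= ep$onset & t < ep$onset + ep$duration
      dx_sig[sel] <- A * sin(2 * pi * ep$frequency * (t[sel] - ep$onset))
    }
  }
  drift_amp <- spec$background_drift$amplitude %||% 0
  drift_f <- spec$background_drift$frequency %||% 2
  with_seed(spec$seed, {
    if (drift_amp > 0) {
      phase <- stats::runif(1, 0, 2 * pi)
      drift <- drift_amp * sin(2 * pi * drift_f * t + phase) +
        one_over_f_drift(n, drift_amp / 2)
    } else drift <- numeric(n)
    dx <- dx_sig + drift
    nr <- spec$image_size[1]; nc <- spec$image_size[2]
    cy <- (nr - 1) / 2
    cx0 <- (nc - 1) / 2
    bg <- spec$background_intensity
    amp_i <- spec$disc_intensity - bg
    Kr <- blur_matrix(nr, spec$psf_sigma)
    Kc <- blur_matrix(nc, spec$psf_sigma)
    stack <- array(0, dim = c(nr, nc, n))
    for (i in seq_len(n)) {
      cov <- render_disc(nr, nc, cy, cx0 + dx[i] / spec$pixel_size,
                         spec$disc_radius)
      frame <- bg + amp_i * cov
      if (spec$psf_sigma > 0) frame <- Kr %*% frame %*% t(Kc)
      if (spec$photon_noise_sd > 0)
        frame <- frame + stats::rnorm(nr * nc, 0, spec$photon_noise_sd)
      stack[, , i] <- pmin(pmax(round(frame), 0), 65535)
    }
  })
  attr(stack, "frame_rate") <- fs
  structure(list(stack = stack,
                 truth = displacement_trace(t, dx, 0, frame_rate = fs,
                                            pixel_size = spec$pixel_size),
                 spec = spec),
            class = "otolith_video")
}

#' @export
print.otolith_video <- function(x, ...) {
  d <- dim(x$stack)
  cat(sprintf("Synthetic otolith video: %dx%d px, %d frames @ %g Hz (%g nm @ %g Hz)\n",
              d[1], d[2], d[3], x$spec$frame_rate,
              x$spec$ground_truth_amplitude, x$spec$ground_truth_frequency))
  invisible(x)
}
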
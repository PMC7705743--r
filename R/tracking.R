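#' Displacement trace
#'
#' Time-stamped 2-D otolith displacement in nm at a uniform frame rate.
#' `dx` is the image-column axis (the rostro-caudal stimulation axis),
#' `dy` the image-row axis; origin top-left, 0-based.
#'
#' @param time_s time stamps, seconds (uniform).
#' @param dx_nm,dy_nm displacements in nm.
#' @param frame_rate sampling rate, Hz.
#' @param pixel_size nm per pixel (NA if not derived from video).
#' @return A `displacement_trace` data frame.
#' @export
displacement_trace <- function(time_s, dx_nm, dy_nm = 0, frame_rate,
                               pixel_size = NA_real_) {
  n <- length(time_s)
  if (length(dy_nm) == 1L) dy_nm <- rep(dy_nm, n)
  if (length(dx_nm) != n || length(dy_nm) != n)
    stop("time and displacement vectors must have equal length", call. = FALSE)
  if (n > 2L) {
    dt <- diff(time_s)
    if (max(abs(dt - dt[1])) > 1e-9 * max(dt[1], 1e-12))
      stop("time stamps must be uniformly spaced", call. = FALSE)
  }
  structure(data.frame(time_s = time_s, dx_nm = dx_nm, dy_nm = dy_nm),
            frame_rate = frame_rate, pixel_size = pixel_size,
            class = c("displacement_trace", "data.frame"))
}

#' Subpixel image registration by cross-correlation
#'
#' Estimates the translation of `frame` relative to `reference` by locating
#' the cross-correlation peak, then refining it to `1/upsample_factor` px by
#' a locally upsampled discrete Fourier transform evaluated in a 1.5 px
#' neighbourhood of the coarse peak (matrix-multiply DFT; no large zero-padded
#' FFT is formed).  Both images are mean-subtracted before correlation.
#'
#' The returned shift `(dx, dy)` is the displacement of the frame content in
#' (columns, rows): `frame ~ reference` translated by `+dx` columns and
#' `+dy` rows.  Swapping `frame` and `reference` negates the shift.
#'
#' @param frame,reference numeric matrices of identical dimensions.
#' @param upsample_factor integer >= 1; subpixel resolution is
#'   `1/upsample_factor` px (default 100).
#' @return List with `dx`, `dy` (pixels) and `peak_correlation` (normalized
#'   correlation at the peak, in \[0, 1\]).
#' @references Guizar-Sicairos, Thurman & Fienup (2008) Opt. Lett. 33:156.
#' @export
register_subpixel <- function(frame, reference, upsample_factor = 100L) {
  if (!all(dim(frame) == dim(reference)))
    stop("frame and reference must have the same shape", call. = FALSE)
  if (upsample_factor < 1) stop("upsample_factor must be >= 1", call. = FALSE)
  f <- frame - mean(frame)
  r <- reference - mean(reference)
  if (sum(f^2) == 0 || sum(r^2) == 0)
    stop("degenerate input: image has zero variance", call. = FALSE)
  register_core(stats::fft(f), stats::fft(r), upsample_factor,
                norm = sqrt(sum(f^2) * sum(r^2)))
}

# Core registration on precomputed 2-D FFTs of mean-subtracted images.
register_core <- function(F1, F2, usfac, norm) {
  nr <- nrow(F1); nc <- ncol(F1)
  P <- F1 * Conj(F2)
  cc <- stats::fft(P, inverse = TRUE) / (nr * nc)
  pk <- arrayInd(which.max(Mod(cc)), dim(cc))
  sr <- pk[1] - 1L; if (sr > nr / 2) sr <- sr - nr
  sc <- pk[2] - 1L; if (sc > nc / 2) sc <- sc - nc
  peak <- Mod(cc[pk[1], pk[2]])
  if (usfac > 1) {
    nloc <- ceiling(1.5 * usfac)
    dftshift <- floor(nloc / 2)
    up <- dft_upsample(P, nloc, nloc, usfac,
                       roff = dftshift - sr * usfac,
                       coff = dftshift - sc * usfac)
    mu <- Mod(up)
    pk2 <- arrayInd(which.max(mu), dim(mu))
    sr <- sr + (pk2[1] - 1L - dftshift) / usfac
    sc <- sc + (pk2[2] - 1L - dftshift) / usfac
    peak <- mu[pk2[1], pk2[2]] / (nr * nc)
  }
  list(dx = sc, dy = sr, peak_correlation = min(peak / norm, 1))
}

# Upsampled inverse DFT of cross-spectrum P on an (nor x noc) grid with
# spacing 1/usfac px, offset so output row i maps to lag (i - roff)/usfac.
dft_upsample <- function(P, nor, noc, usfac, roff, coff) {
  nr <- nrow(P); nc <- ncol(P)
  fr <- fft_freq_index(nr)
  fc <- fft_freq_index(nc)
  kern_r <- exp((2i * pi / (nr * usfac)) * outer((0:(nor - 1)) - roff, fr))
  kern_c <- exp((2i * pi / (nc * usfac)) * outer(fc, (0:(noc - 1)) - coff))
  kern_r %*% P %*% kern_c
}

#' Track otolith displacement through an image stack
#'
#' Registers every frame against one fixed reference frame (the first, by
#' default, so that drift does not accumulate through a running reference)
#' and converts pixel shifts to nm.
#'
#' @param stack a numeric array (rows x cols x frames) or an
#'   `otolith_video` from [render_otolith_video()].
#' @param reference index of the reference frame (default 1).
#' @param pixel_size nm per pixel (taken from the video spec if available).
#' @param upsample_factor see [register_subpixel()].
#' @param detrend subtract the mean displacement (default `TRUE`).
#' @param crop optional crop region `c(row0, col0, height, width)`, 0-based
#'   half-open, applied to every frame before registration.
#' @return A [displacement_trace()].
#' @export
track_displacement <- function(stack, reference = 1L, pixel_size = NULL,
                               upsample_factor = 100L, detrend = TRUE,
                               crop = NULL) {
  if (inherits(stack, "otolith_video")) {
    pixel_size <- pixel_size %||% stack$spec$pixel_size
    frame_rate <- stack$spec$frame_rate
    stack <- stack$stack
  } else {
    frame_rate <- attr(stack, "frame_rate") %||% NA_real_
  }
  if (is.null(pixel_size))
    stop("pixel_size (nm/px) is required", call. = FALSE)
  if (length(dim(stack)) != 3L || dim(stack)[3] < 2L)
    stop("stack length >= 2 required", call. = FALSE)
  if (!is.null(crop)) {
    rows <- (crop[1] + 1):(crop[1] + crop[3])
    cols <- (crop[2] + 1):(crop[2] + crop[4])
    stack <- stack[rows, cols, , drop = FALSE]
  }
  n <- dim(stack)[3]
  ref <- stack[, , reference]
  refc <- ref - mean(ref)
  if (sum(refc^2) == 0)
    stop("degenerate reference frame: zero variance", call. = FALSE)
  F2 <- stats::fft(refc)
  e_ref <- sum(refc^2)
  dx <- dy <- numeric(n)
  for (i in seq_len(n)) {
    fr <- stack[, , i]
    frc <- fr - mean(fr)
    e <- sum(frc^2)
    if (e == 0)
      stop(sprintf("degenerate input at frame %d: zero variance", i),
           call. = FALSE)
    res <- register_core(stats::fft(frc), F2, upsample_factor,
                         norm = sqrt(e * e_ref))
    dx[i] <- res$dx
    dy[i] <- res$dy
  }
  dx <- dx * pixel_size
  dy <- dy * pixel_size
  if (detrend) {
    dx <- dx - mean(dx)
    dy <- dy - mean(dy)
  }
  if (is.na(frame_rate))
    stop("frame_rate unknown: supply a stack with a frame_rate attribute",
         call. = FALSE)
  displacement_trace((seq_len(n) - 1L) / frame_rate, dx, dy,
                     frame_rate = frame_rate, pixel_size = pixel_size)
}

#' Read / write displacement traces as CSV
#'
#' Columns `time_s`, `dx_nm`, `dy_nm`; frame rate is recovered from the time
#' stamps.
#'
#' @param trace a [displacement_trace()].
#' @param path file path.
#' @export
write_displacement_trace <- function(trace, path) {
  write.csv(as.data.frame(trace), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_displacement_trace
#' @export
read_displacement_trace <- function(path) {
  df <- read.csv(path)
  fr <- 1 / stats::median(diff(df$time_s))
  displacement_trace(df$time_s, df$dx_nm, df$dy_nm, frame_rate = fr)
}
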
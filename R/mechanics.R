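#' Otolith mechanics parameters
#'
#' The otolith is modelled as a driven, damped, stiffness-bound body: in the
#' Fourier domain its position under a drive force of amplitude `force` at
#' frequency f is x(f) = F / (k + i 2 pi gamma f - m (2 pi f)^2), where
#' `gamma` is the viscous drag coefficient of the ear fluid, `k` the
#' elasticity constant of the hair cells, and the mass term is neglected by
#' default (`mass = 0`).  Units need only be mutually consistent; throughout
#' the package amplitudes are treated as nm and frequencies as Hz.
#'
#' @param gamma viscous drag coefficient (force * s / length), >= 0.
#' @param k hair-cell elasticity constant (force / length), > 0.
#' @param force drive force amplitude F, >= 0 (default 1).
#' @param mass otolith mass (default 0, i.e. neglected).
#' @return An object of class `mechanics_params`.
#' @export
mechanics_params <- function(gamma, k, force = 1, mass = 0) {
  stopifnot_scalar(gamma, "gamma", nonneg = TRUE)
  stopifnot_scalar(k, "k", positive = TRUE)
  stopifnot_scalar(force, "force", nonneg = TRUE)
  stopifnot_scalar(mass, "mass", nonneg = TRUE)
  structure(list(gamma = gamma, k = k, force = force, mass = mass),
            class = "mechanics_params")
}

#' Mass densities of otolith and ear fluid
#'
#' @param rho_fluid ear-fluid mass density (> 0).
#' @param rho_otolith otolith mass density (> 0), same units.
#' @return An object of class `densities`.
#' @export
densities <- function(rho_fluid, rho_otolith) {
  stopifnot_scalar(rho_fluid, "rho_fluid", positive = TRUE)
  stopifnot_scalar(rho_otolith, "rho_otolith", positive = TRUE)
  structure(list(rho_fluid = rho_fluid, rho_otolith = rho_otolith),
            class = "densities")
}

#' Effective acceleration of an otolith under whole-body acceleration
#'
#' During acoustic stimulation the whole larva accelerates with the water;
#' only the otolith's motion relative to the body deflects hair cells.  The
#' relevant effective acceleration is (1 - rho_fluid / rho_otolith) * a: a
#' dense otolith (rho_otolith >> rho_fluid) feels nearly the full body
#' acceleration, a neutrally buoyant one feels none.
#'
#' @param a body acceleration (any consistent units).
#' @param d a [densities()] object.
#' @return Effective acceleration, same units as `a`.
#' @export
effective_acceleration <- function(a, d) {
  if (!inherits(d, "densities")) d <- do.call(densities, as.list(d))
  (1 - d$rho_fluid / d$rho_otolith) * a
}

#' Complex frequency response of the otolith
#'
#' x(f) = F / (k + i 2 pi gamma f - m (2 pi f)^2).  At f = 0 the response is
#' the purely real static deflection F/k; for gamma > 0 the amplitude decays
#' towards the 1/f drag-dominated asymptote and the phase tends to -90 deg.
#'
#' @param p a [mechanics_params()] object.
#' @param f frequency or vector of frequencies, Hz (>= 0).
#' @return Complex displacement(s); `Mod()` gives the amplitude, `Arg()` the
#'   phase.
#' @export
frequency_response <- function(p, f) {
  if (!inherits(p, "mechanics_params")) p <- do.call(mechanics_params, as.list(p))
  if (any(f < 0)) stop("frequencies must be >= 0", call. = FALSE)
  w <- 2 * pi * f
  p$force / complex(real = p$k - p$mass * w^2, imaginary = p$gamma * w)
}

#' Amplitude-frequency curve
#'
#' Measured (or predicted) otolith vibration amplitudes at a set of
#' stimulation frequencies, for one organ.
#'
#' @param frequencies strictly increasing frequencies, Hz.
#' @param amplitudes non-negative amplitudes, nm.
#' @param organ `"utricle"`, `"saccule"`, or `NA`.
#' @return An `amplitude_curve` data frame.
#' @export
amplitude_curve <- function(frequencies, amplitudes, organ = NA_character_) {
  if (length(frequencies) != length(amplitudes))
    stop("frequencies and amplitudes must have equal length", call. = FALSE)
  if (length(frequencies) == 0L)
    stop("empty frequency list", call. = FALSE)
  if (any(diff(frequencies) <= 0))
    stop("frequencies must be strictly increasing", call. = FALSE)
  if (any(amplitudes < 0)) stop("amplitudes must be >= 0", call. = FALSE)
  structure(data.frame(frequency_hz = as.numeric(frequencies),
                       amplitude_nm = as.numeric(amplitudes)),
            organ = as.character(organ),
            class = c("amplitude_curve", "data.frame"))
}

#' Predict the amplitude-frequency curve of the oscillator model
#'
#' |x(f)| = F / sqrt((k - m (2 pi f)^2)^2 + (2 pi gamma f)^2).  With the mass
#' neglected the curve is monotone non-increasing, has plateau F/k at low
#' frequency, and falls off as 1/f (log-log slope -1) at high frequency.
#'
#' @inheritParams frequency_response
#' @param frequencies frequencies in Hz (> 0 or 0 allowed).
#' @param organ passed through to the returned curve.
#' @return An [amplitude_curve()].
#' @export
predict_amplitude_curve <- function(p, frequencies, organ = NA_character_) {
  if (length(frequencies) == 0L) stop("empty frequency list", call. = FALSE)
  amplitude_curve(frequencies, Mod(frequency_response(p, frequencies)),
                  organ = organ)
}

#' Read / write amplitude curves as CSV
#'
#' Columns `frequency_hz`, `amplitude_nm`, `organ`.
#'
#' @param curve an [amplitude_curve()].
#' @param path file path.
#' @export
write_amplitude_curve <- function(curve, path) {
  df <- as.data.frame(curve)
  df$organ <- attr(curve, "organ")
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_amplitude_curve
#' @export
read_amplitude_curve <- function(path) {
  df <- read.csv(path)
  amplitude_curve(df$frequency_hz, df$amplitude_nm,
                  organ = if ("organ" %in% names(df)) df$organ[1] else NA)
}
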
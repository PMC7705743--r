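#' Fit the otolith oscillator model to an amplitude-frequency curve
#'
#' Least-squares fit of |x(f)| = F / sqrt((k - m w^2)^2 + (gamma w)^2)
#' (w = 2 pi f) to measured amplitudes, performed on log-amplitudes with
#' equal weight per frequency point so that the decades-spanning curve is not
#' dominated by its low-frequency plateau.  From amplitudes alone only the
#' ratios F/k (the low-frequency plateau) and F/gamma (the high-frequency
#' 1/f asymptote, via |x| -> (F/gamma)/w) are identifiable; absolute gamma
#' and k are reported only when the caller fixes the drive force `force`.
#'
#' Internally the model is parameterised as |x|^-2 = (u - w_m w^2)^2 + v w^2
#' with u = k/F >= 0, v = (gamma/F)^2 >= 0, which makes the noiseless
#' no-mass problem exactly linear in (u^2, v); that linear solution seeds a
#' bounded `nlminb` refinement on the log-amplitude objective.  A curve with
#' no measurable high-frequency decay fits v = 0: the gamma estimate is ~0,
#' `F/gamma` is reported as `Inf` and `gamma_zero` is flagged.
#'
#' @param curve an [amplitude_curve()] (or data frame with columns
#'   `frequency_hz`, `amplitude_nm`); needs >= 2 distinct frequencies with
#'   positive amplitude.
#' @param force optional known drive force F; unlocks absolute `gamma`, `k`
#'   (and `mass`).
#' @param mass logical; include the inertial term (default `FALSE`,
#'   i.e. mass neglected).
#' @return An object of class `mechanics_fit` with components
#'   `ratios` (`F_over_k`, `F_over_gamma`), `gamma_zero`, `residual_norm`
#'   (on log-amplitudes), `fitted`, `data`, and -- when `force` is given --
#'   `gamma`, `k` (and `mass_estimate`).
#' @seealso [predict.mechanics_fit()], [simulate.mechanics_fit()]
#' @examples
#' p <- mechanics_params(gamma = 0.05, k = 2, force = 1)
#' curve <- predict_amplitude_curve(p, 10^seq(0, 3, length.out = 8))
#' fit <- fit_mechanics(curve)
#' coef(fit)   # F/k = 0.5, F/gamma = 20
#' @export
fit_mechanics <- function(curve, force = NULL, mass = FALSE) {
  f <- curve$frequency_hz
  A <- curve$amplitude_nm
  keep <- is.finite(f) & is.finite(A) & A > 0 & f > 0
  f <- f[keep]; A <- A[keep]
  if (length(unique(f)) < 2L)
    stop("need >= 2 distinct frequencies with positive amplitudes",
         call. = FALSE)
  if (length(unique(A)) < 2L && length(unique(f)) < 3L)
    stop("underdetermined: amplitudes all equal at < 3 frequencies",
         call. = FALSE)
  w <- 2 * pi * f
  logA <- log(A)

  # u and v live on wildly different scales (v ~ u^2 / w_max^2), so the
  # search runs in log-parameters.  Two analytic starts: a linear seed
  # (A^-2 = u^2 + v w^2 is linear in (u^2, v)) and the plateau/half-power
  # heuristic; keep whichever converges lower.
  vfloor <- (min(A)^-2 / max(w)^2) * 1e-14
  X <- cbind(1, w^2)
  ab <- tryCatch(solve(crossprod(X), crossprod(X, A^-2)),
                 error = function(e) c(mean(A^-2), 0))
  u0a <- sqrt(max(ab[1], min(A^-2) * 1e-2))
  v0a <- max(ab[2], vfloor)
  plateau <- A[which.min(f)]
  u0b <- 1 / plateau
  below <- which(A < plateau / sqrt(2))
  v0b <- if (length(below)) u0b^2 / min(w[below])^2 else vfloor

  obj <- function(par) {
    u <- exp(par[1]); v <- exp(par[2])
    wm <- if (mass) exp(par[3]) else 0
    a2inv <- (u - wm * w^2)^2 + v * w^2
    if (any(a2inv <= 0) || any(!is.finite(a2inv))) return(1e10)
    sum((logA + 0.5 * log(a2inv))^2)
  }
  wm_init <- if (mass) log(u0a / max(w)^2 * 1e-3)
  starts <- list(c(log(u0a), log(v0a), wm_init),
                 c(log(u0b), log(v0b), wm_init))
  opt <- NULL
  for (s in starts) {
    o <- nlminb(s, obj, control = list(iter.max = 500, eval.max = 1000))
    if (is.null(opt) || o$objective < opt$objective) opt <- o
  }
  u <- exp(opt$par[1]); v <- exp(opt$par[2])
  wm <- if (mass) exp(opt$par[3]) else 0

  F_over_k <- 1 / u
  # gamma ~ 0 when the fitted decay is negligible over the observed band
  gamma_zero <- v * max(w)^2 < u^2 * 1e-10
  F_over_gamma <- if (gamma_zero) Inf else 1 / sqrt(v)
  fitted_amp <- 1 / sqrt((u - wm * w^2)^2 + v * w^2)

  out <- list(
    ratios = c(F_over_k = F_over_k, F_over_gamma = F_over_gamma),
    gamma_zero = gamma_zero,
    residual_norm = sqrt(obj(opt$par)),
    par = c(u = u, v = v, w_m = wm),
    mass = mass,
    force = force,
    fitted = fitted_amp,
    data = data.frame(frequency_hz = f, amplitude_nm = A),
    organ = attr(curve, "organ"),
    n = length(f),
    convergence = opt$convergence,
    call = match.call()
  )
  if (!is.null(force)) {
    stopifnot_scalar(force, "force", positive = TRUE)
    out$k <- force * u
    out$gamma <- if (gamma_zero) 0 else force * sqrt(v)
    if (mass) out$mass_estimate <- force * wm
  }
  class(out) <- "mechanics_fit"
  out
}

#' @export
print.mechanics_fit <- function(x, ...) {
  cat("Otolith oscillator fit (", if (x$mass) "with" else "neglecting",
      " mass)\n", sep = "")
  cat(sprintf("  F/k     = %.6g  (low-frequency plateau, nm)\n",
              x$ratios["F_over_k"]))
  cat(sprintf("  F/gamma = %.6g  (1/f asymptote scale, nm*Hz*2pi)\n",
              x$ratios["F_over_gamma"]))
  if (x$gamma_zero) cat("  note: no measurable decay; gamma ~ 0\n")
  if (!is.null(x$k))
    cat(sprintf("  with F = %g:  k = %.6g, gamma = %.6g\n",
                x$force, x$k, x$gamma))
  cat(sprintf("  residual norm (log-amplitude) = %.3g on %d points\n",
              x$residual_norm, x$n))
  invisible(x)
}

#' @export
summary.mechanics_fit <- function(object, ...) {
  res <- residuals(object)
  structure(list(fit = object,
                 resid_summary = summary(res),
                 corner_hz = object$ratios["F_over_gamma"] /
                   object$ratios["F_over_k"] / (2 * pi)),
            class = "summary.mechanics_fit")
}

#' @export
print.summary.mechanics_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  corner frequency k/(2 pi gamma) = %.6g Hz\n", x$corner_hz))
  cat("  log-amplitude residuals:\n")
  print(x$resid_summary)
  invisible(x)
}

#' @export
coef.mechanics_fit <- function(object, ...) {
  if (!is.null(object$k))
    c(object$ratios, gamma = object$gamma, k = object$k)
  else object$ratios
}

#' @export
residuals.mechanics_fit <- function(object, ...) {
  log(object$data$amplitude_nm) - log(object$fitted)
}

#' Predict amplitudes from a fitted oscillator model
#'
#' @param object a [fit_mechanics()] result.
#' @param frequencies frequencies in Hz at which to predict (defaults to the
#'   fitted ones).
#' @param ... unused.
#' @return An [amplitude_curve()].
#' @export
predict.mechanics_fit <- function(object, frequencies = NULL, ...) {
  f <- frequencies %||% object$data$frequency_hz
  w <- 2 * pi * f
  amp <- 1 / sqrt((object$par["u"] - object$par["w_m"] * w^2)^2 +
                    object$par["v"] * w^2)
  amplitude_curve(f, amp, organ = object$organ)
}

#' Simulate noisy amplitude curves from a fitted oscillator model
#'
#' Draws curves with i.i.d. multiplicative log-normal noise whose log-sd
#' defaults to the fit's residual scale.
#'
#' @param object a [fit_mechanics()] result.
#' @param nsim number of curves.
#' @param seed optional seed.
#' @param noise_sd sd of log-amplitude noise.
#' @param ... unused.
#' @return List of [amplitude_curve()]s.
#' @export
simulate.mechanics_fit <- function(object, nsim = 1, seed = NULL,
                                   noise_sd = NULL, ...) {
  noise_sd <- noise_sd %||% max(object$residual_norm / sqrt(object$n), 1e-12)
  base <- predict(object)
  with_seed(seed, lapply(seq_len(nsim), function(i) {
    amplitude_curve(base$frequency_hz,
                    base$amplitude_nm * exp(rnorm(nrow(base), 0, noise_sd)),
                    organ = object$organ)
  }))
}

#' Plot a fitted amplitude-frequency curve
#'
#' Log-log plot of measured amplitudes with the fitted model curve.
#'
#' @param x a [fit_mechanics()] result.
#' @param ... passed to [graphics::plot()].
#' @export
plot.mechanics_fit <- function(x, ...) {
  f <- x$data$frequency_hz
  graphics::plot(f, x$data$amplitude_nm, log = "xy",
                 xlab = "frequency (Hz)", ylab = "amplitude (nm)",
                 pch = 1, ...)
  fgrid <- exp(seq(log(min(f)), log(max(f)), length.out = 200))
  graphics::lines(fgrid, predict(x, fgrid)$amplitude_nm, col = 2)
  invisible(x)
}

#' Write a mechanics fit report as JSON
#'
#' @param fit a [fit_mechanics()] result.
#' @param path file path.
#' @export
write_mechanics_fit <- function(fit, path) {
  rep <- list(F_over_k = unname(fit$ratios["F_over_k"]),
              F_over_gamma = unname(fit$ratios["F_over_gamma"]),
              gamma_zero = fit$gamma_zero,
              residual_norm = fit$residual_norm,
              n_points = fit$n,
              organ = fit$organ)
  if (!is.null(fit$k)) rep <- c(rep, list(gamma = fit$gamma, k = fit$k,
                                          force = fit$force))
  jsonlite::write_json(rep, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
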
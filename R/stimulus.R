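#' Stimulation epochs and trains
#'
#' A stimulus train is an ordered, non-overlapping set of stimulation epochs.
#' Each epoch vibrates a target organ -- the utricular otolith, the saccular
#' otolith, both at once (dual optical traps), or plays an acoustic tone from
#' a speaker -- at a fixed frequency for a fixed duration, followed by a rest
#' period.  The default protocol uses 1 s of stimulation and 4 s of rest,
#' with three trials per (target, frequency) configuration.
#'
#' @param epochs data frame with columns `target`, `frequency`, `onset`,
#'   `duration`, `rest_after` (and optionally `trial`).
#' @param total_duration total recording length in seconds; defaults to the
#'   end of the last rest period.
#' @return A `stimulus_train`: a data frame of epochs with attribute
#'   `total_duration`.
#' @export
stimulus_train <- function(epochs, total_duration = NULL) {
  if (is.null(epochs) || nrow(epochs) == 0L) {
    epochs <- data.frame(target = character(), frequency = numeric(),
                         onset = numeric(), duration = numeric(),
                         rest_after = numeric(), trial = integer())
    total_duration <- total_duration %||% 0
  } else {
    needed <- c("target", "frequency", "onset", "duration")
    missing <- setdiff(needed, names(epochs))
    if (length(missing))
      stop("epochs lack column(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    if (is.null(epochs$rest_after)) epochs$rest_after <- 4
    if (is.null(epochs$trial)) epochs$trial <- seq_len(nrow(epochs))
    epochs$target <- as.character(epochs$target)
    validate_targets(epochs$target)
    if (any(epochs$frequency <= 0)) stop("frequencies must be > 0", call. = FALSE)
    if (any(epochs$duration <= 0)) stop("durations must be > 0", call. = FALSE)
    epochs <- epochs[order(epochs$onset), , drop = FALSE]
    rownames(epochs) <- NULL
    ends <- epochs$onset + epochs$duration
    if (nrow(epochs) > 1L && any(epochs$onset[-1L] < ends[-nrow(epochs)] - 1e-12))
      stop("stimulus epochs overlap", call. = FALSE)
    last_end <- ends[nrow(epochs)] + epochs$rest_after[nrow(epochs)]
    total_duration <- total_duration %||% last_end
    if (total_duration < ends[nrow(epochs)])
      stop("total_duration ends before the last epoch", call. = FALSE)
  }
  structure(epochs, total_duration = total_duration,
            class = c("stimulus_train", "data.frame"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

valid_targets <- c("utricle", "saccule", "both", "speaker")

validate_targets <- function(x) {
  bad <- setdiff(unique(x), valid_targets)
  if (length(bad))
    stop("unknown stimulation target(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  invisible(x)
}

#' Build a stimulus train from a configuration grid
#'
#' Lays out `n_trials` consecutive epochs per configuration (rows of
#' `configurations`), each `duration` seconds of stimulation followed by
#' `rest_after` seconds of rest, starting at time `start`.  Configurations
#' are presented blockwise in the order given; the layout is deterministic.
#'
#' @param configurations data frame with columns `target`
#'   (utricle/saccule/both/speaker) and `frequency` (Hz).
#' @param n_trials trials per configuration (default 3).
#' @param duration stimulation time per epoch, seconds (default 1).
#' @param rest_after rest time after each epoch, seconds (default 4).
#' @param start onset of the first epoch, seconds (default 0).
#' @return A [stimulus_train()].
#' @examples
#' make_stimulus_train(data.frame(target = "utricle", frequency = 100))
#' @export
make_stimulus_train <- function(configurations, n_trials = 3L, duration = 1,
                                rest_after = 4, start = 0) {
  if (is.null(configurations) || nrow(configurations) == 0L)
    return(stimulus_train(NULL))
  stopifnot_scalar(duration, "duration", positive = TRUE)
  stopifnot_scalar(rest_after, "rest_after", nonneg = TRUE)
  validate_targets(as.character(configurations$target))
  n_cfg <- nrow(configurations)
  idx <- rep(seq_len(n_cfg), each = n_trials)
  period <- duration + rest_after
  epochs <- data.frame(
    target = as.character(configurations$target)[idx],
    frequency = configurations$frequency[idx],
    onset = start + (seq_along(idx) - 1L) * period,
    duration = duration,
    rest_after = rest_after,
    trial = rep(seq_len(n_trials), times = n_cfg)
  )
  stimulus_train(epochs)
}

#' Default BOA configuration grid
#'
#' The targeted-otolith grid \{utricle, saccule, both\} x \{1, 10, 100,
#' 1000 Hz\} plus a 100 Hz acoustic tone from the speaker.
#'
#' @param frequencies BOA frequencies in Hz.
#' @param speaker_frequency tone frequency in Hz (`NULL` to omit).
#' @return Data frame with columns `target` and `frequency`.
#' @export
default_configurations <- function(frequencies = c(1, 10, 100, 1000),
                                   speaker_frequency = 100) {
  grid <- expand.grid(frequency = frequencies,
                      target = c("utricle", "saccule", "both"),
                      stringsAsFactors = FALSE)[, c("target", "frequency")]
  if (!is.null(speaker_frequency))
    grid <- rbind(grid, data.frame(target = "speaker",
                                   frequency = speaker_frequency))
  grid
}

#' Default stimulus train
#'
#' The full default protocol: three trials per configuration of
#' [default_configurations()], 1 s stimulation + 4 s rest, preceded by
#' `baseline` seconds of pre-stimulus rest (used as the baseline for the
#' "1 SD above baseline" cluster criterion).
#'
#' @param baseline pre-stimulus rest in seconds (default 30).
#' @inheritParams make_stimulus_train
#' @return A [stimulus_train()] with 39 epochs under the defaults.
#' @export
default_stimulus_train <- function(baseline = 30, n_trials = 3L) {
  make_stimulus_train(default_configurations(), n_trials = n_trials,
                      start = baseline)
}

#' @export
print.stimulus_train <- function(x, ...) {
  cat(sprintf("Stimulus train: %d epochs, %.1f s total\n", nrow(x),
              attr(x, "total_duration")))
  if (nrow(x)) {
    cfg <- unique(paste0(x$target, "@", x$frequency, "Hz"))
    cat("  configurations:", paste(cfg, collapse = ", "), "\n")
  }
  invisible(x)
}

# Unique configurations of a train, in order of first appearance.
train_configurations <- function(train) {
  if (nrow(train) == 0L) return(data.frame(target = character(),
                                           frequency = numeric()))
  key <- paste0(train$target, "@", train$frequency)
  first <- !duplicated(key)
  data.frame(target = train$target[first], frequency = train$frequency[first])
}

config_key <- function(target, frequency) paste0(target, "@", frequency)

#' Write / read a stimulus train as JSON
#'
#' @param train a [stimulus_train()].
#' @param path file path.
#' @return `read_stimulus_train` returns a [stimulus_train()];
#'   `write_stimulus_train` returns `path` invisibly.
#' @export
write_stimulus_train <- function(train, path) {
  obj <- list(total_duration = attr(train, "total_duration"),
              epochs = as.data.frame(train))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_stimulus_train
#' @export
read_stimulus_train <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  ep <- as.data.frame(obj$epochs)
  if (length(ep) == 0L || nrow(ep) == 0L) ep <- NULL
  stimulus_train(ep, total_duration = obj$total_duration)
}

#' Volumetric acquisition rate
#'
#' Volume rate of a plane-scanned light-sheet acquisition: `n_planes` planes
#' at `plane_time` seconds each (25 planes x 10 ms gives 4 Hz).
#'
#' @param n_planes planes per volume.
#' @param plane_time exposure/step time per plane, seconds.
#' @return Volume rate in Hz.
#' @export
volume_rate <- function(n_planes = 25L, plane_time = 0.010) {
  stopifnot_scalar(n_planes, "n_planes", positive = TRUE)
  stopifnot_scalar(plane_time, "plane_time", positive = TRUE)
  1 / (n_planes * plane_time)
}
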
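#' Multi-fish fluorescence dataset
#'
#' Pooled per-ROI calcium traces across fish, with the stimulus train and
#' (for synthetic data) ground-truth cluster labels.
#'
#' @param traces numeric matrix, ROIs x frames (all fish pooled).
#' @param roi data frame with columns `fish_id`, `roi_id` and optionally
#'   `label` (ground truth; `"none"` for non-responders).
#' @param frame_rate imaging rate, Hz.
#' @param train the [stimulus_train()] presented.
#' @return A `fluorescence_dataset` list.
#' @export
fluorescence_dataset <- function(traces, roi, frame_rate, train) {
  if (nrow(traces) != nrow(roi))
    stop("one roi row per trace required", call. = FALSE)
  if (length(unique(roi$fish_id)) < 1L) stop(">= 1 fish required", call. = FALSE)
  structure(list(traces = traces, roi = roi, frame_rate = frame_rate,
                 train = train),
            class = "fluorescence_dataset")
}

#' @export
print.fluorescence_dataset <- function(x, ...) {
  cat(sprintf("Fluorescence dataset: %d ROIs from %d fish, %d frames @ %g Hz\n",
              nrow(x$traces), length(unique(x$roi$fish_id)), ncol(x$traces),
              x$frame_rate))
  invisible(x)
}

#' Cluster response profile
#'
#' Ground-truth response profile planted in synthetic data: an amplitude per
#' stimulus configuration (z-units at the GCaMP-kernel peak) and the
#' fraction of ROIs per fish drawn from this profile.
#'
#' @param name profile label.
#' @param amplitudes named numeric vector, names `"target@frequency"`
#'   (missing configurations respond with 0).
#' @param fraction fraction of ROIs with this profile.
#' @return A `cluster_profile` list.
#' @export
cluster_profile <- function(name, amplitudes, fraction) {
  if (fraction < 0 || fraction > 1) stop("fraction must be in [0, 1]",
                                         call. = FALSE)
  structure(list(name = name, amplitudes = amplitudes, fraction = fraction),
            class = "cluster_profile")
}

#' Default planted response profiles
#'
#' Two profiles mirroring the two tone-responsive functional classes seen in
#' BOA experiments, plus (implicitly) non-responders:
#' \describe{
#'   \item{broad_superadditive}{responds to utricle, saccule and speaker
#'     stimulation at every frequency, with the dual-trap ("both") response
#'     three times the single-organ response -- i.e. super-additive.}
#'   \item{saccule_low_freq}{saccule-specific, responding at 1-100 Hz (not
#'     1000 Hz) and to the speaker tone, with additive "both" responses.}
#' }
#' The amplitude `scale` of each profile is calibrated so that, with
#' `noise_sd = 1`, planted responders of either class sit near r^2 = 0.5
#' under the default stimulus train (signal sd ~ 1 z-unit).
#'
#' @param scale per-profile amplitude scales in z-units (recycled; defaults
#'   1.0 and 2.27, each putting the profile's signal sd at ~1 under the
#'   default train).
#' @param fractions member fractions for the two profiles (default 5% each;
#'   the rest are non-responders).
#' @return List of [cluster_profile()]s.
#' @export
default_cluster_profiles <- function(scale = c(1.0, 2.27),
                                     fractions = c(0.05, 0.05)) {
  scale <- rep_len(scale, 2L)
  freqs <- c(1, 10, 100, 1000)
  a1 <- c(
    stats::setNames(rep(scale[1], 4), config_key("utricle", freqs)),
    stats::setNames(rep(scale[1], 4), config_key("saccule", freqs)),
    stats::setNames(rep(3 * scale[1], 4), config_key("both", freqs)),
    stats::setNames(2 * scale[1], config_key("speaker", 100))
  )
  lf <- c(1, 10, 100)
  a2 <- c(
    stats::setNames(rep(scale[2], 3), config_key("saccule", lf)),
    stats::setNames(rep(scale[2], 3), config_key("both", lf)),
    stats::setNames(scale[2], config_key("speaker", 100))
  )
  list(cluster_profile("broad_superadditive", a1, fractions[1]),
       cluster_profile("saccule_low_freq", a2, fractions[2]))
}

#' Synthetic calcium dataset specification
#'
#' @param n_fish number of fish (default 6).
#' @param n_rois_per_fish ROIs per fish (default 2000).
#' @param frame_rate volumetric imaging rate, Hz (default 4).
#' @param cluster_profiles list of [cluster_profile()]s; member fractions
#'   plus the non-responder remainder must sum to 1.
#' @param noise_sd additive Gaussian noise sd, z-units (default 1).
#' @param baseline constant baseline level (default 0).
#' @param kernel_params `list(tau_rise, tau_decay)` for the GCaMP kernel.
#' @param seed RNG seed (explicit, never global).
#' @return A `calcium_spec` list.
#' @export
calcium_spec <- function(n_fish = 6L, n_rois_per_fish = 2000L, frame_rate = 4,
                         cluster_profiles = default_cluster_profiles(),
                         noise_sd = 1, baseline = 0,
                         kernel_params = list(tau_rise = 0.2, tau_decay = 3.5),
                         seed = 1L) {
  stopifnot_scalar(frame_rate, "frame_rate", positive = TRUE)
  stopifnot_scalar(noise_sd, "noise_sd", nonneg = TRUE)
  if (kernel_params$tau_rise <= 0 || kernel_params$tau_decay <= 0)
    stop("kernel taus must be > 0", call. = FALSE)
  fr <- vapply(cluster_profiles, `[[`, numeric(1), "fraction")
  if (sum(fr) > 1 + 1e-9)
    stop("cluster member fractions exceed 1", call. = FALSE)
  structure(list(n_fish = as.integer(n_fish),
                 n_rois_per_fish = as.integer(n_rois_per_fish),
                 frame_rate = frame_rate, cluster_profiles = cluster_profiles,
                 noise_sd = noise_sd, baseline = baseline,
                 kernel_params = kernel_params, seed = as.integer(seed)),
            class = "calcium_spec")
}

#' Simulate a multi-fish calcium dataset with planted cluster structure
#'
#' Each responsive ROI's trace is baseline + sum over epochs of the
#' profile's configuration amplitude times the GCaMP kernel at the epoch
#' onset, plus Gaussian noise; non-responders are baseline + noise.  Labels
#' are drawn per fish from the profile fractions, and the ground-truth label
#' of every ROI is stored.  The result is reproducible from `spec$seed`.
#'
#' @param spec a [calcium_spec()].
#' @param train a [stimulus_train()].
#' @return A [fluorescence_dataset()] with a `label` column in `$roi`.
#' @export
simulate_calcium_dataset <- function(spec, train) {
  if (!inherits(spec, "calcium_spec")) spec <- do.call(calcium_spec, spec)
  R <- build_regressors(train, frame_rate = spec$frame_rate,
                        kernel_params = spec$kernel_params)
  # un-normalized per-configuration responses: kernel peak = 1 per impulse
  Rk <- unnormalized_regressors(train, spec$frame_rate, spec$kernel_params)
  n_frames <- nrow(Rk)
  profiles <- spec$cluster_profiles
  pnames <- vapply(profiles, `[[`, character(1), "name")
  fractions <- vapply(profiles, `[[`, numeric(1), "fraction")
  signals <- vapply(profiles, function(p) {
    amp <- stats::setNames(rep(0, ncol(Rk)), colnames(Rk))
    common <- intersect(names(p$amplitudes), names(amp))
    amp[common] <- p$amplitudes[common]
    as.numeric(Rk %*% amp)
  }, numeric(n_frames))
  with_seed(spec$seed, {
    labels <- character(0)
    for (f in seq_len(spec$n_fish)) {
      lab <- sample(c(pnames, "none"), spec$n_rois_per_fish, replace = TRUE,
                    prob = c(fractions, 1 - sum(fractions)))
      labels <- c(labels, lab)
    }
    n <- length(labels)
    traces <- matrix(stats::rnorm(n * n_frames, 0, spec$noise_sd),
                     nrow = n, ncol = n_frames)
    traces <- traces + spec$baseline
    for (j in seq_along(profiles)) {
      sel <- labels == pnames[j]
      if (any(sel))
        traces[sel, ] <- traces[sel, ] + rep(signals[, j], each = sum(sel))
    }
  })
  roi <- data.frame(
    fish_id = rep(seq_len(spec$n_fish), each = spec$n_rois_per_fish),
    roi_id = seq_along(labels),
    label = labels
  )
  fluorescence_dataset(traces, roi, spec$frame_rate, train)
}

# Regressor-like matrix without per-column peak normalization: each epoch
# contributes the peak-1 kernel, so a profile amplitude is the per-trial
# peak response in trace units.
unnormalized_regressors <- function(train, frame_rate, kernel_params) {
  kernel <- gcamp_kernel(kernel_params$tau_rise, kernel_params$tau_decay,
                         frame_rate)
  n_frames <- ceiling(attr(train, "total_duration") * frame_rate)
  cfg <- train_configurations(train)
  R <- matrix(0, nrow = n_frames, ncol = nrow(cfg))
  colnames(R) <- config_key(cfg$target, cfg$frequency)
  key <- config_key(train$target, train$frequency)
  for (i in seq_len(nrow(train))) {
    col <- match(key[i], colnames(R))
    at <- floor(train$onset[i] * frame_rate) + 1L
    span <- at:min(at + length(kernel) - 1L, n_frames)
    R[span, col] <- R[span, col] + kernel[seq_along(span)]
  }
  R
}

#' Read / write fluorescence datasets as CSV
#'
#' Columns `fish_id`, `roi_id`, `label`, then one column per frame
#' (`t0` ... `tN`).
#'
#' @param ds a [fluorescence_dataset()].
#' @param path file path.
#' @param train used on read (the CSV stores traces only).
#' @param frame_rate used on read.
#' @export
write_fluorescence_dataset <- function(ds, path) {
  tr <- as.data.frame(ds$traces)
  names(tr) <- paste0("t", seq_len(ncol(tr)) - 1L)
  df <- cbind(ds$roi[, intersect(c("fish_id", "roi_id", "label"),
                                 names(ds$roi)), drop = FALSE], tr)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_fluorescence_dataset
#' @export
read_fluorescence_dataset <- function(path, train, frame_rate = 4) {
  df <- read.csv(path)
  meta <- intersect(c("fish_id", "roi_id", "label"), names(df))
  traces <- as.matrix(df[, setdiff(names(df), meta), drop = FALSE])
  dimnames(traces) <- NULL
  fluorescence_dataset(traces, df[, meta, drop = FALSE], frame_rate, train)
}
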
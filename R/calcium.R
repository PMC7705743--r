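#' GCaMP response kernel
#'
#' Difference-of-exponentials impulse response of the calcium indicator,
#' h(t) = exp(-t/tau_decay) - exp(-t/tau_rise), sampled at `frame_rate`,
#' peak-normalized to 1 and truncated once it falls below 1e-3 of the peak.
#' Defaults (rise 0.2 s, decay 3.5 s) describe nuclear GCaMP6s at slow
#' volumetric rates.
#'
#' @param tau_rise rise time constant, s (0 < tau_rise < tau_decay).
#' @param tau_decay decay time constant, s.
#' @param frame_rate sampling rate, Hz.
#' @return Numeric kernel vector starting at t = 0 (where h = 0).
#' @export
gcamp_kernel <- function(tau_rise = 0.2, tau_decay = 3.5, frame_rate = 4) {
  stopifnot_scalar(tau_rise, "tau_rise", positive = TRUE)
  stopifnot_scalar(tau_decay, "tau_decay", positive = TRUE)
  if (tau_rise >= tau_decay)
    stop("need 0 < tau_rise < tau_decay", call. = FALSE)
  stopifnot_scalar(frame_rate, "frame_rate", positive = TRUE)
  # support: decay to 1e-3 of peak takes < tau_decay * log(2000)
  t <- seq(0, tau_decay * log(2e3), by = 1 / frame_rate)
  h <- exp(-t / tau_decay) - exp(-t / tau_rise)
  h <- h / max(h)
  last <- max(which(h >= 1e-3 | t <= tau_rise))
  h[seq_len(last)]
}

#' Build the stimulus regressor matrix
#'
#' One column per stimulus configuration (target x frequency, including the
#' speaker tone): a unit impulse at each epoch onset convolved with the
#' GCaMP kernel, with linear superposition of overlapping responses.  Each
#' column is peak-normalized to 1.
#'
#' @param train a non-empty [stimulus_train()].
#' @param frame_rate imaging rate, Hz (default 4).
#' @param kernel indicator kernel vector (default
#'   `gcamp_kernel(frame_rate = frame_rate)`).
#' @param kernel_params alternatively, `list(tau_rise, tau_decay)` used to
#'   build the kernel.
#' @return A `regressor_matrix`: frames x configurations numeric matrix with
#'   column names `"target@frequency"` and attributes `frame_rate`,
#'   `configurations`.
#' @export
build_regressors <- function(train, frame_rate = 4, kernel = NULL,
                             kernel_params = NULL) {
  if (nrow(train) == 0L) stop("empty stimulus train", call. = FALSE)
  if (is.null(kernel)) {
    kp <- kernel_params %||% list(tau_rise = 0.2, tau_decay = 3.5)
    kernel <- gcamp_kernel(kp$tau_rise, kp$tau_decay, frame_rate)
  }
  n_frames <- ceiling(attr(train, "total_duration") * frame_rate)
  cfg <- train_configurations(train)
  R <- matrix(0, nrow = n_frames, ncol = nrow(cfg))
  colnames(R) <- config_key(cfg$target, cfg$frequency)
  key <- config_key(train$target, train$frequency)
  kl <- length(kernel)
  for (i in seq_len(nrow(train))) {
    col <- match(key[i], colnames(R))
    at <- floor(train$onset[i] * frame_rate) + 1L
    span <- at:min(at + kl - 1L, n_frames)
    R[span, col] <- R[span, col] + kernel[seq_along(span)]
  }
  peaks <- apply(R, 2, max)
  if (any(peaks == 0))
    stop("all-zero regressor column(s): ",
         paste(colnames(R)[peaks == 0], collapse = ", "), call. = FALSE)
  R <- sweep(R, 2, peaks, `/`)
  structure(R, frame_rate = frame_rate, configurations = cfg,
            kernel = kernel, class = c("regressor_matrix", "matrix", "array"))
}

#' z-score fluorescence traces
#'
#' Scales each ROI trace to mean 0, sd 1.  Zero-variance traces cannot be
#' z-scored; they are excluded with a message and recorded in the
#' `excluded` attribute of the result.
#'
#' @param ds a [fluorescence_dataset()] or a traces matrix (ROIs x frames).
#' @return Same type as the input, z-scored.
#' @export
zscore_traces <- function(ds) {
  is_ds <- inherits(ds, "fluorescence_dataset")
  traces <- if (is_ds) ds$traces else ds
  mu <- rowMeans(traces)
  s <- sqrt(rowSums((traces - mu)^2) / (ncol(traces) - 1L))
  bad <- s == 0 | !is.finite(s)
  if (any(bad)) {
    message(sum(bad), " zero-variance trace(s) excluded from z-scoring")
    traces <- traces[!bad, , drop = FALSE]
    mu <- mu[!bad]; s <- s[!bad]
  }
  z <- (traces - mu) / s
  if (is_ds) {
    excluded <- ds$roi[bad, , drop = FALSE]
    ds$traces <- z
    ds$roi <- ds$roi[!bad, , drop = FALSE]
    attr(ds, "excluded") <- excluded
    ds
  } else {
    attr(z, "excluded") <- which(bad)
    z
  }
}

#' Regress ROI traces on the stimulus regressors
#'
#' Ordinary least squares of each trace on all regressor columns plus an
#' intercept (joint regression); r^2 is the coefficient of determination of
#' the full model, 1 - RSS/TSS.  Under the null (noise traces) the expected
#' r^2 is p/(n-1) for p regressors and n frames.
#'
#' @param ds a [fluorescence_dataset()] or traces matrix (ROIs x frames).
#' @param R a [build_regressors()] matrix with `nrow(R)` equal to the trace
#'   length.
#' @return List with `r2` (per-ROI), `coefficients` (ROIs x (1 + p),
#'   intercept first), and `roi` (the ROI table when a dataset was given).
#' @export
regress_rois <- function(ds, R) {
  traces <- if (inherits(ds, "fluorescence_dataset")) ds$traces else ds
  if (ncol(traces) != nrow(R))
    stop("trace length does not match regressor rows", call. = FALSE)
  X <- cbind(`(Intercept)` = 1, R)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("rank-deficient regressor matrix; collinear column(s): ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  Y <- t(traces)                         # frames x ROIs
  Q <- qr.Q(qrX)
  qty <- crossprod(Q, Y)                 # p+1 x ROIs
  coefs <- backsolve(qr.R(qrX), qty)
  rss <- colSums(Y^2) - colSums(qty^2)
  tss <- colSums(Y^2) - nrow(Y) * colMeans(Y)^2
  r2 <- ifelse(tss > 0, pmax(0, 1 - rss / tss), NA_real_)
  coefs <- t(coefs)
  colnames(coefs) <- colnames(X)
  list(r2 = as.numeric(r2), coefficients = coefs,
       roi = if (inherits(ds, "fluorescence_dataset")) ds$roi else NULL)
}

#' Selection thresholds for the calcium pipeline
#'
#' The filtering constants of the whole-brain analysis: the conservative
#' r^2 >= 0.2 pre-selection, k-means into 120 clusters (cityblock distance,
#' five replicates), the "1 SD above baseline" response criterion, the
#' r^2 > 0.4 within-cluster refinement, and the cross-fish representation
#' cap (no single fish may contribute 90% or more of a cluster).
#'
#' @param r2_select inclusive pre-selection threshold (default 0.2).
#' @param r2_refine strict within-cluster threshold (default 0.4).
#' @param sd_above_baseline response criterion in baseline SDs (default 1).
#' @param n_clusters k for k-means (default 120).
#' @param kmeans_replicates random restarts (default 5).
#' @param max_single_fish_fraction dominance cap (default 0.9).
#' @param tone_correlation minimum centroid correlation with the tone
#'   regressor for the "GCaMP6s profile" criterion (default 0.5).
#' @param fish_criterion `"dominance_cap"` (no fish holds >=
#'   `max_single_fish_fraction` of a cluster) or `"representation_floor"`
#'   (every fish holds < that fraction ... i.e. each fish must be
#'   represented); the former is the default reading.
#' @return A `selection_thresholds` list.
#' @export
selection_thresholds <- function(r2_select = 0.2, r2_refine = 0.4,
                                 sd_above_baseline = 1, n_clusters = 120L,
                                 kmeans_replicates = 5L,
                                 max_single_fish_fraction = 0.9,
                                 tone_correlation = 0.5,
                                 fish_criterion = c("dominance_cap",
                                                    "representation_floor")) {
  if (r2_select <= 0 || r2_select >= 1 || r2_refine <= 0 || r2_refine >= 1)
    stop("r2 thresholds must lie in (0, 1)", call. = FALSE)
  if (n_clusters < 2) stop("n_clusters must be >= 2", call. = FALSE)
  structure(list(r2_select = r2_select, r2_refine = r2_refine,
                 sd_above_baseline = sd_above_baseline,
                 n_clusters = as.integer(n_clusters),
                 kmeans_replicates = as.integer(kmeans_replicates),
                 max_single_fish_fraction = max_single_fish_fraction,
                 tone_correlation = tone_correlation,
                 fish_criterion = match.arg(fish_criterion)),
            class = "selection_thresholds")
}

#' Select stimulus-responsive ROIs by r-squared
#'
#' Keeps ROIs with r^2 >= `thresholds$r2_select` (boundary inclusive).
#'
#' @param r2 per-ROI r^2 values from [regress_rois()].
#' @param thresholds a [selection_thresholds()].
#' @return Logical mask over ROIs.
#' @export
select_responsive <- function(r2, thresholds = selection_thresholds()) {
  mask <- r2 >= thresholds$r2_select
  mask[is.na(mask)] <- FALSE
  if (!any(mask)) warning("no ROI passed the r2 selection threshold")
  mask
}
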
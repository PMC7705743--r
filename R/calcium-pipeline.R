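# Cluster selection, refinement, filters, peak responses and the
# super-additivity comparison -- the back half of the whole-brain pipeline.

# Pooled baseline frame indices of a train at a given frame rate: the
# pre-stimulus rest plus all frames at least `gap` seconds after an epoch
# end and before the next onset.
baseline_frames <- function(train, frame_rate, n_frames, gap = 3) {
  t <- (seq_len(n_frames) - 1L) / frame_rate
  if (nrow(train) == 0L) return(seq_len(n_frames))
  keep <- t < min(train$onset)
  ends <- train$onset + train$duration
  next_onset <- c(train$onset[-1L], Inf)
  for (i in seq_len(nrow(train)))
    keep <- keep | (t >= ends[i] + gap & t < next_onset[i])
  which(keep)
}

# Union of response-window frames of the tone epochs.
tone_windows <- function(train, frame_rate, n_frames, tone_targets, lag = 2) {
  tone <- train[train$target %in% tone_targets, , drop = FALSE]
  idx <- integer(0)
  for (i in seq_len(nrow(tone))) {
    i0 <- floor(tone$onset[i] * frame_rate) + 1L
    i1 <- min(ceiling((tone$onset[i] + tone$duration[i] + lag) * frame_rate) + 1L,
              n_frames)
    idx <- c(idx, i0:i1)
  }
  sort(unique(idx))
}

# Peak of `x` within [onset, onset + duration + lag] for one epoch.
epoch_peak <- function(x, frame_rate, onset, duration, lag = 2) {
  n <- length(x)
  i0 <- floor(onset * frame_rate) + 1L
  i1 <- ceiling((onset + duration + lag) * frame_rate) + 1L
  if (i1 > n) {
    warning("response window extends past trace end; truncated")
    i1 <- n
  }
  max(x[i0:min(i1, n)])
}

#' Select tone-responsive clusters
#'
#' A cluster is tone-responsive when its centroid's peak inside every tone
#' (speaker) epoch -- extended by `lag` seconds for indicator decay --
#' exceeds baseline mean + `sd_above_baseline` x baseline SD, with the
#' baseline pooled from the pre-stimulus rest and all frames >= `gap`
#' seconds after any epoch end and before the next onset.
#'
#' @param centroids k x frames matrix (e.g. `$centers` of
#'   [cluster_traces()]).
#' @param train the [stimulus_train()].
#' @param frame_rate imaging rate, Hz.
#' @param R optional [build_regressors()] matrix; when given, each
#'   centroid's correlation with every regressor is reported.
#' @param thresholds a [selection_thresholds()].
#' @param tone_targets epoch targets that count as tones (default
#'   `"speaker"`).
#' @param lag response-window extension after stimulus offset, s (default 2).
#' @param gap baseline guard after epoch end, s (default 3).
#' @return List with `selected` (cluster ids) and `report` (per-cluster
#'   baseline stats, minimum tone-epoch peak, pass flag, and regressor
#'   correlations when `R` is given).
#' @export
select_clusters <- function(centroids, train, frame_rate, R = NULL,
                            thresholds = selection_thresholds(),
                            tone_targets = "speaker", lag = 2, gap = 3) {
  tone <- train[train$target %in% tone_targets, , drop = FALSE]
  if (nrow(tone) == 0L)
    stop("train contains no tone epochs (targets: ",
         paste(tone_targets, collapse = ", "), ")", call. = FALSE)
  bl <- baseline_frames(train, frame_rate, ncol(centroids), gap = gap)
  if (length(bl) == 0L) stop("empty baseline window", call. = FALSE)
  k <- nrow(centroids)
  report <- data.frame(cluster = seq_len(k),
                       baseline_mean = NA_real_, baseline_sd = NA_real_,
                       min_tone_peak = NA_real_, tone_responsive = FALSE)
  for (j in seq_len(k)) {
    x <- centroids[j, ]
    bm <- mean(x[bl]); bs <- stats::sd(x[bl])
    peaks <- vapply(seq_len(nrow(tone)), function(i)
      epoch_peak(x, frame_rate, tone$onset[i], tone$duration[i], lag),
      numeric(1))
    report$baseline_mean[j] <- bm
    report$baseline_sd[j] <- bs
    report$min_tone_peak[j] <- min(peaks)
    report$tone_responsive[j] <-
      all(peaks > bm + thresholds$sd_above_baseline * bs)
  }
  if (!is.null(R)) {
    cors <- t(apply(centroids, 1, function(x)
      suppressWarnings(cor(x, R))))
    colnames(cors) <- paste0("cor_", colnames(R))
    report <- cbind(report, as.data.frame(cors))
  }
  selected <- report$cluster[report$tone_responsive]
  if (length(selected) == 0L)
    message("no cluster passed the tone-responsiveness criterion")
  list(selected = selected, report = report)
}

#' Refine cluster membership by per-ROI regression
#'
#' Within selected clusters, each member trace is regressed on the
#' regressors and only ROIs with r^2 strictly above
#' `thresholds$r2_refine` are retained ("above 0.4" is read as a strict
#' inequality).
#'
#' @param traces member traces, ROIs x frames.
#' @param R a [build_regressors()] matrix.
#' @param thresholds a [selection_thresholds()].
#' @return Logical mask over the member ROIs, with the per-ROI r^2 as
#'   attribute `r2`.
#' @export
refine_rois <- function(traces, R, thresholds = selection_thresholds()) {
  if (nrow(traces) == 0L) stop("no member traces", call. = FALSE)
  r2 <- regress_rois(traces, R)$r2
  mask <- r2 > thresholds$r2_refine
  mask[is.na(mask)] <- FALSE
  attr(mask, "r2") <- r2
  mask
}

#' Apply the final cluster selection criteria
#'
#' Drops clusters failing any of: (1) responsivity to each tone stimulus as
#' a GCaMP6s profile -- the centroid, restricted to the tone-epoch response
#' windows (`[onset, onset + duration + lag]`), must correlate with the
#' tone regressor over those same windows at
#' least `thresholds$tone_correlation` (a global correlation would be
#' diluted towards zero by the cluster's responses to the other
#' configurations, so the shape criterion is evaluated where the tone
#' response lives); (2) a response at least
#' `sd_above_baseline` SD above baseline in every tone epoch; (3) the
#' cross-fish criterion -- under the default `"dominance_cap"` reading, no
#' single fish contributes `max_single_fish_fraction` (90%) or more of the
#' cluster's ROIs; under `"representation_floor"`, every fish must
#' contribute at least one ROI and none may hold >= the cap.
#'
#' @param centroids k x frames matrix.
#' @param membership data frame with columns `cluster` and `fish_id`, one
#'   row per retained ROI.
#' @param train the [stimulus_train()].
#' @param frame_rate imaging rate, Hz.
#' @param R a [build_regressors()] matrix.
#' @param thresholds a [selection_thresholds()].
#' @param candidates cluster ids to consider (default all in `membership`).
#' @param n_fish total number of fish in the experiment (default: the
#'   number of distinct fish among the retained ROIs; pass explicitly when
#'   some fish contribute no retained ROI, as the representation-floor
#'   variant depends on it).
#' @param tone_targets,lag,gap see [select_clusters()].
#' @return List with `clusters` (ids passing all criteria) and a
#'   per-criterion `report`.
#' @export
apply_cluster_filters <- function(centroids, membership, train, frame_rate,
                                  R, thresholds = selection_thresholds(),
                                  candidates = NULL, n_fish = NULL,
                                  tone_targets = "speaker",
                                  lag = 2, gap = 3) {
  candidates <- candidates %||% sort(unique(membership$cluster))
  sel <- select_clusters(centroids, train, frame_rate, R = R,
                         thresholds = thresholds,
                         tone_targets = tone_targets, lag = lag, gap = gap)
  tone_cols <- colnames(R)[attr(R, "configurations")$target %in% tone_targets]
  n_fish_total <- n_fish %||% length(unique(membership$fish_id))
  report <- data.frame(cluster = candidates, profile_ok = FALSE,
                       sd_ok = FALSE, fish_ok = FALSE, n_rois = 0L,
                       max_fish_fraction = NA_real_)
  tone_win <- tone_windows(train, frame_rate, ncol(centroids),
                           tone_targets, lag)
  for (i in seq_along(candidates)) {
    j <- candidates[i]
    cors <- vapply(tone_cols, function(cl)
      suppressWarnings(cor(centroids[j, tone_win], R[tone_win, cl])),
      numeric(1))
    report$profile_ok[i] <- !anyNA(cors) &&
      all(cors >= thresholds$tone_correlation)
    report$sd_ok[i] <- sel$report$tone_responsive[j]
    members <- membership[membership$cluster == j, , drop = FALSE]
    report$n_rois[i] <- nrow(members)
    if (nrow(members) > 0L) {
      frac <- max(table(members$fish_id)) / nrow(members)
      report$max_fish_fraction[i] <- frac
      report$fish_ok[i] <- frac < thresholds$max_single_fish_fraction
      if (thresholds$fish_criterion == "representation_floor")
        report$fish_ok[i] <- report$fish_ok[i] &&
          length(unique(members$fish_id)) == n_fish_total
    }
  }
  keep <- report$profile_ok & report$sd_ok & report$fish_ok &
    report$n_rois > 0L
  list(clusters = report$cluster[keep], report = report)
}

#' Per-epoch, per-trial peak responses of a cluster trace
#'
#' Peak of the (z-scored) cluster mean trace within
#' `[onset, onset + duration + lag]` for every epoch of the train; the
#' default `lag` of 2 s captures the indicator decay at 4 Hz sampling.
#'
#' @param trace numeric cluster mean trace.
#' @param train the [stimulus_train()].
#' @param frame_rate imaging rate, Hz.
#' @param lag window extension after stimulus offset, s (default 2).
#' @return Data frame with columns `target`, `frequency`, `trial`, `peak`.
#' @export
peak_responses <- function(trace, train, frame_rate, lag = 2) {
  if (nrow(train) == 0L) stop("empty train", call. = FALSE)
  data.frame(
    target = train$target, frequency = train$frequency, trial = train$trial,
    peak = vapply(seq_len(nrow(train)), function(i)
      epoch_peak(trace, frame_rate, train$onset[i], train$duration[i], lag),
      numeric(1))
  )
}

#' Super-additivity index
#'
#' mean trial peak for dual-organ ("both") stimulation minus the sum of the
#' single-organ (utricle + saccule) mean trial peaks, at one frequency.  A
#' positive index means the combined stimulation drives the response
#' super-additively.
#'
#' @param peaks a [peak_responses()] table.
#' @param frequency frequency at which to compare, Hz.
#' @return The index (same units as the peaks).
#' @export
superadditivity_index <- function(peaks, frequency) {
  sub <- peaks[peaks$frequency == frequency, , drop = FALSE]
  m <- function(tgt) {
    v <- sub$peak[sub$target == tgt]
    if (length(v) == 0L)
      stop("missing configuration: ", tgt, "@", frequency, call. = FALSE)
    mean(v)
  }
  m("both") - (m("utricle") + m("saccule"))
}

#' Run the whole-brain calcium analysis pipeline
#'
#' The full chain: z-score pooled traces, joint OLS against the stimulus
#' regressors, keep ROIs with r^2 >= 0.2, cityblock k-means into 120
#' clusters (5 replicates), select tone-responsive clusters (1 SD above
#' baseline), refine members at r^2 > 0.4, apply the final cluster
#' criteria, and tabulate per-trial peak responses and super-additivity
#' indices for the retained clusters.
#'
#' @param ds a [fluorescence_dataset()].
#' @param thresholds a [selection_thresholds()].
#' @param kernel_params GCaMP kernel parameters for the regressors.
#' @param tone_targets,lag,gap see [select_clusters()].
#' @param seed RNG seed for the k-means initializations.
#' @return A `calcium_analysis` object: list with `r2`, `selected_mask`,
#'   `kmeans`, `cluster_selection`, `refined` (per-ROI retention),
#'   `filters`, `final_clusters`, `membership` (fish_id/roi_id/label/
#'   cluster for retained ROIs), `peaks`, `superadditivity`, `thresholds`.
#' @export
analyze_calcium <- function(ds, thresholds = selection_thresholds(),
                            kernel_params = list(tau_rise = 0.2,
                                                 tau_decay = 3.5),
                            tone_targets = "speaker", lag = 2, gap = 3,
                            seed = 1L) {
  R <- build_regressors(ds$train, frame_rate = ds$frame_rate,
                        kernel_params = kernel_params)
  ds <- zscore_traces(ds)
  reg <- regress_rois(ds, R)
  mask <- select_responsive(reg$r2, thresholds)
  if (sum(mask) < thresholds$n_clusters)
    stop(sprintf(paste0("only %d ROIs pass r2 selection but n_clusters = %d; ",
                        "reduce n_clusters"),
                 sum(mask), thresholds$n_clusters), call. = FALSE)
  sel_traces <- ds$traces[mask, , drop = FALSE]
  sel_roi <- ds$roi[mask, , drop = FALSE]
  km <- cluster_traces(sel_traces, k = thresholds$n_clusters,
                       replicates = thresholds$kmeans_replicates, seed = seed)
  cs <- select_clusters(km$centers, ds$train, ds$frame_rate, R = R,
                        thresholds = thresholds, tone_targets = tone_targets,
                        lag = lag, gap = gap)
  # refine members of the tone-responsive clusters
  refined <- logical(nrow(sel_traces))
  r2_refine <- rep(NA_real_, nrow(sel_traces))
  for (j in cs$selected) {
    members <- which(km$labels == j)
    if (!length(members)) next
    rm_ <- refine_rois(sel_traces[members, , drop = FALSE], R, thresholds)
    refined[members] <- rm_
    r2_refine[members] <- attr(rm_, "r2")
  }
  membership <- cbind(sel_roi, cluster = km$labels)[refined, , drop = FALSE]
  filt <- apply_cluster_filters(km$centers, membership, ds$train,
                                ds$frame_rate, R, thresholds,
                                candidates = intersect(cs$selected,
                                                       unique(membership$cluster)),
                                n_fish = length(unique(ds$roi$fish_id)),
                                tone_targets = tone_targets, lag = lag,
                                gap = gap)
  final <- filt$clusters
  membership <- membership[membership$cluster %in% final, , drop = FALSE]
  peaks <- NULL
  sa <- NULL
  for (j in final) {
    rows <- which(km$labels == j & refined)
    mt <- colMeans(sel_traces[rows, , drop = FALSE])
    pk <- peak_responses(mt, ds$train, ds$frame_rate, lag = lag)
    pk <- cbind(cluster = j, pk)
    peaks <- rbind(peaks, pk)
    freqs <- intersect(unique(pk$frequency[pk$target == "both"]),
                       intersect(unique(pk$frequency[pk$target == "utricle"]),
                                 unique(pk$frequency[pk$target == "saccule"])))
    for (fq in freqs)
      sa <- rbind(sa, data.frame(cluster = j, frequency = fq,
                                 index = superadditivity_index(pk, fq)))
  }
  structure(list(r2 = reg$r2, roi = ds$roi, selected_mask = mask,
                 kmeans = km, cluster_selection = cs, refined = refined,
                 r2_refine = r2_refine, filters = filt,
                 final_clusters = final, membership = membership,
                 peaks = peaks, superadditivity = sa,
                 thresholds = thresholds, train = ds$train,
                 frame_rate = ds$frame_rate),
            class = "calcium_analysis")
}

#' @export
print.calcium_analysis <- function(x, ...) {
  cat("Whole-brain calcium analysis\n")
  cat(sprintf("  %d ROIs, %d pass r2 >= %g\n", length(x$r2),
              sum(x$selected_mask), x$thresholds$r2_select))
  cat(sprintf("  %d/%d clusters tone-responsive; %d retained after filters\n",
              length(x$cluster_selection$selected), x$kmeans$k,
              length(x$final_clusters)))
  cat(sprintf("  %d ROIs in final clusters\n", nrow(x$membership)))
  if (!is.null(x$superadditivity)) {
    cat("  super-additivity indices:\n")
    print(x$superadditivity, row.names = FALSE)
  }
  invisible(x)
}

#' @export
summary.calcium_analysis <- function(object, ...) {
  print(object)
  invisible(object)
}
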
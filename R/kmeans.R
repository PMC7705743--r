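#' Cluster traces by k-means with the cityblock distance
#'
#' Lloyd-type k-means under the L1 (cityblock) distance with component-wise
#' median centroid updates, run from `replicates` random initializations
#' (centroids seeded from distinct observations); the replicate with the
#' lowest total within-cluster L1 cost is returned.  Empty clusters are
#' re-seeded from the point farthest from its centroid.  Deterministic
#' given `seed`.
#'
#' @param traces numeric matrix, observations x features (ROIs x frames).
#' @param k number of clusters (default 120).
#' @param replicates random restarts (default 5).
#' @param max_iter Lloyd iterations per replicate (default 100).
#' @param seed RNG seed for the initializations.
#' @return List of class `kmeans_l1` with `labels`, `centers` (k x
#'   features), `cost`, `cost_history` (per-iteration cost of the winning
#'   replicate), `replicate_costs`.
#' @export
cluster_traces <- function(traces, k = 120L, replicates = 5L, max_iter = 100L,
                           seed = NULL) {
  traces <- as.matrix(traces)
  n <- nrow(traces)
  if (n < k)
    stop(sprintf(paste0("fewer observations (%d) than clusters (%d); ",
                        "reduce n_clusters"), n, k), call. = FALSE)
  Xt <- t(traces)                        # feature-contiguous layout
  best <- NULL
  costs <- numeric(replicates)
  with_seed(seed, {
    for (r in seq_len(replicates)) {
      init <- sample.int(n, k)
      fit <- .km_cityblock(Xt, init, max_iter)
      costs[r] <- fit$cost
      if (is.null(best) || fit$cost < best$cost) best <- fit
    }
  })
  structure(list(labels = best$labels, centers = best$centers,
                 cost = best$cost, cost_history = best$cost_history,
                 iterations = best$iterations, replicate_costs = costs,
                 k = as.integer(k)),
            class = "kmeans_l1")
}

#' @export
print.kmeans_l1 <- function(x, ...) {
  cat(sprintf("Cityblock k-means: k = %d, cost = %.4g (best of %d replicates)\n",
              x$k, x$cost, length(x$replicate_costs)))
  invisible(x)
}
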
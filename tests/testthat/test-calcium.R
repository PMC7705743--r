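test_that("GCaMP kernel is normalized, causal and peaks where calculus says", {
  h <- gcamp_kernel(0.2, 3.5, frame_rate = 1000)
  expect_equal(max(h), 1)
  expect_equal(h[1], 0)
  expect_true(all(h >= 0))
  # analytic time-to-peak of exp(-t/td) - exp(-t/tr)
  tp <- log(3.5 / 0.2) / (1 / 0.2 - 1 / 3.5)
  expect_equal((which.max(h) - 1) / 1000, tp, tolerance = 1.5e-3)
  # tail truncation at 1e-3 of peak
  expect_gte(h[length(h)], 1e-3)
  expect_error(gcamp_kernel(3.5, 0.2), "tau_rise < tau_decay")
  expect_error(gcamp_kernel(0, 1), "> 0")
})

test_that("regressors place one kernel per onset and superpose overlaps", {
  fs <- 4
  kern <- gcamp_kernel(0.2, 3.5, fs)
  tr1 <- single_epoch_train(target = "both", frequency = 10, onset = 3)
  R1 <- build_regressors(tr1, fs)
  expect_equal(colnames(R1), "both@10")
  expected <- numeric(nrow(R1))
  span <- (3 * fs + 1):min(3 * fs + length(kern), nrow(R1))
  expected[span] <- kern[seq_along(span)]
  expect_equal(as.numeric(R1[, 1]), expected, tolerance = 1e-12)
  # two onsets closer than the kernel: samplewise sum, renormalized to peak 1
  tr2 <- stimulus_train(data.frame(target = "both", frequency = 10,
                                   onset = c(2, 5), duration = 1,
                                   rest_after = c(2, 20)))
  R2 <- build_regressors(tr2, fs)
  raw <- numeric(nrow(R2))
  for (on in c(2, 5)) {
    span <- (on * fs + 1):min(on * fs + length(kern), nrow(R2))
    raw[span] <- raw[span] + kern[seq_along(span)]
  }
  expect_equal(as.numeric(R2[, 1]), raw / max(raw), tolerance = 1e-12)
  expect_equal(max(R2[, 1]), 1)
  expect_true(all(R2 >= 0))
  expect_error(build_regressors(stimulus_train(NULL)), "empty")
})

test_that("z-scoring standardizes, excludes flat traces, ignores affine maps", {
  x <- matrix(rnorm(5 * 40, mean = 3, sd = 2), 5)
  z <- zscore_traces(x)
  expect_equal(rowMeans(z), rep(0, 5), tolerance = 1e-12)
  expect_equal(apply(z, 1, sd), rep(1, 5), tolerance = 1e-12)
  expect_equal(zscore_traces(z), z, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(zscore_traces(2 * x + 7), z, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_message(zf <- zscore_traces(rbind(x, 5)), "zero-variance")
  expect_equal(nrow(zf), 5)
  expect_equal(attr(zf, "excluded"), 6L)
})

test_that("regression r2 matches an independent projection oracle", {
  train <- single_epoch_train(onset = 1)
  R <- build_regressors(train, 4)
  # exact copy of a regressor: r2 = 1
  reg <- regress_rois(matrix(R[, 1], nrow = 1), R)
  expect_equal(reg$r2, 1, tolerance = 1e-12)
  # small instances vs lm() to 1e-10
  set.seed(21)
  Rs <- matrix(rnorm(20 * 3), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
  Y <- matrix(rnorm(5 * 20), 5, 20)
  out <- regress_rois(Y, Rs)
  for (i in 1:5) {
    fit <- lm(Y[i, ] ~ Rs)
    expect_equal(out$r2[i], summary(fit)$r.squared, tolerance = 1e-10)
    expect_equal(unname(out$coefficients[i, ]), unname(coef(fit)),
                 tolerance = 1e-8)
  }
  # collinear columns are named
  expect_error(regress_rois(Y, cbind(Rs, dup = Rs[, 1])), "dup")
})

test_that("null r2 matches the analytic p/(n-1) mean", {
  set.seed(77)
  n <- 600; p <- 13
  R <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, paste0("r", 1:p)))
  Y <- matrix(rnorm(300 * n), 300, n)
  r2 <- regress_rois(Y, R)$r2
  expect_equal(mean(r2), p / (n - 1), tolerance = 0.15)
  # signal at 1:1 variance ratio: r2 ~ 0.5
  sig <- scale(as.numeric(R[, 1]))
  Y2 <- matrix(rep(sig, each = 100), 100, n) + matrix(rnorm(100 * n), 100, n)
  expect_equal(mean(regress_rois(Y2, R)$r2), 0.5, tolerance = 0.05)
})

test_that("r2 pre-selection is boundary-inclusive and monotone", {
  th <- selection_thresholds()
  r2 <- c(0.1, 0.2, 0.3, NA)
  expect_equal(select_responsive(r2, th), c(FALSE, TRUE, TRUE, FALSE))
  expect_warning(select_responsive(c(0.05, 0.1), th), "no ROI")
  # lowering the threshold never removes a kept ROI
  set.seed(9); r2r <- runif(200)
  hi <- select_responsive(r2r, selection_thresholds(r2_select = 0.4))
  lo <- select_responsive(r2r, selection_thresholds(r2_select = 0.15))
  expect_true(all(lo[hi]))
})

test_that("cityblock k-means recovers planted profiles up to permutation", {
  set.seed(31)
  centers <- matrix(c(rep(c(5, 0, 0), each = 40),
                      rep(c(0, 5, 0), each = 40),
                      rep(c(0, 0, 5), each = 40)), nrow = 3, byrow = TRUE)
  truth <- rep(1:3, each = 30)
  X <- centers[truth, ] + matrix(rnorm(90 * 120, 0, 0.3), 90)
  km <- cluster_traces(X, k = 3, replicates = 5, seed = 4)
  perms <- list(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2), c(3,2,1))
  agreement <- max(vapply(perms, function(p) mean(p[km$labels] == truth),
                          numeric(1)))
  expect_equal(agreement, 1.0)
})

test_that("k-means honours its determinism and cost contracts", {
  set.seed(12)
  X <- matrix(rnorm(60 * 20), 60)
  km1 <- cluster_traces(X, k = 5, replicates = 5, seed = 3)
  km2 <- cluster_traces(X, k = 5, replicates = 5, seed = 3)
  expect_identical(km1$labels, km2$labels)
  # best-of-replicates: returned cost <= every replicate's cost
  expect_true(all(km1$cost <= km1$replicate_costs + 1e-9))
  # objective never increases across iterations
  expect_true(all(diff(km1$cost_history) <= 1e-9))
  # identical traces: both centroids collapse onto the common trace
  Xc <- matrix(rep(rnorm(20), each = 10), nrow = 10, byrow = FALSE)
  kmc <- cluster_traces(Xc, k = 2, replicates = 2, seed = 1)
  expect_equal(kmc$centers[1, ], Xc[1, ], tolerance = 1e-12)
  expect_equal(kmc$centers[2, ], Xc[1, ], tolerance = 1e-12)
  expect_error(cluster_traces(X, k = 100), "reduce n_clusters")
})

test_that("tone-responsive cluster selection applies the 1 SD criterion", {
  train <- default_stimulus_train(baseline = 20)
  fs <- 4
  R <- build_regressors(train, fs)
  n <- nrow(R)
  flat <- rep(0, n)
  tone <- as.numeric(R[, "speaker@100"])
  set.seed(2)
  noisy_tone <- 3 * tone + rnorm(n, 0, 0.2)
  cents <- rbind(flat, tone, noisy_tone)
  sel <- select_clusters(cents, train, fs, R = R)
  expect_false(1 %in% sel$selected)    # flat: never above baseline
  expect_true(2 %in% sel$selected)     # exact tone regressor
  expect_true(3 %in% sel$selected)     # 3 SD planted response, noisy
  expect_true(all(c("baseline_mean", "min_tone_peak") %in%
                    colnames(sel$report)))
  expect_error(select_clusters(cents, train[train$target != "speaker", ],
                               fs, thresholds = selection_thresholds()),
               "no tone epochs")
})

test_that("refinement keeps r2 strictly above 0.4", {
  train <- single_epoch_train(onset = 1)
  R <- build_regressors(train, 4)
  n <- nrow(R)
  X <- cbind(1, R)
  # construct traces with exact r2 by mixing a fitted and an orthogonal part
  r1 <- scale(R[, 1], scale = FALSE); u <- r1 / sqrt(sum(r1^2))
  set.seed(5)
  v <- residuals(lm(rnorm(n) ~ X - 1)); v <- v / sqrt(sum(v^2))
  make_trace <- function(r2) sqrt(r2) * u + sqrt(1 - r2) * v
  traces <- rbind(exact04 = t(make_trace(0.4)),
                  above = t(make_trace(0.41)),
                  centroid = R[, 1],
                  noise = rnorm(n))
  mask <- refine_rois(traces, R)
  expect_false(mask[1])                 # exactly 0.4: removed (strict)
  expect_true(mask[2])
  expect_true(mask[3])                  # centroid copy kept
  expect_false(mask[4])
  expect_equal(attr(mask, "r2")[1], 0.4, tolerance = 1e-9)
})

test_that("cluster filters enforce the cross-fish criterion", {
  train <- default_stimulus_train(baseline = 20)
  fs <- 4
  R <- build_regressors(train, fs)
  tone <- as.numeric(R[, "speaker@100"])
  cents <- rbind(3 * tone, 3 * tone)
  membership <- data.frame(
    cluster = c(rep(1, 20), rep(2, 24)),
    fish_id = c(c(rep(1, 19), 2),                  # 95% from fish 1
                rep(1:6, each = 4)))               # balanced across 6 fish
  out <- apply_cluster_filters(cents, membership, train, fs, R)
  expect_false(1 %in% out$clusters)
  expect_true(2 %in% out$clusters)
  expect_equal(out$report$max_fish_fraction[1], 0.95)
  # representation floor variant: fish missing from a cluster fails it
  th2 <- selection_thresholds(fish_criterion = "representation_floor")
  membership2 <- data.frame(cluster = rep(2, 10), fish_id = rep(1:5, 2))
  out2 <- apply_cluster_filters(cents, membership2, train, fs, R,
                                thresholds = th2, n_fish = 6)
  expect_false(2 %in% out2$clusters)
})

test_that("peak responses read trial windows, with truncation warning", {
  train <- single_epoch_train(onset = 2, duration = 1)
  fs <- 4
  n <- 40
  x <- rep(0.5, n)                                 # flat at baseline value
  pk <- peak_responses(x, train, fs)
  expect_equal(pk$peak, 0.5)
  x2 <- x; x2[(2 * fs + 1):(3 * fs)] <- 2          # boxcar of height 2
  expect_equal(peak_responses(x2, train, fs)$peak, 2)
  late <- single_epoch_train(onset = 9, duration = 1)
  expect_warning(peak_responses(rep(0, 40), late, fs), "truncated")
})

test_that("super-additivity index is the both-minus-sum contrast", {
  peaks <- data.frame(target = rep(c("both", "utricle", "saccule"), each = 3),
                      frequency = 100, trial = rep(1:3, 3),
                      peak = c(2, 2, 2, 0.5, 0.5, 0.5, 0.5, 0.5, 0.5))
  expect_equal(superadditivity_index(peaks, 100), 1.0)
  peaks$peak <- c(1, 1, 1, 0.5, 0.5, 0.5, 0.5, 0.5, 0.5)
  expect_equal(superadditivity_index(peaks, 100), 0)
  expect_error(superadditivity_index(peaks[peaks$target != "both", ], 100),
               "missing configuration")
})

test_that("the assembled pipeline recovers planted structure on a small world", {
  w <- small_calcium_world(seed = 6, n_fish = 4, n_rois = 400)
  res <- analyze_calcium(w$ds, thresholds = selection_thresholds(n_clusters = 12),
                         seed = 6)
  expect_s3_class(res, "calcium_analysis")
  expect_gte(length(res$final_clusters), 1)
  truth <- res$roi$label
  recovered <- res$roi$roi_id %in% res$membership$roi_id
  expect_gte(mean(recovered[truth != "none"]), 0.8)
  expect_lte(mean(recovered[truth == "none"]), 0.01)
  expect_true(!is.null(res$superadditivity))
  expect_output(print(res), "calcium analysis")
})
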
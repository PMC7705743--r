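test_that("static noiseless video renders identical frames", {
  spec <- small_video_spec(n_frames = 5, ground_truth_amplitude = 0)
  v <- render_otolith_video(spec)
  for (i in 2:5) expect_identical(v$stack[, , i], v$stack[, , 1])
  expect_equal(v$truth$dx_nm, rep(0, 5))
})

test_that("rendered motion matches the analytic sinusoid via the centroid", {
  spec <- small_video_spec(n_frames = 100, ground_truth_amplitude = 140,
                           ground_truth_frequency = 10)
  v <- render_otolith_video(spec)
  t <- v$truth$time_s
  expect_equal(v$truth$dx_nm, 140 * sin(2 * pi * 10 * t))
  # intensity-centroid oracle agrees with ground truth to < 0.02 px
  cx0 <- (spec$image_size[2] - 1) / 2
  for (i in c(1, 13, 26, 39, 77)) {
    est_px <- centroid_col(v$stack[, , i], spec$background_intensity) - cx0
    expect_lt(abs(est_px - v$truth$dx_nm[i] / spec$pixel_size), 0.02)
  }
})

test_that("video generation is a pure function of (spec, seed)", {
  spec <- small_video_spec(n_frames = 20, photon_noise_sd = 50,
                           background_drift = list(amplitude = 80,
                                                   frequency = 2),
                           seed = 99L)
  v1 <- render_otolith_video(spec)
  v2 <- render_otolith_video(spec)
  expect_identical(v1$stack, v2$stack)
  expect_identical(v1$truth, v2$truth)
  # and does not disturb the caller's RNG stream
  set.seed(5); before <- rnorm(1)
  set.seed(5); invisible(render_otolith_video(spec)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("train-gated videos vibrate only inside epochs", {
  train <- single_epoch_train(onset = 0.1, duration = 0.2)
  spec <- small_video_spec(n_frames = 400, ground_truth_amplitude = 100,
                           ground_truth_frequency = 100)
  v <- render_otolith_video(spec, train = train)
  t <- v$truth$time_s
  inside <- t >= 0.1 & t < 0.3
  expect_lt(max(abs(v$truth$dx_nm[!inside])), 1e-9)
  expect_gt(max(abs(v$truth$dx_nm[inside])), 90)
})

test_that("Nyquist violations are rejected", {
  expect_error(video_spec(frame_rate = 100, ground_truth_frequency = 50),
               "Nyquist")
  spec <- small_video_spec()
  expect_error(render_otolith_video(spec, train = single_epoch_train(
    frequency = 900, onset = 0.05, duration = 0.2)), "Nyquist")
})

test_that("simulated displacement traces follow the oscillator amplitude", {
  train <- single_epoch_train(frequency = 50, onset = 1, duration = 1)
  # gamma = 0: amplitude F/k at any frequency
  tr <- simulate_displacement_trace(mechanics_params(0, 1, force = 1), train,
                                    frame_rate = 1000)
  expect_equal(estimate_amplitude(tr, 50, epoch = c(1, 1)), 1,
               tolerance = 1e-3)
  expect_true(all(tr$dx_nm[tr$time_s < 1] == 0))
  # doubling F doubles the response
  tr2 <- simulate_displacement_trace(mechanics_params(0, 1, force = 2), train,
                                     frame_rate = 1000)
  expect_equal(tr2$dx_nm, 2 * tr$dx_nm, tolerance = 1e-12)
  # half-power point: amplitude 1/sqrt(2) at f = k/(2 pi gamma)
  tr3 <- simulate_displacement_trace(
    mechanics_params(1 / (2 * pi), 1, force = 1),
    single_epoch_train(frequency = 1, onset = 0, duration = 5),
    frame_rate = 200)
  expect_equal(estimate_amplitude(tr3, 1, epoch = c(0, 5)), 1 / sqrt(2),
               tolerance = 1e-3)
  expect_error(mechanics_params(1, -2), "> 0")
})

test_that("noiseless calcium traces are exact kernel copies", {
  train <- single_epoch_train(target = "saccule", frequency = 100, onset = 5)
  prof <- cluster_profile("resp", c("saccule@100" = 2), 1)
  spec <- calcium_spec(n_fish = 1, n_rois_per_fish = 1, noise_sd = 0,
                       baseline = 3, cluster_profiles = list(prof))
  ds <- simulate_calcium_dataset(spec, train)
  expect_equal(ds$roi$label, "resp")
  kern <- gcamp_kernel(0.2, 3.5, 4)
  expected <- rep(3, ncol(ds$traces))
  at <- floor(5 * 4) + 1
  span <- at:min(at + length(kern) - 1, length(expected))
  expected[span] <- expected[span] + 2 * kern[seq_along(span)]
  expect_equal(as.numeric(ds$traces[1, ]), expected, tolerance = 1e-12)
})

test_that("non-responders are constant at baseline without noise", {
  train <- single_epoch_train()
  spec <- calcium_spec(n_fish = 1, n_rois_per_fish = 20, noise_sd = 0,
                       baseline = 1,
                       cluster_profiles = list(
                         cluster_profile("resp", c("utricle@100" = 1), 0.3)),
                       seed = 3)
  ds <- simulate_calcium_dataset(spec, train)
  none <- ds$roi$label == "none"
  expect_true(any(none))
  expect_true(all(ds$traces[none, ] == 1))
})

test_that("planted super-additive amplitudes yield a positive index", {
  train <- make_stimulus_train(
    data.frame(target = c("utricle", "saccule", "both"), frequency = 100))
  prof <- cluster_profile("super", c("utricle@100" = 0.5, "saccule@100" = 0.5,
                                     "both@100" = 2), 1)
  spec <- calcium_spec(n_fish = 1, n_rois_per_fish = 1, noise_sd = 0,
                       cluster_profiles = list(prof))
  ds <- simulate_calcium_dataset(spec, train)
  peaks <- peak_responses(as.numeric(ds$traces[1, ]), train, 4)
  expect_gt(superadditivity_index(peaks, 100), 0)
})

test_that("calcium generator validates parameters and is reproducible", {
  expect_error(calcium_spec(kernel_params = list(tau_rise = -1,
                                                 tau_decay = 3.5)), "> 0")
  expect_error(calcium_spec(cluster_profiles = list(
    cluster_profile("a", c("utricle@100" = 1), 0.7),
    cluster_profile("b", c("saccule@100" = 1), 0.7))), "exceed 1")
  w <- small_calcium_world(seed = 8, n_fish = 2, n_rois = 30)
  ds2 <- simulate_calcium_dataset(w$spec, w$train)
  expect_identical(w$ds$traces, ds2$traces)
  expect_identical(w$ds$roi, ds2$roi)
})
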
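# Independent oracles and fixture builders shared across tests.

# Exact subpixel translation via the Fourier shift theorem: content moves by
# (+dy rows, +dx columns), circularly.
fourier_shift <- function(img, dy, dx) {
  nr <- nrow(img); nc <- ncol(img)
  fr <- c(0:(ceiling(nr / 2) - 1), -(floor(nr / 2)):-1)
  fc <- c(0:(ceiling(nc / 2) - 1), -(floor(nc / 2)):-1)
  ph <- exp(-2i * pi * (outer(fr, rep(1, nc)) * dy / nr +
                          outer(rep(1, nr), fc) * dx / nc))
  Re(stats::fft(stats::fft(img) * ph, inverse = TRUE)) / length(img)
}

# Integer circular shift: content moves by (+dy rows, +dx columns).
roll2 <- function(img, dy, dx) {
  nr <- nrow(img); nc <- ncol(img)
  ri <- ((seq_len(nr) - 1 - dy) %% nr) + 1
  ci <- ((seq_len(nc) - 1 - dx) %% nc) + 1
  img[ri, ci]
}

# A bright anti-aliased disc test image.
disc_image <- function(n = 64, r = 20) {
  boatools:::render_disc(n, n, (n - 1) / 2, (n - 1) / 2, r) * 9000 + 1000
}

# Background-subtracted intensity centroid (0-based column coordinate).
centroid_col <- function(frame, bg = 1000) {
  w <- pmax(frame - bg, 0)
  sum((col(frame) - 1) * w) / sum(w)
}

# Small, fast video spec for unit tests.
small_video_spec <- function(...) {
  args <- utils::modifyList(list(n_frames = 500, image_size = c(48L, 48L),
                                 disc_radius = 14), list(...))
  do.call(video_spec, args)
}

# One-configuration train with a single trial.
single_epoch_train <- function(target = "utricle", frequency = 100,
                               onset = 2, duration = 1) {
  stimulus_train(data.frame(target = target, frequency = frequency,
                            onset = onset, duration = duration,
                            rest_after = 4))
}

# Small calcium world: few fish/ROIs, short train, used where the full
# 12,000-ROI default would be wasteful.
small_calcium_world <- function(seed = 1, n_fish = 4L, n_rois = 300L,
                                noise_sd = 1) {
  train <- default_stimulus_train(baseline = 20)
  spec <- calcium_spec(n_fish = n_fish, n_rois_per_fish = n_rois,
                       noise_sd = noise_sd, seed = seed)
  list(train = train, spec = spec,
       ds = simulate_calcium_dataset(spec, train))
}
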
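# Shared fixtures, all built in code.

# Analytic textured image: sum of Gaussian blobs, rendered at optionally
# transformed positions (content moved by `shift` / rotated by `theta`
# about the image center). No resampling, so subpixel motion is exact.
blob_image <- function(centers, H, W, shift = c(0, 0), theta = 0, sigma2 = 4) {
  cx <- (W + 1) / 2; cy <- (H + 1) / 2
  R <- matrix(c(cos(theta), -sin(theta), sin(theta), cos(theta)), 2, 2)
  xs <- rep(seq_len(W), each = H); ys <- rep(seq_len(H), W)
  img <- matrix(0, H, W)
  for (i in seq_len(nrow(centers))) {
    p <- R %*% (centers[i, 1:2] - c(cx, cy)) + c(cx, cy) + shift
    img <- img + centers[i, 3] *
      matrix(exp(-((xs - p[1])^2 + (ys - p[2])^2) / (2 * sigma2)), H, W)
  }
  img
}

random_blob_centers <- function(n, H, W, seed) {
  set.seed(seed)
  cbind(runif(n, 5, W - 5), runif(n, 5, H - 5), runif(n, 50, 150))
}

# Small mosaic with frame-dimension attributes preserved on subsetting.
small_mosaic <- function(spacing = 5, jitter = 0.3, field = 0.15, seed = 1) {
  generate_mosaic(mosaic_spec(spacing = spacing, jitter_sd = jitter,
                              field_size = field, seed = seed))
}

# Random mean-subtracted-style signal table with a missing mask.
random_signal_table <- function(nc, nt, seed, frame_rate = 10,
                                stimulus_frame = floor(nt / 2),
                                missing_frac = 0) {
  set.seed(seed)
  sig <- matrix(rnorm(nc * nt), nc, nt)
  miss <- matrix(runif(nc * nt) < missing_frac, nc, nt)
  cone_signal_table(sig, miss, frame_rate, stimulus_frame)
}

# Extract per-cone individual-RMS amplitudes from a list of raw
# (not yet mean-subtracted) signal tables.
trial_amplitudes <- function(tables, window = 1) {
  tables <- lapply(tables, subtract_prestim_mean)
  ids <- tables[[1L]]$cone_ids
  vapply(ids, function(id) {
    extract_amplitude(individual_rms(tables, id), window)$amplitude
  }, numeric(1L))
}

# Log individual-RMS amplitudes for a simulated trial arm.
simulate_arm_log_amplitudes <- function(n_cones, resp, seed,
                                        n_acquisitions = 10, duration = 4) {
  a <- draw_amplitudes(n_cones, resp, seed = seed)
  tabs <- simulate_trial_signals(a, resp, n_acquisitions = n_acquisitions,
                                 duration = duration, seed = seed + 1)
  suppressMessages(log_transform(trial_amplitudes(tabs)))
}
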
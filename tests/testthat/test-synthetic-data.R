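test_that("unjittered mosaics are exactly hexagonal and seeded runs repeat", {
  spec <- mosaic_spec(spacing = 5, jitter_sd = 0, field_size = 0.25, seed = 3)
  m <- generate_mosaic(spec)
  res <- bound_nnd(m, scale = attr(m, "um_per_px"))
  expect_equal(res$mean_bound_nnd, 5, tolerance = 1e-12)

  spec_j <- mosaic_spec(spacing = 5, jitter_sd = 0.5, field_size = 0.25, seed = 11)
  expect_identical(generate_mosaic(spec_j), generate_mosaic(spec_j))
  expect_false(isTRUE(all.equal(generate_mosaic(spec_j),
                                generate_mosaic(mosaic_spec(spacing = 5,
                                                            jitter_sd = 0.5,
                                                            field_size = 0.25,
                                                            seed = 12)))))
  expect_error(mosaic_spec(spacing = 0), "spacing")
})

test_that("jittered mosaic mean bound NND shrinks predictably from the spacing", {
  # Positional jitter shortens nearest-neighbor distances (the minimum
  # over ~6 jittered neighbor distances concentrates below the lattice
  # spacing). Bounds below are Monte-Carlo derived for this generator:
  # light jitter (0.2 um) stays within a tenth of the spacing; moderate
  # jitter (0.5 um) lands near 5 - 1.2 * (sqrt(2) * 0.5) ~ 4.1 um.
  means_02 <- vapply(1:10, function(s) {
    m <- generate_mosaic(mosaic_spec(spacing = 5, jitter_sd = 0.2,
                                     field_size = 0.3, seed = s))
    bound_nnd(m, scale = attr(m, "um_per_px"))$mean_bound_nnd
  }, numeric(1L))
  expect_true(all(abs(means_02 - 5) < 0.5))
  means_05 <- vapply(1:10, function(s) {
    m <- generate_mosaic(mosaic_spec(spacing = 5, jitter_sd = 0.5,
                                     field_size = 0.3, seed = s))
    bound_nnd(m, scale = attr(m, "um_per_px"))$mean_bound_nnd
  }, numeric(1L))
  expect_true(all(means_05 > 3.9 & means_05 < 4.4))
  expect_true(all(means_05 < 5))
})

test_that("rendered acquisitions honour the response manifest", {
  m <- small_mosaic(seed = 5)
  resp0 <- response_spec(noise_sd = 0, dropout_fraction = 0,
                         nonresponder_fraction = 0, seed = 2)
  amps <- draw_amplitudes(nrow(m), resp0, seed = 9)
  amps[1L] <- 0                      # a non-responding cone
  acq <- render_acquisition(m, resp0, duration = 4, amplitudes = amps, seed = 31)
  tab <- subtract_prestim_mean(
    extract_cone_signals(acq$stack, m, compute_column_radius(m)))
  # nonresponder: signal identically zero, amplitude zero
  expect_true(all(abs(tab$signal[1L, ]) < 1e-9))
  a1 <- extract_amplitude(individual_rms(list(tab), 1L))$amplitude
  expect_equal(a1, 0, tolerance = 1e-9)

  # programmed a vs 2a: extracted amplitudes in ratio 1:2
  amps2 <- amps * 2
  acq2 <- render_acquisition(m, resp0, duration = 4, amplitudes = amps2, seed = 31)
  tab2 <- subtract_prestim_mean(
    extract_cone_signals(acq2$stack, m, compute_column_radius(m)))
  i <- which(amps > 0)[1:5]
  g1 <- vapply(i, function(c) extract_amplitude(individual_rms(list(tab), c))$amplitude, numeric(1))
  g2 <- vapply(i, function(c) extract_amplitude(individual_rms(list(tab2), c))$amplitude, numeric(1))
  expect_equal(g2 / g1, rep(2, 5), tolerance = 1e-9)
})

test_that("frame dropout is counted and recorded exactly", {
  m <- small_mosaic(field = 0.1, seed = 6)
  resp <- response_spec(dropout_fraction = 0.3, seed = 4)
  acq <- render_acquisition(m, resp, frame_rate = 29.4, duration = 6, seed = 8)
  expect_equal(dim(acq$stack$frames)[3L], 176L)
  expect_length(acq$manifest$excluded_frames, floor(0.3 * 176))
  expect_identical(which(!acq$stack$valid), as.integer(acq$manifest$excluded_frames))
  expect_error(render_acquisition(rbind(m, c(1e4, 1e4)), resp, duration = 6,
                                  dim_px = attr(m, "dim_px")),
               "out of bounds")
})

test_that("synthetic LRPs place the EZ and IZ peaks as programmed", {
  lrp <- generate_lrp(30, peak_sd = 3, noise_sd = 0, depth_step = 0.5)
  i <- order(-lrp$reflectance)
  expect_equal(as.numeric(detect_os_length(lrp)), 30, tolerance = 1e-6)
  expect_error(generate_lrp(1, depth_step = 0.5), "unresolvable")
  expect_error(generate_lrp(-3), "positive")
  # determinism of the noisy profile
  expect_identical(generate_lrp(25, noise_sd = 0.1, seed = 7),
                   generate_lrp(25, noise_sd = 0.1, seed = 7))
})

test_that("cohort generation writes the expected trial structure, reproducibly", {
  tiny_mosaic <- list(spacing = 5, jitter_sd = 0.1, field_size = 0.06,
                      pixels_per_degree = 600, retinal_magnification = 291)
  tiny_resp <- list(stimulus_time = 0.1, response_duration = 0.2,
                    noise_sd = 1, dropout_fraction = 0)
  spec <- list(mosaic = do.call(mosaic_spec, tiny_mosaic),
               response = do.call(response_spec, tiny_resp))
  d1 <- file.path(tempdir(), "cohort_a"); d2 <- file.path(tempdir(), "cohort_b")
  on.exit(unlink(c(d1, d2), recursive = TRUE), add = TRUE)
  for (d in c(d1, d2)) {
    generate_cohort(spec, disease_spec = NULL, eccentricities = c(1, 4),
                    n_subjects = 2, seed = 42, out_dir = d,
                    n_stim_trials = 3, n_acquisitions = 10,
                    frame_rate = 29.4, duration = 0.5)
  }
  trials <- list.dirs(d1, recursive = TRUE)
  trials <- trials[grepl("trial_[0-9]+$", trials)]
  expect_length(trials, 2 * 2 * 4)                       # subj x ecc x trials
  tifs <- list.files(d1, pattern = "\\.tif$", recursive = TRUE)
  expect_length(tifs, 2 * 2 * 4 * 10)                    # 160 acquisitions
  # identical seeds => byte-identical manifests
  for (f in c("cohort_manifest.json",
              file.path("control_01", "ecc_1", "manifest.json"))) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
  }
})

test_that("frame stacks survive the 16-bit TIFF round trip", {
  m <- small_mosaic(field = 0.1, seed = 2)
  # moderate amplitudes so the 16-bit range is not clipped
  resp <- response_spec(mean_log_amplitude = 1, sd_log_amplitude = 0.1,
                        noise_sd = 1, stimulus_time = 0.1,
                        response_duration = 0.2, seed = 1)
  acq <- render_acquisition(m, resp, duration = 0.5, seed = 3)
  p <- tempfile(fileext = ".tif")
  on.exit(unlink(p), add = TRUE)
  write_frame_stack(acq$stack, p)
  rt <- read_frame_stack(p, acq$stack$frame_rate, acq$stack$stimulus_frame,
                         valid = acq$stack$valid)
  expect_equal(dim(rt$frames), dim(acq$stack$frames))
  expect_lt(max(abs(rt$frames - acq$stack$frames)), 0.5 / 16 + 1e-9)
})
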
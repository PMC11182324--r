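make_stack <- function(frames3d, fr = 29.4, stim = 2, ...) {
  frame_stack(frames3d, fr, stim, ...)
}

test_that("acquisitions keeping at least half their frames are retained", {
  mk <- function(nvalid, nt = 176) {
    v <- rep(FALSE, nt); v[seq_len(nvalid)] <- TRUE
    make_stack(array(1, dim = c(4, 4, nt)), valid = v)
  }
  out <- exclude_short_acquisitions(list(mk(88), mk(87), mk(176)), 176)
  expect_length(out, 2L)
  expect_equal(vapply(out, function(s) sum(s$valid), numeric(1)), c(88, 176))
  full <- list(mk(176), mk(176))
  expect_identical(exclude_short_acquisitions(full, 176), full)
  expect_identical(exclude_short_acquisitions(list(), 176), list())
})

test_that("frame standardization hits the target moments and is stable", {
  set.seed(1)
  f <- array(rnorm(32 * 32 * 3, mean = 10, sd = 2), dim = c(32, 32, 3))
  region <- array(TRUE, dim = dim(f))
  st <- standardize_frames(make_stack(f, image_region = region))
  for (t in 1:3) {
    expect_equal(mean(st$frames[, , t]), 70, tolerance = 1e-6)
    expect_equal(sd(st$frames[, , t]), 35, tolerance = 1e-6)
  }
  # idempotence
  st2 <- standardize_frames(st)
  expect_equal(st2$frames, st$frames, tolerance = 1e-9)
  # affine invariance: gain/offset on the input changes nothing
  st3 <- standardize_frames(make_stack(3.7 * f + 11, image_region = region))
  expect_equal(st3$frames, st$frames, tolerance = 1e-9)
  # zero-variance frame flagged invalid
  f0 <- f; f0[, , 2] <- 5
  st4 <- standardize_frames(make_stack(f0, image_region = region))
  expect_false(st4$valid[2])
  expect_true(all(st4$valid[c(1, 3)]))
})

test_that("hill climbing lands on local maxima and respects plateaus", {
  img <- blob_image(cbind(20, 20, 100), 40, 40)
  expect_equal(unname(refine_coordinates(img, cbind(19, 20))[1, ]), c(20, 20))
  expect_equal(unname(refine_coordinates(img, cbind(20, 20))[1, ]), c(20, 20))
  flat <- matrix(1, 40, 40)
  expect_equal(unname(refine_coordinates(flat, cbind(13, 27))[1, ]), c(13, 27))
  # displacement cap: a far-off start cannot travel beyond max_radius
  ref <- refine_coordinates(img, cbind(10, 20), max_radius = 3)
  expect_lte(sqrt(sum((ref[1, ] - c(10, 20))^2)), 3)
})

test_that("column radius follows median nearest-neighbor spacing", {
  hexa <- generate_mosaic(mosaic_spec(spacing = 10 * 0.485, jitter_sd = 0,
                                      field_size = 0.25, seed = 1))
  expect_equal(compute_column_radius(hexa, 0.6), 3, tolerance = 1e-9)
  two <- cbind(c(0, 8), c(0, 0))
  expect_equal(compute_column_radius(two, 0.5), 2)
  expect_error(compute_column_radius(cbind(1, 1)), "single cone")
  # jittered: median spacing equals the O(n^2) all-pairs oracle
  m <- small_mosaic(jitter = 0.6, seed = 8)
  nn <- vapply(seq_len(nrow(m)), function(i) {
    min(sqrt((m[-i, 1] - m[i, 1])^2 + (m[-i, 2] - m[i, 2])^2))
  }, numeric(1L))
  expect_equal(compute_column_radius(m, 0.6),
               max(1, 0.5 * median(nn) * 0.6), tolerance = 1e-12)
})

test_that("column extraction equals a per-pixel loop oracle", {
  # uniform frames: every cone signal equals the frame value
  f <- array(7, dim = c(32, 32, 4))
  stk <- make_stack(f, valid = c(TRUE, TRUE, FALSE, TRUE))
  coords <- cbind(c(10, 20), c(12, 25))
  tab <- extract_cone_signals(stk, coords, radius = 3)
  expect_true(all(tab$signal[, c(1, 2, 4)] == 7))
  expect_true(all(tab$missing[, 3]))                    # invalid frame
  # single off-center Gaussian vs brute-force pixel loop, exactly
  ctr <- c(16.3, 14.7)
  img <- blob_image(cbind(ctr[1], ctr[2], 90), 32, 32)
  stk1 <- make_stack(array(img, dim = c(32, 32, 2)))
  tab1 <- extract_cone_signals(stk1, rbind(ctr), radius = 2.5)
  acc <- c()
  for (y in 1:32) for (x in 1:32) {
    if ((x - ctr[1])^2 + (y - ctr[2])^2 <= 2.5^2 && img[y, x] > 0) {
      acc <- c(acc, img[y, x])
    }
  }
  expect_identical(tab1$signal[1, 1], mean(acc))
})

test_that("cone exclusion rules match their boundary semantics in any order", {
  nt <- 30L; fr <- 29.4; stim <- 10L
  win <- stim:(stim + ceiling(0.2 * fr))               # 7 frames
  sig <- matrix(1, 4, nt)
  miss <- matrix(FALSE, 4, nt)
  miss[1, win[1:4]] <- TRUE                            # 4/7 > 50% of window
  miss[2, 16:30] <- TRUE                               # exactly 50% of frames
  tab <- cone_signal_table(sig, miss, fr, stim)
  out <- apply_exclusion(tab, n_acquisitions_present = c(10, 10, 5, 4),
                         n_acquisitions_total = 10)
  rep <- attr(out, "exclusion_report")
  expect_identical(rep$reason,
                   c("stimulus_window_missing", "half_frames_missing",
                     "retained", "too_few_acquisitions"))
  expect_identical(out$cone_ids, 3L)
  # 3 of 7 window frames missing (43%) is tolerated
  miss2 <- matrix(FALSE, 1, nt); miss2[1, win[1:3]] <- TRUE
  ok <- apply_exclusion(cone_signal_table(sig[1, , drop = FALSE], miss2, fr, stim))
  expect_identical(attr(ok, "exclusion_report")$reason, "retained")
  # order independence: the retained set is the complement of the union
  # of per-rule violations, checked rule by rule
  r_win <- rowMeans(miss[, win]) > 0.5
  r_all <- rowMeans(miss) >= 0.5
  r_acq <- c(10, 10, 5, 4) / 10 < 0.5
  expect_identical(which(!(r_win | r_all | r_acq)), 3L)
})

test_that("pre-stimulus mean subtraction centers the baseline", {
  tab <- cone_signal_table(matrix(c(1, 3, 5), 1), frame_rate = 1,
                           stimulus_frame = 3)
  out <- subtract_prestim_mean(tab)
  expect_equal(out$signal[1, ], c(-1, 1, 3))            # pre {1,3}, post {5}->3
  const <- cone_signal_table(matrix(4, 2, 6), frame_rate = 2, stimulus_frame = 4)
  expect_true(all(subtract_prestim_mean(const)$signal == 0))
  # property: pre-stimulus mean is 0 afterwards, over random tables
  for (s in 1:25) {
    tab <- random_signal_table(6, 40, seed = s, missing_frac = 0.1)
    out <- subtract_prestim_mean(tab)
    pre <- out$signal[, seq_len(out$stimulus_frame - 1L), drop = FALSE]
    expect_true(all(abs(rowMeans(pre, na.rm = TRUE)) < 1e-9))
  }
})

test_that("per-cone offsets vanish from downstream RMS traces", {
  tab <- random_signal_table(8, 60, seed = 3, missing_frac = 0.05)
  shifted <- cone_signal_table(tab$signal + seq_len(8) * 10, tab$missing,
                               tab$frame_rate, tab$stimulus_frame)
  r1 <- population_rms(subtract_prestim_mean(tab))
  r2 <- population_rms(subtract_prestim_mean(shifted))
  expect_equal(r1$values, r2$values, tolerance = 1e-9)
})
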
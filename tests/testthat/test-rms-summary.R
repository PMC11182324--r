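test_that("population RMS matches hand arithmetic and a brute-force oracle", {
  tab <- cone_signal_table(matrix(c(3, 4), 2, 1), frame_rate = 1,
                           stimulus_frame = 1)
  expect_equal(population_rms(tab)$values, sqrt((9 + 16) / 2))
  zero <- cone_signal_table(matrix(0, 3, 10), frame_rate = 1, stimulus_frame = 5)
  expect_true(all(population_rms(zero)$values == 0))
  # random 20 x 100 table vs element-wise double loop, exactly
  tab <- random_signal_table(20, 100, seed = 14, missing_frac = 0.1)
  tr <- population_rms(tab)
  for (t in seq_len(100)) {
    vals <- c()
    for (c in seq_len(20)) {
      if (!tab$missing[c, t]) vals <- c(vals, tab$signal[c, t]^2)
    }
    expected <- if (length(vals)) sqrt(mean(vals)) else NA_real_
    expect_identical(tr$values[t], expected)
    expect_equal(tr$n_contributing[t], length(vals))
  }
})

test_that("individual RMS pools one cone across acquisitions", {
  one <- cone_signal_table(matrix(c(-2, 5), 1), frame_rate = 1, stimulus_frame = 1)
  expect_equal(individual_rms(list(one), 1L)$values, c(2, 5))   # m = 1: |c|
  a <- cone_signal_table(matrix(0, 1, 1), frame_rate = 1, stimulus_frame = 1)
  b <- cone_signal_table(matrix(6, 1, 1), frame_rate = 1, stimulus_frame = 1)
  expect_equal(individual_rms(list(a, b), 1L)$values, 6 / sqrt(2))
  expect_error(individual_rms(list(a), 99L), "absent")
  # 10-acquisition fixture vs brute-force oracle
  acqs <- lapply(1:10, function(s) random_signal_table(5, 30, seed = 100 + s,
                                                       missing_frac = 0.15))
  for (id in 1:5) {
    tr <- individual_rms(acqs, id)
    for (t in 1:30) {
      vals <- c()
      for (s in 1:10) {
        if (!acqs[[s]]$missing[id, t]) vals <- c(vals, acqs[[s]]$signal[id, t]^2)
      }
      expected <- if (length(vals)) sqrt(mean(vals)) else NA_real_
      expect_identical(tr$values[t], expected)
    }
  }
})

test_that("amplitude extraction uses interpolated percentiles over 1-s windows", {
  time <- (0:179) / 30
  stim <- which(time >= 2)[1]
  k <- rep(5, 180)
  tr <- rms_trace(k, time, stim, rep(10L, 180), "population")
  expect_equal(extract_amplitude(tr)$amplitude, 0)
  v <- rep(0, 180); v[time > 2 & time <= 3] <- 10
  tr2 <- rms_trace(v, time, stim, rep(10L, 180), "population")
  expect_equal(extract_amplitude(tr2)$amplitude, 10)
  # post window = {0, 1, ..., 29} -> p99 = 28.71 by rank interpolation
  v3 <- rep(0, 180)
  v3[time > 2 & time <= 3] <- 0:29
  tr3 <- rms_trace(v3, time, stim, rep(10L, 180), "individual")
  rec <- extract_amplitude(tr3)
  expect_equal(rec$poststim_p99, 28.71, tolerance = 1e-9)
  expect_equal(rec$amplitude, 28.71, tolerance = 1e-9)
  expect_error(extract_amplitude(rms_trace(c(1, 1), c(0, 10), 2L, c(1L, 1L),
                                           "population")),
               "at least 2")
})

test_that("log transform and CDF behave as order statistics", {
  expect_equal(suppressMessages(log_transform(c(100, 1))), c(2, 0))
  expect_equal(suppressMessages(log_transform(10^c(-2, 0, 3))), c(-2, 0, 3))
  expect_message(out <- log_transform(c(10, -1, 0)), "non-positive")
  expect_identical(is.na(out), c(FALSE, TRUE, TRUE))
  F <- amplitude_cdf(c(1, 2, 3))
  expect_equal(F(2), 2 / 3)
  set.seed(2)
  x <- rnorm(1000)
  F2 <- amplitude_cdf(x)
  expect_equal(F2(x), rank(x) / 1000)                  # rank/n oracle
  xs <- sort(x)
  expect_true(all(diff(F2(xs)) >= 0))
  expect_equal(F2(min(x)), 1 / 1000)
  expect_equal(F2(max(x)), 1)
  expect_error(amplitude_cdf(NA_real_), "empty")
})

test_that("healthy fraction is calibrated against its own normative sample", {
  set.seed(5)
  x <- rnorm(200, 1.5, 0.35)
  nd <- normative_distribution(x)
  expect_equal(unname(nd$p5_threshold), unname(quantile(x, 0.05, type = 7)))
  f <- healthy_fraction(x, nd)
  expect_gte(f, 0.95 - 1 / 200)
  expect_lte(f, 0.95 + 1 / 200)
  expect_equal(healthy_fraction(nd$p5_threshold - 1, nd), 0)
  expect_equal(healthy_fraction(c(2, NA), nd), 0.5)     # NA counts unhealthy
})

test_that("RMS summaries are scale-equivariant and reduce to |signal| for one cone", {
  tab <- random_signal_table(6, 50, seed = 9)
  k <- 3.7
  scaled <- cone_signal_table(tab$signal * k, tab$missing, tab$frame_rate,
                              tab$stimulus_frame)
  expect_equal(population_rms(scaled)$values, k * population_rms(tab)$values)
  a1 <- extract_amplitude(population_rms(tab))
  a2 <- extract_amplitude(population_rms(scaled))
  expect_equal(a2$amplitude, k * a1$amplitude)
  one <- cone_signal_table(tab$signal[1, , drop = FALSE], frame_rate = 10,
                           stimulus_frame = 25)
  expect_equal(population_rms(one)$values, abs(tab$signal[1, ]))
})

test_that("the noise floor is positive and shrinks with more acquisitions", {
  resp <- response_spec(mean_log_amplitude = -10, sd_log_amplitude = 0,
                        nonresponder_fraction = 0, noise_sd = 5, seed = 1)
  floor_m <- function(m) {
    tabs <- simulate_trial_signals(rep(0, 80), resp, n_acquisitions = m,
                                   duration = 4, seed = 77)
    mean(trial_amplitudes(tabs))
  }
  f2 <- floor_m(2); f10 <- floor_m(10)
  expect_gt(f2, 0)
  expect_gt(f10, 0)
  expect_lt(f10, f2)
})
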
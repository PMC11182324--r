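#' Specification of the stimulus-evoked reflectance response
#'
#' Parameters of the synthetic per-cone response. After stimulus delivery,
#' each responding cone's reflectance fluctuates about its baseline with a
#' root-mean-square amplitude drawn from a log10-normal distribution;
#' `nonresponder_fraction` of cones (an S-cone-like subpopulation that the
#' 554 nm stimulus barely excites) do not respond at all. Reflectance noise
#' of SD `noise_sd` is present on every frame, and `dropout_fraction` of
#' frames are marked invalid to emulate registration losses.
#'
#' The fluctuation is a controlled-RMS process: amplitude times an
#' independent random sign per frame. Its per-frame RMS equals the
#' programmed amplitude exactly, which is what makes the manifest a usable
#' ground truth for the extraction pipeline (see the methods vignette).
#'
#' @param mean_log_amplitude mean of log10 amplitude (amplitude in the
#'   same arbitrary units as extracted signals).
#' @param sd_log_amplitude SD of log10 amplitude across cones.
#' @param nonresponder_fraction fraction of cones with zero response.
#' @param noise_sd per-frame reflectance noise SD (signal units). The
#'   default of 5 puts the extracted-amplitude noise floor near 5 AU for
#'   a 10-acquisition trial, the floor observed for cone populations with
#'   mean response amplitudes around 30 AU.
#' @param dropout_fraction fraction of frames marked invalid.
#' @param stimulus_time stimulus delivery time, s.
#' @param response_duration length of the respondent window, s.
#' @param seed RNG seed.
#' @return an object of class `response_spec`.
#' @export
response_spec <- function(mean_log_amplitude = 1.5, sd_log_amplitude = 0.35,
                          nonresponder_fraction = 0.05, noise_sd = 5,
                          dropout_fraction = 0, stimulus_time = 2,
                          response_duration = 1, seed = NULL) {
  if (nonresponder_fraction < 0 || nonresponder_fraction > 1) {
    stop("nonresponder_fraction must lie in [0, 1]")
  }
  if (dropout_fraction < 0 || dropout_fraction > 1) {
    stop("dropout_fraction must lie in [0, 1]")
  }
  stopifnot(noise_sd >= 0, stimulus_time >= 0, response_duration > 0)
  structure(list(mean_log_amplitude = mean_log_amplitude,
                 sd_log_amplitude = sd_log_amplitude,
                 nonresponder_fraction = nonresponder_fraction,
                 noise_sd = noise_sd, dropout_fraction = dropout_fraction,
                 stimulus_time = stimulus_time,
                 response_duration = response_duration, seed = seed),
            class = "response_spec")
}

#' Draw ground-truth cone amplitudes
#'
#' Amplitudes are `10^N(mean_log_amplitude, sd_log_amplitude)` for
#' responders and exactly 0 for the non-responding fraction (rounded down
#' to `floor(fraction * n)` cones, chosen at random).
#'
#' @param n number of cones.
#' @param resp a [response_spec()].
#' @param seed RNG seed (defaults to `resp$seed`).
#' @return numeric vector of length `n`.
#' @export
draw_amplitudes <- function(n, resp, seed = resp$seed) {
  with_seed(seed, {
    a <- 10^stats::rnorm(n, resp$mean_log_amplitude, resp$sd_log_amplitude)
    k <- floor(resp$nonresponder_fraction * n)
    if (k > 0) a[sample.int(n, k)] <- 0
    a
  })
}

# Internal: simulation timebase. T frames, frame k at (k-1)/rate seconds;
# the stimulus frame is the first frame at or after stimulus_time.
sim_timebase <- function(frame_rate, duration, stimulus_time) {
  nt <- floor(duration * frame_rate)
  if (nt < 2L) stop("duration * frame_rate must give at least 2 frames")
  time <- (seq_len(nt) - 1) / frame_rate
  stim <- which(time >= stimulus_time)[1L]
  if (is.na(stim)) stop("stimulus_time lies beyond the recording")
  list(n = nt, time = time, stimulus_frame = stim)
}

# Internal: per-cone, per-frame reflectance deviations about baseline
# (response signs * amplitude in the response window, plus noise), and the
# dropout frame set. Draws happen in a fixed order for reproducibility.
sim_deviations <- function(amplitudes, resp, tb) {
  nc <- length(amplitudes)
  in_resp <- tb$time >= resp$stimulus_time &
    tb$time <= resp$stimulus_time + resp$response_duration
  signs <- matrix(0, nc, tb$n)
  signs[, in_resp] <- sample(c(-1, 1), nc * sum(in_resp), replace = TRUE)
  dev <- amplitudes * signs
  if (resp$noise_sd > 0) {
    dev <- dev + matrix(stats::rnorm(nc * tb$n, 0, resp$noise_sd), nc, tb$n)
  }
  n_drop <- floor(resp$dropout_fraction * tb$n)
  dropped <- if (n_drop > 0) sort(sample.int(tb$n, n_drop)) else integer(0)
  list(dev = dev, dropped = dropped)
}

#' Render a synthetic iORG acquisition
#'
#' Renders cones as truncated 2-D Gaussian profiles (FWHM =
#' `fwhm_fraction` of the mosaic spacing, truncated at half the spacing so
#' neighboring sampling columns stay optically independent) whose peak
#' intensity fluctuates after the stimulus. Each cone's fluctuation is
#' scaled so that the mean intensity over its sampling column equals the
#' programmed deviation exactly; manifest amplitudes are therefore in
#' extracted-signal units.
#'
#' @param coords cone centers (px), e.g. from [generate_mosaic()].
#' @param resp a [response_spec()].
#' @param frame_rate frames per second (default 29.4).
#' @param duration recording length, s (default 6).
#' @param dim_px frame size `c(H, W)`; defaults to the `dim_px` attribute
#'   of `coords`.
#' @param amplitudes per-cone ground-truth amplitudes; drawn from `resp`
#'   when omitted.
#' @param base_peak baseline peak intensity of each cone profile.
#' @param fwhm_fraction cone FWHM as a fraction of median spacing.
#' @param motion_sd per-frame residual translation SD, px (0 disables).
#' @param seed RNG seed (defaults to `resp$seed`).
#' @return list with elements `stack` (a [frame_stack()]) and `manifest`
#'   (cone positions, true amplitudes, excluded frames, applied per-frame
#'   affine transforms, column radius).
#' @export
render_acquisition <- function(coords, resp, frame_rate = 29.4, duration = 6,
                               dim_px = attr(coords, "dim_px"),
                               amplitudes = NULL, base_peak = 120,
                               fwhm_fraction = 0.6, motion_sd = 0,
                               seed = resp$seed) {
  coords <- as_coords(coords)
  if (is.null(dim_px)) stop("frame dimensions dim_px are required")
  tb <- sim_timebase(frame_rate, duration, resp$stimulus_time)
  if (any(coords[, 1L] < 1 | coords[, 1L] > dim_px[2L] |
          coords[, 2L] < 1 | coords[, 2L] > dim_px[1L])) {
    stop("out of bounds: all cones must lie within the frame")
  }
  nc <- nrow(coords)
  d <- median_nn_spacing(coords)
  sigma <- fwhm_fraction * d / (2 * sqrt(2 * log(2)))
  trunc_r <- 0.5 * d
  col_radius <- max(1, 0.5 * d * fwhm_fraction)

  # Static per-cone profile patches and column weights.
  patches <- vector("list", nc)
  w <- numeric(nc)
  for (c in seq_len(nc)) {
    px <- disc_pixels(coords[c, ], trunc_r, dim_px)
    g <- exp(-((px[, "x"] - coords[c, 1L])^2 +
               (px[, "y"] - coords[c, 2L])^2) / (2 * sigma^2))
    patches[[c]] <- list(idx = (px[, "x"] - 1L) * dim_px[1L] + px[, "y"], g = g)
    col <- disc_pixels(coords[c, ], col_radius, dim_px)
    if (!nrow(col)) stop("column radius too small for the pixel grid")
    w[c] <- mean(exp(-((col[, "x"] - coords[c, 1L])^2 +
                       (col[, "y"] - coords[c, 2L])^2) / (2 * sigma^2)))
  }

  with_seed(seed, {
    if (is.null(amplitudes)) amplitudes <- draw_amplitudes(nc, resp, seed = NULL)
    stopifnot(length(amplitudes) == nc)
    sim <- sim_deviations(amplitudes, resp, tb)
    shifts <- matrix(0, tb$n, 2L)
    if (motion_sd > 0) shifts <- matrix(stats::rnorm(tb$n * 2L, 0, motion_sd), tb$n, 2L)

    base <- matrix(0, dim_px[1L], dim_px[2L])
    if (motion_sd == 0) {
      for (c in seq_len(nc)) {
        base[patches[[c]]$idx] <- base[patches[[c]]$idx] + base_peak * patches[[c]]$g
      }
    }
    frames <- array(0, dim = c(dim_px[1L], dim_px[2L], tb$n))
    for (t in seq_len(tb$n)) {
      if (motion_sd == 0) {
        f <- base
        for (c in seq_len(nc)) {
          dv <- sim$dev[c, t]
          if (dv != 0) {
            p <- patches[[c]]
            f[p$idx] <- f[p$idx] + (dv / w[c]) * p$g
          }
        }
      } else {
        f <- matrix(0, dim_px[1L], dim_px[2L])
        for (c in seq_len(nc)) {
          ctr <- coords[c, ] + shifts[t, ]
          px <- disc_pixels(ctr, trunc_r, dim_px)
          if (!nrow(px)) next
          g <- exp(-((px[, "x"] - ctr[1L])^2 + (px[, "y"] - ctr[2L])^2) / (2 * sigma^2))
          idx <- (px[, "x"] - 1L) * dim_px[1L] + px[, "y"]
          f[idx] <- f[idx] + (base_peak + sim$dev[c, t] / w[c]) * g
        }
      }
      frames[, , t] <- f
    }

    valid <- rep(TRUE, tb$n)
    valid[sim$dropped] <- FALSE
    stack <- frame_stack(frames, frame_rate, tb$stimulus_frame, valid = valid)
    affine <- lapply(seq_len(tb$n), function(t) {
      cbind(diag(2), shifts[t, ])
    })
    manifest <- list(cone_positions = coords,
                     cone_true_amplitude = amplitudes,
                     excluded_frames = sim$dropped,
                     applied_affine = affine,
                     column_radius_px = col_radius,
                     fwhm_fraction = fwhm_fraction)
    list(stack = stack, manifest = manifest)
  })
}

#' Simulate cone signal tables directly
#'
#' Signal-level counterpart of [render_acquisition()]: produces the
#' cone-by-frame reflectance tables that column extraction would yield
#' (baseline plus deviations), without rendering pixels. Used for
#' cohort-scale statistical simulations where the pixel round trip —
#' validated separately — would only add cost.
#'
#' @param amplitudes per-cone ground-truth amplitudes.
#' @param resp a [response_spec()].
#' @param n_acquisitions acquisitions in the trial.
#' @param frame_rate,duration timebase (defaults 29.4 Hz, 6 s).
#' @param baseline per-cone baseline reflectance (recycled).
#' @param seed RNG seed.
#' @return list of [cone_signal_table()] objects, one per acquisition,
#'   with the amplitudes attached as attribute `true_amplitudes`.
#' @export
simulate_trial_signals <- function(amplitudes, resp, n_acquisitions = 10,
                                   frame_rate = 29.4, duration = 6,
                                   baseline = 70, seed = resp$seed) {
  tb <- sim_timebase(frame_rate, duration, resp$stimulus_time)
  nc <- length(amplitudes)
  base <- rep_len(baseline, nc)
  out <- with_seed(seed, {
    lapply(seq_len(n_acquisitions), function(a) {
      sim <- sim_deviations(amplitudes, resp, tb)
      missing <- matrix(FALSE, nc, tb$n)
      missing[, sim$dropped] <- TRUE
      cone_signal_table(base + sim$dev, missing = missing,
                        frame_rate = frame_rate,
                        stimulus_frame = tb$stimulus_frame)
    })
  })
  attr(out, "true_amplitudes") <- amplitudes
  out
}

#' Generate a synthetic cohort on disk
#'
#' For each subject and eccentricity, writes one control trial (no
#' stimulus response) and `n_stim_trials` stimulus trials of
#' `n_acquisitions` acquisitions each, as 16-bit multi-frame TIFFs with a
#' coordinate CSV and a JSON ground-truth manifest per location, plus a
#' cohort-level manifest. Mean log amplitude declines with eccentricity at
#' `ecc_slope_log10` decades per degree (relative to 1 degree).
#'
#' @param control_spec list with elements `mosaic` ([mosaic_spec()]) and
#'   `response` ([response_spec()]) for the control arm.
#' @param disease_spec same structure for the disease arm, or `NULL` for a
#'   single-arm cohort.
#' @param eccentricities retinal eccentricities, degrees.
#' @param n_subjects subjects per arm.
#' @param seed master RNG seed.
#' @param out_dir output directory (created).
#' @param n_stim_trials,n_acquisitions trial structure (defaults 3 and 10).
#' @param frame_rate,duration acquisition timebase.
#' @param ecc_slope_log10 eccentricity slope of mean log10 amplitude.
#' @return invisibly, the cohort manifest (also written as
#'   `cohort_manifest.json`).
#' @export
generate_cohort <- function(control_spec, disease_spec = NULL,
                            eccentricities = c(1, 4), n_subjects = 2,
                            seed = 1, out_dir,
                            n_stim_trials = 3, n_acquisitions = 10,
                            frame_rate = 29.4, duration = 6,
                            ecc_slope_log10 = -0.017) {
  stopifnot(n_subjects >= 1)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  arms <- list(control = control_spec)
  if (!is.null(disease_spec)) arms$disease <- disease_spec
  manifest <- list(seed = seed, eccentricities = eccentricities,
                   n_subjects = n_subjects, n_stim_trials = n_stim_trials,
                   n_acquisitions = n_acquisitions,
                   frame_rate = frame_rate, duration = duration,
                   arms = names(arms), locations = list())
  li <- 0L
  for (arm in names(arms)) {
    spec <- arms[[arm]]
    for (s in seq_len(n_subjects)) {
      subj <- sprintf("%s_%02d", arm, s)
      for (ecc in eccentricities) {
        li <- li + 1L
        loc_seed <- child_seed(seed, li * 1000L)
        mspec <- spec$mosaic
        mspec$seed <- child_seed(loc_seed, 1L)
        coords <- generate_mosaic(mspec)
        resp <- spec$response
        resp$mean_log_amplitude <- resp$mean_log_amplitude +
          ecc_slope_log10 * (ecc - 1)
        amps <- draw_amplitudes(nrow(coords), resp,
                                seed = child_seed(loc_seed, 2L))
        loc_dir <- file.path(out_dir, subj, sprintf("ecc_%g", ecc))
        dir.create(loc_dir, recursive = TRUE, showWarnings = FALSE)
        write_cone_coords(coords, file.path(loc_dir, "cone_coords.csv"))
        trials <- character(0)
        for (tr in 0:n_stim_trials) {        # trial 0 = control (no stimulus)
          trial_amps <- if (tr == 0) rep(0, nrow(coords)) else amps
          tdir <- file.path(loc_dir, sprintf("trial_%d", tr))
          dir.create(tdir, showWarnings = FALSE)
          for (a in seq_len(n_acquisitions)) {
            acq <- render_acquisition(coords, resp, frame_rate, duration,
                                      amplitudes = trial_amps,
                                      seed = child_seed(loc_seed, 10L + tr * 100L + a))
            write_frame_stack(acq$stack,
                              file.path(tdir, sprintf("acq_%02d.tif", a)))
          }
          trials <- c(trials, basename(tdir))
        }
        loc_manifest <- list(arm = arm, subject = subj, eccentricity = ecc,
                             n_cones = nrow(coords),
                             true_amplitudes = amps,
                             mean_log_amplitude = resp$mean_log_amplitude,
                             trials = trials,
                             stimulus_frame = sim_timebase(frame_rate, duration,
                                                           resp$stimulus_time)$stimulus_frame)
        jsonlite::write_json(loc_manifest,
                             file.path(loc_dir, "manifest.json"),
                             auto_unbox = TRUE, digits = NA)
        manifest$locations[[li]] <- list(arm = arm, subject = subj,
                                         eccentricity = ecc,
                                         path = file.path(subj, sprintf("ecc_%g", ecc)))
      }
    }
  }
  jsonlite::write_json(manifest, file.path(out_dir, "cohort_manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
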
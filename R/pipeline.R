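#' Default pipeline configuration
#'
#' A complete run configuration for an end-to-end synthetic experiment:
#' simulate a two-arm cohort, extract per-cone signals, summarize RMS
#' amplitudes and healthy-cone fractions, compute mosaic metrics, and
#' write a statistics report. Any element can be overridden via a YAML or
#' JSON config file ([read_run_config()]). The defaults are scaled for a
#' demonstration run (small field, short acquisitions); study-scale
#' parameters (6 s at 29.4 Hz, trials of 10) are set by raising
#' `duration`, `n_acquisitions` and `n_stim_trials`.
#'
#' @return nested configuration list.
#' @export
default_config <- function() {
  list(
    seed = 1,
    n_subjects = 2,
    eccentricities = c(1, 4),
    frame_rate = 29.4,
    duration = 4,
    n_stim_trials = 2,
    n_acquisitions = 3,
    amplitude_window = 1,
    standardize = FALSE,
    refine = FALSE,
    fwhm_fraction = 0.6,
    ecc_slope_log10 = -0.017,
    mosaic = list(spacing = 5, jitter_sd = 0.3, field_size = 0.12,
                  pixels_per_degree = 600, retinal_magnification = 291),
    control_response = list(mean_log_amplitude = 1.5, sd_log_amplitude = 0.35,
                            nonresponder_fraction = 0.05, noise_sd = 5,
                            dropout_fraction = 0, stimulus_time = 2,
                            response_duration = 1),
    disease_response = list(mean_log_amplitude = 1.5 - log10(2),
                            sd_log_amplitude = 0.35,
                            nonresponder_fraction = 0.05, noise_sd = 5,
                            dropout_fraction = 0, stimulus_time = 2,
                            response_duration = 1),
    photometry = list(corneal_power_density = 17.6, wavelength_nm = 554,
                      stimulus_duration = 0.066, stimulus_area = 1.13,
                      retinal_magnification = 291,
                      lens_transmission = 0.78, macular_transmission = 0.8)
  )
}

# Recursively merge user values over defaults.
merge_config <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(base[[nm]]) && is.list(user[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], user[[nm]])
    } else {
      base[[nm]] <- user[[nm]]
    }
  }
  base
}

#' Read a run configuration
#'
#' Reads a YAML or JSON configuration file and merges it over
#' [default_config()]; unknown keys are kept (and echoed into the run
#' manifest).
#'
#' @param path `.yaml`/`.yml` or `.json` file, or `NULL` for defaults.
#' @return configuration list.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  merge_config(cfg, user)
}

# Process one location: render/extract/summarize all stimulus trials.
# Returns location-level summaries plus per-cone log amplitudes.
process_location <- function(coords, resp, cfg, loc_seed) {
  amps <- draw_amplitudes(nrow(coords), resp, seed = child_seed(loc_seed, 2L))
  radius <- compute_column_radius(coords, cfg$fwhm_fraction)
  pop_amp_trials <- numeric(0)
  indiv_amp_trials <- list()
  trace <- NULL
  for (tr in seq_len(cfg$n_stim_trials)) {
    tables <- vector("list", cfg$n_acquisitions)
    pop_amps <- numeric(cfg$n_acquisitions)
    for (a in seq_len(cfg$n_acquisitions)) {
      acq <- render_acquisition(coords, resp, cfg$frame_rate, cfg$duration,
                                amplitudes = amps,
                                seed = child_seed(loc_seed, 10L + tr * 100L + a))
      stack <- acq$stack
      if (isTRUE(cfg$standardize)) stack <- standardize_frames(stack)
      use_coords <- coords
      if (isTRUE(cfg$refine)) {
        avg <- apply(stack$frames[, , stack$valid, drop = FALSE], c(1, 2), mean)
        use_coords <- refine_coordinates(avg, coords, max_radius = 2)
      }
      tab <- extract_cone_signals(stack, use_coords, radius)
      tab <- apply_exclusion(tab, n_acquisitions_total = 1L)
      tab <- subtract_prestim_mean(tab)
      tables[[a]] <- tab
      ptr <- population_rms(tab)
      pop_amps[a] <- extract_amplitude(ptr, cfg$amplitude_window)$amplitude
      if (is.null(trace)) trace <- ptr
    }
    pop_amp_trials <- c(pop_amp_trials, mean(pop_amps))
    present <- table(unlist(lapply(tables, function(t) t$cone_ids)))
    ids <- as.integer(names(present))[present >= cfg$n_acquisitions / 2]
    indiv <- vapply(ids, function(id) {
      extract_amplitude(individual_rms(tables, id), cfg$amplitude_window)$amplitude
    }, numeric(1L))
    indiv_amp_trials[[tr]] <- stats::setNames(indiv, ids)
  }
  all_ids <- sort(unique(unlist(lapply(indiv_amp_trials, names))))
  indiv_amp <- vapply(all_ids, function(id) {
    mean(unlist(lapply(indiv_amp_trials, function(v) v[id])), na.rm = TRUE)
  }, numeric(1L))
  # tiny demo fields can lack bound cones; record NA rather than fail
  nnd <- tryCatch(bound_nnd(coords, scale = attr(coords, "um_per_px")),
                  error = function(e) list(mean_bound_nnd = NA_real_,
                                           n_bound_cones = 0L))
  list(pop_amplitude = mean(pop_amp_trials),
       indiv_amplitudes = indiv_amp,
       log_amplitudes = suppressMessages(log_transform(indiv_amp)),
       mean_nnd_um = nnd$mean_bound_nnd,
       n_bound = nnd$n_bound_cones,
       n_cones = nrow(coords),
       trace = trace)
}

#' Run the full synthetic iORG pipeline
#'
#' Simulates a control arm and (optionally) a disease arm, extracts and
#' summarizes iORG responses per subject and eccentricity, computes
#' mosaic metrics and healthy-cone fractions against the control
#' normative distribution, fits location-level structure-function
#' regressions, and writes all artifacts under `out_dir`:
#' per-location RMS trace CSVs, amplitude CSVs, CDF CSVs, a metrics CSV,
#' a statistics report JSON and a provenance manifest JSON.
#'
#' @param config configuration list (see [default_config()]).
#' @param out_dir output directory (created).
#' @return invisibly, the metrics data.frame.
#' @export
run_pipeline <- function(config = default_config(), out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "traces"), showWarnings = FALSE)
  dir.create(file.path(out_dir, "amplitudes"), showWarnings = FALSE)
  dir.create(file.path(out_dir, "cdf"), showWarnings = FALSE)
  cfg <- config
  arms <- list(control = cfg$control_response)
  if (!is.null(cfg$disease_response)) arms$disease <- cfg$disease_response
  rows <- list(); log_amps <- list()
  li <- 0L
  for (arm in names(arms)) {
    for (s in seq_len(cfg$n_subjects)) {
      for (ecc in cfg$eccentricities) {
        li <- li + 1L
        loc_seed <- child_seed(cfg$seed, li * 1000L)
        mspec <- do.call(mosaic_spec,
                         c(cfg$mosaic, list(seed = child_seed(loc_seed, 1L))))
        coords <- generate_mosaic(mspec)
        resp <- do.call(response_spec, arms[[arm]])
        resp$mean_log_amplitude <- resp$mean_log_amplitude +
          cfg$ecc_slope_log10 * (ecc - 1)
        res <- process_location(coords, resp, cfg, loc_seed)
        loc <- sprintf("%s_%02d_ecc%g", arm, s, ecc)
        write_rms_trace(res$trace, file.path(out_dir, "traces",
                                             paste0(loc, ".csv")))
        write_amplitudes(names(res$indiv_amplitudes), res$indiv_amplitudes,
                         file.path(out_dir, "amplitudes", paste0(loc, ".csv")))
        cdf <- amplitude_cdf(res$log_amplitudes)
        xs <- sort(res$log_amplitudes[!is.na(res$log_amplitudes)])
        utils::write.csv(data.frame(log_amplitude = xs, cumulative_prob = cdf(xs)),
                         file.path(out_dir, "cdf", paste0(loc, ".csv")),
                         row.names = FALSE)
        rows[[li]] <- data.frame(arm = arm, subject = s, eccentricity = ecc,
                                 n_cones = res$n_cones, n_bound = res$n_bound,
                                 mean_nnd_um = res$mean_nnd_um,
                                 pop_amplitude = res$pop_amplitude)
        log_amps[[li]] <- res$log_amplitudes
      }
    }
  }
  metrics <- do.call(rbind, rows)
  ctl <- metrics$arm == "control"
  normative <- normative_distribution(unlist(log_amps[ctl]))
  metrics$healthy_fraction <- vapply(seq_len(nrow(metrics)), function(i) {
    healthy_fraction(log_amps[[i]], normative)
  }, numeric(1L))
  utils::write.csv(metrics, file.path(out_dir, "metrics.csv"), row.names = FALSE)

  reg <- tryCatch(
    linear_fit_with_pi(metrics$mean_nnd_um[ctl], metrics$pop_amplitude[ctl]),
    error = function(e) NULL)
  report <- list(
    normative_p5_log_amplitude = normative$p5_threshold,
    arm_mean_pop_amplitude = as.list(tapply(metrics$pop_amplitude, metrics$arm, mean)),
    arm_mean_healthy_fraction = as.list(tapply(metrics$healthy_fraction, metrics$arm, mean)),
    control_amplitude_vs_nnd = if (is.null(reg)) NULL else
      list(slope = reg$slope, intercept = reg$intercept,
           r_squared = reg$r_squared, p_value = reg$p_value),
    photon_density_um2 = as.numeric(
      photon_density(do.call(photometry_params, cfg$photometry)))
  )
  jsonlite::write_json(report, file.path(out_dir, "stats_report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)

  cfg_path <- file.path(out_dir, "config.json")
  jsonlite::write_json(cfg, cfg_path, auto_unbox = TRUE, digits = NA)
  manifest <- list(config_md5 = unname(tools::md5sum(cfg_path)),
                   seed = cfg$seed,
                   package_version = as.character(utils::packageVersion("iorgtools")),
                   artifacts = c("traces", "amplitudes", "cdf", "metrics.csv",
                                 "stats_report.json", "config.json"))
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(metrics)
}
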
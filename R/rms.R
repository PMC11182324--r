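#' Frame-wise RMS trace
#'
#' @param values per-frame RMS (NA where no terms contributed).
#' @param time per-frame timestamps, s.
#' @param stimulus_frame 1-based stimulus frame index.
#' @param n_contributing per-frame count of non-missing terms.
#' @param kind `"population"` or `"individual"`.
#' @return object of class `rms_trace`.
#' @export
rms_trace <- function(values, time, stimulus_frame, n_contributing, kind) {
  stopifnot(length(values) == length(time),
            length(n_contributing) == length(values))
  kind <- match.arg(kind, c("population", "individual"))
  if (any(values < 0, na.rm = TRUE)) stop("RMS values cannot be negative")
  structure(list(values = values, time = time,
                 stimulus_frame = as.integer(stimulus_frame),
                 n_contributing = n_contributing, kind = kind),
            class = "rms_trace")
}

#' @export
print.rms_trace <- function(x, ...) {
  cat(sprintf("<rms_trace> %s, %d frames, stimulus frame %d\n",
              x$kind, length(x$values), x$stimulus_frame))
  invisible(x)
}

#' Population RMS of one acquisition
#'
#' Frame-wise root mean square over cones of the mean-subtracted
#' reflectances: `RMS_pop[t] = sqrt(mean_c R_c[t]^2)` over the cones
#' non-missing at frame `t`. Frames with no contributing cones are `NA`.
#'
#' @param table a mean-subtracted [cone_signal_table()].
#' @return an [rms_trace()] of kind `"population"`.
#' @export
population_rms <- function(table) {
  stopifnot(inherits(table, "cone_signal_table"))
  if (nrow(table$signal) < 1L) stop("population RMS of an empty table")
  n_t <- colSums(!table$missing)
  vals <- sqrt(colMeans(table$signal^2, na.rm = TRUE))
  vals[n_t == 0L] <- NA_real_
  rms_trace(vals, table$time, table$stimulus_frame, n_t, "population")
}

#' Individual RMS of one cone across acquisitions
#'
#' Frame-wise RMS of a single cone's mean-subtracted reflectance across
#' the acquisitions in which it was retained:
#' `RMS_indiv[t] = sqrt(mean_a R_a[t]^2)`.
#'
#' @param acquisitions list of mean-subtracted [cone_signal_table()]s
#'   (one per acquisition; frame grids must agree).
#' @param cone_id the cone to summarize.
#' @return an [rms_trace()] of kind `"individual"`.
#' @export
individual_rms <- function(acquisitions, cone_id) {
  rows <- lapply(acquisitions, function(tab) {
    i <- match(cone_id, tab$cone_ids)
    if (is.na(i)) return(NULL)
    tab$signal[i, ]
  })
  rows <- rows[!vapply(rows, is.null, logical(1L))]
  if (!length(rows)) stop("cone ", cone_id, " absent from every acquisition")
  m <- do.call(rbind, rows)
  tb <- acquisitions[[1L]]
  n_t <- colSums(!is.na(m))
  vals <- sqrt(colMeans(m^2, na.rm = TRUE))
  vals[n_t == 0L] <- NA_real_
  rms_trace(vals, tb$time, tb$stimulus_frame, n_t, "individual")
}

#' iORG response amplitude of an RMS trace
#'
#' Amplitude is the 99th percentile of the RMS within one second after
#' stimulus delivery minus the mean RMS within one second before it.
#' Percentiles interpolate linearly between order statistics; missing
#' frames are dropped from both windows.
#'
#' @param trace an [rms_trace()].
#' @param window window length on each side of the stimulus, s.
#' @return list of class `amplitude_record` with `prestim_mean`,
#'   `poststim_p99`, `amplitude` and `log_amplitude` (base 10; `NA`
#'   unless the amplitude is positive).
#' @export
extract_amplitude <- function(trace, window = 1) {
  stopifnot(inherits(trace, "rms_trace"), window > 0)
  t_s <- trace$time[trace$stimulus_frame]
  pre <- trace$values[trace$time >= t_s - window & trace$time < t_s]
  post <- trace$values[trace$time > t_s & trace$time <= t_s + window]
  pre <- pre[!is.na(pre)]; post <- post[!is.na(post)]
  if (length(pre) < 2L || length(post) < 2L) {
    stop("amplitude windows need at least 2 non-missing frames each")
  }
  p99 <- unname(stats::quantile(post, 0.99, type = 7))
  amp <- p99 - mean(pre)
  structure(list(prestim_mean = mean(pre), poststim_p99 = p99,
                 amplitude = amp,
                 log_amplitude = if (amp > 0) log10(amp) else NA_real_),
            class = "amplitude_record")
}

#' @export
print.amplitude_record <- function(x, ...) {
  cat(sprintf("<amplitude_record> amplitude %.3f AU (pre %.3f, post p99 %.3f)\n",
              x$amplitude, x$prestim_mean, x$poststim_p99))
  invisible(x)
}

#' Log-transform amplitudes
#'
#' Base-10 logarithm of positive amplitudes. Non-positive amplitudes
#' (possible when the post-stimulus RMS falls below the pre-stimulus
#' mean) are flagged `NA` and reported via a message; they are excluded
#' from distributional summaries.
#'
#' @param amplitude numeric vector of amplitudes (AU).
#' @return log10 amplitudes with `NA` for non-positive inputs.
#' @export
log_transform <- function(amplitude) {
  bad <- !(amplitude > 0)
  if (any(bad, na.rm = TRUE)) {
    message(sum(bad, na.rm = TRUE), " non-positive amplitude(s) flagged NA")
  }
  out <- rep(NA_real_, length(amplitude))
  out[!bad & !is.na(amplitude)] <- log10(amplitude[!bad & !is.na(amplitude)])
  out
}

#' Empirical CDF of log amplitudes
#'
#' Right-continuous empirical cumulative distribution (step 1/n at each
#' order statistic), the summary used to compare individual-cone
#' response distributions across locations and cohorts.
#'
#' @param log_amplitudes sample of log10 amplitudes (`NA` dropped).
#' @return a function of class `ecdf`.
#' @export
amplitude_cdf <- function(log_amplitudes) {
  x <- log_amplitudes[!is.na(log_amplitudes)]
  if (!length(x)) stop("empty amplitude sample")
  stats::ecdf(x)
}

#' Normative amplitude distribution and 5th-percentile threshold
#'
#' Stores a control sample of log amplitudes and its 5th percentile. The
#' threshold choice reflects the expected share of S cones, which the
#' 554 nm stimulus leaves essentially unstimulated: in a fully healthy
#' mosaic ~95% of cones should exceed it.
#'
#' @param log_amplitudes control-cone log10 amplitudes (`NA` dropped).
#' @param probs threshold percentile (default 0.05).
#' @return list of class `normative_distribution` with sorted
#'   `log_amplitudes` and `p5_threshold`.
#' @export
normative_distribution <- function(log_amplitudes, probs = 0.05) {
  x <- sort(log_amplitudes[!is.na(log_amplitudes)])
  if (!length(x)) stop("empty normative sample")
  structure(list(log_amplitudes = x,
                 p5_threshold = unname(stats::quantile(x, probs, type = 7))),
            class = "normative_distribution")
}

#' Fraction of putatively healthy cones
#'
#' Fraction of a sample of log amplitudes at or above the normative
#' 5th-percentile threshold. `NA` log amplitudes (non-positive
#' amplitudes) count as below threshold: a cone without a measurable
#' response is not healthy by this criterion.
#'
#' @param log_amplitudes sample of log10 amplitudes.
#' @param normative a [normative_distribution()].
#' @return fraction in `[0, 1]`.
#' @export
healthy_fraction <- function(log_amplitudes, normative) {
  stopifnot(inherits(normative, "normative_distribution"))
  if (!length(log_amplitudes)) stop("empty amplitude sample")
  mean(!is.na(log_amplitudes) & log_amplitudes >= normative$p5_threshold)
}

#' Write an RMS trace / amplitude records to CSV
#'
#' @param trace an [rms_trace()].
#' @param path output CSV.
#' @export
write_rms_trace <- function(trace, path) {
  utils::write.csv(data.frame(time_s = trace$time, rms_au = trace$values,
                              n_contributing = trace$n_contributing),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_rms_trace
#' @param cone_ids,amplitudes parallel vectors of cone ids and amplitudes.
#' @export
write_amplitudes <- function(cone_ids, amplitudes, path) {
  utils::write.csv(data.frame(cone_id = cone_ids, amplitude_au = amplitudes,
                              log_amplitude = suppressMessages(log_transform(amplitudes))),
                   path, row.names = FALSE)
  invisible(path)
}
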
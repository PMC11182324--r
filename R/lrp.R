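# Discrete Gaussian smoothing of a vector (kernel SD in samples).
gauss_smooth <- function(y, sd_samples) {
  if (sd_samples <= 0) return(y)
  r <- max(1L, ceiling(3 * sd_samples))
  k <- stats::dnorm(-r:r, sd = sd_samples)
  k <- k / sum(k)
  n <- length(y)
  ypad <- c(rep(y[1L], r), y, rep(y[n], r))
  stats::convolve(ypad, rev(k), type = "filter")
}

# Prominence of each local maximum: height above the higher of the two
# minima separating it from higher terrain (or the series edge).
peak_prominence <- function(y, peaks) {
  vapply(peaks, function(p) {
    left <- y[seq_len(p)]
    higher_l <- which(left > y[p])
    base_l <- if (length(higher_l)) min(left[max(higher_l):p]) else min(left)
    right <- y[p:length(y)]
    higher_r <- which(right > y[p])
    base_r <- if (length(higher_r)) min(right[1L:min(higher_r)]) else min(right)
    y[p] - max(base_l, base_r)
  }, numeric(1L))
}

#' Outer-segment length from a longitudinal reflectance profile
#'
#' Detects the two most prominent reflectance peaks — the ellipsoid zone
#' (EZ, shallower) and interdigitation zone (IZ, deeper) bands — within a
#' depth window and returns their separation, the cone outer-segment
#' length. The profile is optionally Gaussian-smoothed; peak locations
#' are refined to sub-sample precision by parabolic interpolation.
#' Detection is invariant to reflectance gain and offset, and to the
#' depth axis orientation.
#'
#' @param lrp data.frame with `depth_um` (strictly monotone) and
#'   `reflectance`.
#' @param search_window optional depth window `c(min, max)`, um.
#' @param smooth_sd Gaussian smoothing SD in samples (default 2; 0
#'   disables). The default trades a negligible separation bias for a
#'   roughly halved noise-induced error on band-width-scale peaks.
#' @param min_prominence minimum peak prominence as a fraction of the
#'   profile range (default 0.1).
#' @param qc_range plausible outer-segment lengths, um; results outside
#'   carry attribute `qc_flag = TRUE`.
#' @return outer-segment length, um, with attributes `ez_um`, `iz_um`,
#'   `qc_flag`.
#' @export
detect_os_length <- function(lrp, search_window = NULL, smooth_sd = 2,
                             min_prominence = 0.1,
                             qc_range = c(12.8, 38.4)) {
  depth <- lrp$depth_um
  refl <- lrp$reflectance
  if (length(depth) < 5L) stop("profile too short")
  dd <- diff(depth)
  if (all(dd < 0)) {                       # orientation-normalize
    depth <- rev(depth); refl <- rev(refl); dd <- diff(depth)
  }
  if (any(dd <= 0)) stop("depth grid must be strictly monotone")
  y <- gauss_smooth(refl, smooth_sd)
  n <- length(y)
  if (diff(range(y)) <= 1e-12 * max(abs(y), 1)) {
    stop("no peaks: profile is constant")
  }
  in_win <- if (is.null(search_window)) rep(TRUE, n) else {
    depth >= min(search_window) & depth <= max(search_window)
  }
  cand <- which(y > c(-Inf, y[-n]) & y >= c(y[-1L], -Inf))  # local maxima
  cand <- cand[cand > 1L & cand < n & in_win[cand]]
  if (length(cand)) {
    prom <- peak_prominence(y, cand)
    keep <- prom >= min_prominence * diff(range(y))
    cand <- cand[keep]; prom <- prom[keep]
  }
  if (length(cand) < 2L) stop("no peaks: fewer than 2 prominent maxima in the window")
  top2 <- sort(cand[order(-prom)][1:2])
  if (diff(top2) < 2L) stop("unresolvable: peaks closer than 2 depth samples")
  refine <- function(p) {
    if (p <= 1L || p >= n) return(depth[p])
    den <- y[p - 1L] - 2 * y[p] + y[p + 1L]
    if (den >= 0) return(depth[p])
    frac <- 0.5 * (y[p - 1L] - y[p + 1L]) / den
    step <- if (p < n) depth[p + 1L] - depth[p] else depth[p] - depth[p - 1L]
    depth[p] + frac * step
  }
  ez <- refine(top2[1L]); iz <- refine(top2[2L])
  os <- iz - ez
  structure(os, ez_um = ez, iz_um = iz,
            qc_flag = os < qc_range[1L] || os > qc_range[2L])
}

#' Measure OS length for a set of profiles
#'
#' @param lrps named list of LRP data.frames (names = eccentricity labels).
#' @param ... passed to [detect_os_length()].
#' @return data.frame with `eccentricity`, `os_length_um`, `qc_flag`.
#' @export
os_length_table <- function(lrps, ...) {
  res <- lapply(lrps, detect_os_length, ...)
  data.frame(eccentricity = names(lrps),
             os_length_um = vapply(res, as.numeric, numeric(1L)),
             qc_flag = vapply(res, attr, logical(1L), "qc_flag"),
             row.names = NULL)
}
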
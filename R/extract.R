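#' Cone-by-frame reflectance signals
#'
#' The central container of the extraction stage: one row per cone, one
#' column per frame, plus a congruent missing-data mask (frames lost to
#' registration, or columns with no image content). Missing entries are
#' `NA` in `signal`.
#'
#' @param signal numeric matrix, cones x frames.
#' @param missing logical matrix of the same shape.
#' @param frame_rate frames per second.
#' @param stimulus_frame 1-based stimulus frame index.
#' @param cone_ids identifiers, default `1:n`.
#' @return object of class `cone_signal_table`.
#' @export
cone_signal_table <- function(signal, missing = NULL, frame_rate,
                              stimulus_frame, cone_ids = NULL) {
  signal <- as.matrix(signal)
  if (is.null(missing)) missing <- is.na(signal)
  missing <- missing | is.na(signal)
  if (!identical(dim(missing), dim(signal))) {
    stop("signal and missing must have congruent shapes")
  }
  signal[missing] <- NA_real_
  if (is.null(cone_ids)) cone_ids <- seq_len(nrow(signal))
  if (length(cone_ids) != nrow(signal)) stop("one id per cone required")
  stimulus_frame <- as.integer(stimulus_frame)
  if (stimulus_frame < 1L || stimulus_frame > ncol(signal)) {
    stop("stimulus_frame out of range")
  }
  structure(list(signal = signal, missing = missing,
                 cone_ids = cone_ids,
                 frame_rate = as.numeric(frame_rate),
                 stimulus_frame = stimulus_frame,
                 time = (seq_len(ncol(signal)) - 1) / frame_rate),
            class = "cone_signal_table")
}

#' @export
print.cone_signal_table <- function(x, ...) {
  cat(sprintf("<cone_signal_table> %d cones x %d frames, %.2f Hz, stimulus frame %d, %.1f%% missing\n",
              nrow(x$signal), ncol(x$signal), x$frame_rate, x$stimulus_frame,
              100 * mean(x$missing)))
  invisible(x)
}

#' Standardize the image-containing region of each frame
#'
#' Each frame's image-containing pixels are z-scored and rescaled to a
#' target mean and SD (defaults 70 and 35, typical of raw AOSLO frames),
#' removing frame-to-frame global intensity swings so that acquisitions
#' and participants are comparable. Pixels outside the image region are
#' untouched. Frames whose region has fewer than 2 pixels or zero variance
#' are flagged invalid.
#'
#' @param stack a [frame_stack()].
#' @param target_mean,target_sd target frame statistics.
#' @return a standardized `frame_stack`.
#' @export
standardize_frames <- function(stack, target_mean = 70, target_sd = 35) {
  stopifnot(inherits(stack, "frame_stack"), target_sd > 0)
  nt <- dim(stack$frames)[3L]
  frames <- stack$frames
  valid <- stack$valid
  for (t in seq_len(nt)) {
    reg <- frame_region(stack, t)
    v <- frames[, , t][reg]
    if (length(v) < 2L || stats::sd(v) == 0) {
      valid[t] <- FALSE
      next
    }
    f <- frames[, , t]
    f[reg] <- (v - mean(v)) / stats::sd(v) * target_sd + target_mean
    frames[, , t] <- f
  }
  frame_stack(frames, stack$frame_rate, stack$stimulus_frame,
              valid = valid, image_region = stack$image_region)
}

#' Refine cone coordinates by hill climbing
#'
#' Moves each coordinate uphill on the average image by greedy
#' 8-connected ascent (ties broken by first-found in row-major order over
#' the neighborhood), stopping at a local maximum, after `max_steps`
#' steps, or when the next step would exceed `max_radius` from the start.
#' Compensates for small residual inter-acquisition registration offsets.
#'
#' @param avg_image 2-D numeric matrix (acquisition average image).
#' @param coords cone centers (px).
#' @param max_radius maximum allowed displacement, px.
#' @param max_steps cap on uphill steps (default 10).
#' @return refined coordinate matrix (integer pixel positions).
#' @export
refine_coordinates <- function(avg_image, coords, max_radius = 2, max_steps = 10) {
  stopifnot(max_radius >= 1)
  coords <- as_coords(coords)
  H <- nrow(avg_image); W <- ncol(avg_image)
  # row-major order over the 3x3 neighborhood: (dy, dx) from top-left
  nb <- cbind(dx = c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L),
              dy = c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L))
  nb <- nb[order(nb[, "dy"], nb[, "dx"]), , drop = FALSE]
  out <- coords
  for (i in seq_len(nrow(coords))) {
    x0 <- round(coords[i, 1L]); y0 <- round(coords[i, 2L])
    x <- min(max(x0, 1L), W); y <- min(max(y0, 1L), H)
    for (step in seq_len(max_steps)) {
      best_v <- avg_image[y, x]; best <- NULL
      for (k in seq_len(nrow(nb))) {
        xn <- x + nb[k, "dx"]; yn <- y + nb[k, "dy"]
        if (xn < 1L || xn > W || yn < 1L || yn > H) next
        if ((xn - x0)^2 + (yn - y0)^2 > max_radius^2) next
        if (avg_image[yn, xn] > best_v) {      # strict: plateaus stay put
          best_v <- avg_image[yn, xn]; best <- c(xn, yn)
        }
      }
      if (is.null(best)) break
      x <- best[1L]; y <- best[2L]
    }
    out[i, ] <- c(x, y)
  }
  out
}

#' Column radius from mosaic spacing
#'
#' The sampling column's radius is half the median nearest-neighbor
#' spacing times `fwhm_fraction`, so the column covers the central full
#' width at half maximum of a cone's reflectance profile without touching
#' its neighbors'. Never smaller than 1 px.
#'
#' @param coords cone centers (px).
#' @param fwhm_fraction cone FWHM as a fraction of spacing (default 0.6).
#' @return radius in pixels.
#' @export
compute_column_radius <- function(coords, fwhm_fraction = 0.6) {
  coords <- as_coords(coords)
  if (nrow(coords) < 2L) stop("column radius undefined for a single cone")
  max(1, 0.5 * median_nn_spacing(coords) * fwhm_fraction)
}

#' Extract per-cone reflectance signals
#'
#' Projects a cylindrical column (a disc of `radius` px, the same disc in
#' every frame) through the acquisition at each cone center and averages
#' the pixel intensities frame by frame. A cone-frame is missing when the
#' frame is invalid or its column contains no image-region pixels.
#'
#' @param stack a [frame_stack()].
#' @param coords cone centers (px), typically refined.
#' @param radius column radius, px (>= 1); see [compute_column_radius()].
#' @return a [cone_signal_table()].
#' @export
extract_cone_signals <- function(stack, coords, radius) {
  stopifnot(inherits(stack, "frame_stack"), radius >= 1)
  coords <- as_coords(coords)
  dims <- dim(stack$frames)
  nt <- dims[3L]; nc <- nrow(coords)
  npix <- dims[1L] * dims[2L]
  cols <- lapply(seq_len(nc), function(i) {
    px <- disc_pixels(coords[i, ], radius, dims[1:2])
    (px[, "x"] - 1L) * dims[1L] + px[, "y"]
  })
  signal <- matrix(NA_real_, nc, nt)
  missing <- matrix(TRUE, nc, nt)
  flat <- matrix(stack$frames, nrow = npix)
  has_region <- !is.null(stack$image_region)
  for (t in seq_len(nt)) {
    if (!stack$valid[t]) next
    ft <- flat[, t]
    reg <- if (has_region) as.vector(stack$image_region[, , t]) else ft > 0
    for (i in seq_len(nc)) {
      idx <- cols[[i]]
      use <- idx[reg[idx]]
      if (length(use)) {
        signal[i, t] <- mean(ft[use])
        missing[i, t] <- FALSE
      }
    }
  }
  cone_signal_table(signal, missing, stack$frame_rate, stack$stimulus_frame)
}

#' Apply the cone exclusion rules
#'
#' Removes a cone when (a) more than 50% of the frames within 0.2 s after
#' stimulus delivery are missing (the cone may not have received the
#' stimulus), (b) 50% or more of the acquisition's frames are missing, or
#' (c) it is present in fewer than 50% of the trial's acquisitions. Rules
#' are independent, so their application order does not matter.
#'
#' @param table a [cone_signal_table()].
#' @param n_acquisitions_present per-cone count of acquisitions in which
#'   the cone was extracted (default: all, disabling rule c).
#' @param n_acquisitions_total total acquisitions in the trial.
#' @return the filtered table, with a data.frame of per-cone decisions in
#'   attribute `exclusion_report` (columns `cone_id`, `excluded`, `reason`).
#' @export
apply_exclusion <- function(table, n_acquisitions_present = NULL,
                            n_acquisitions_total = 1L) {
  stopifnot(inherits(table, "cone_signal_table"))
  nc <- nrow(table$signal); nt <- ncol(table$signal)
  if (is.null(n_acquisitions_present)) {
    n_acquisitions_present <- rep(n_acquisitions_total, nc)
  }
  win_end <- min(nt, table$stimulus_frame + ceiling(0.2 * table$frame_rate))
  win <- table$stimulus_frame:win_end
  miss_win <- rowMeans(table$missing[, win, drop = FALSE])
  miss_all <- rowMeans(table$missing)
  frac_acq <- n_acquisitions_present / n_acquisitions_total
  reason <- character(nc)
  reason[frac_acq < 0.5] <- "too_few_acquisitions"
  reason[miss_all >= 0.5] <- "half_frames_missing"
  reason[miss_win > 0.5] <- "stimulus_window_missing"
  excluded <- reason != ""
  report <- data.frame(cone_id = table$cone_ids, excluded = excluded,
                       reason = ifelse(excluded, reason, "retained"))
  out <- cone_signal_table(table$signal[!excluded, , drop = FALSE],
                           table$missing[!excluded, , drop = FALSE],
                           table$frame_rate, table$stimulus_frame,
                           cone_ids = table$cone_ids[!excluded])
  attr(out, "exclusion_report") <- report
  out
}

#' Subtract each cone's pre-stimulus mean
#'
#' Centers every cone signal on its mean over the non-missing frames
#' strictly before the stimulus frame, leaving only stimulus-evoked (and
#' noise) deviations. Cones with no valid pre-stimulus frame cannot be
#' centered and are dropped (with a message).
#'
#' @param table a [cone_signal_table()].
#' @return the mean-subtracted table.
#' @export
subtract_prestim_mean <- function(table) {
  stopifnot(inherits(table, "cone_signal_table"))
  pre <- seq_len(table$stimulus_frame - 1L)
  if (!length(pre)) stop("no pre-stimulus frames available")
  mu <- rowMeans(table$signal[, pre, drop = FALSE], na.rm = TRUE)
  bad <- !is.finite(mu)
  if (any(bad)) {
    message(sum(bad), " cone(s) without valid pre-stimulus frames dropped")
  }
  sig <- table$signal[!bad, , drop = FALSE] - mu[!bad]
  cone_signal_table(sig, table$missing[!bad, , drop = FALSE],
                    table$frame_rate, table$stimulus_frame,
                    cone_ids = table$cone_ids[!bad])
}

#' Write a cone signal table to CSV (long format)
#'
#' @param table a [cone_signal_table()].
#' @param path output CSV with columns `cone_id`, `frame`, `time_s`,
#'   `value`, `missing`.
#' @export
write_signal_table <- function(table, path) {
  nc <- nrow(table$signal); nt <- ncol(table$signal)
  df <- data.frame(cone_id = rep(table$cone_ids, times = nt),
                   frame = rep(seq_len(nt), each = nc),
                   time_s = rep(table$time, each = nc),
                   value = as.vector(table$signal),
                   missing = as.vector(table$missing))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
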
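#' A registered AOSLO acquisition
#'
#' One acquisition is a T-frame grayscale video held as an `H x W x T`
#' array, with a per-frame validity flag (frames lost to registration or
#' blinks), the frame rate, and the index of the stimulus frame. An
#' optional per-frame `image_region` mask marks the image-containing
#' pixels; when absent, pixels `> 0` are treated as image-containing
#' (registration fills empty canvas with zeros).
#'
#' @param frames numeric array `H x W x T` (arbitrary intensity units).
#' @param frame_rate frames per second.
#' @param stimulus_frame 1-based index of the first frame at or after
#'   stimulus delivery.
#' @param valid logical length-T; defaults to all valid.
#' @param image_region optional logical array `H x W x T` (or `H x W`
#'   matrix recycled across frames) of image-containing pixels.
#' @return an object of class `frame_stack`.
#' @export
frame_stack <- function(frames, frame_rate, stimulus_frame,
                        valid = NULL, image_region = NULL) {
  frames <- unclass(frames)
  if (length(dim(frames)) != 3L) stop("frames must be an H x W x T array")
  nt <- dim(frames)[3L]
  if (nt < 2L) stop("a frame stack needs at least 2 frames")
  if (is.null(valid)) valid <- rep(TRUE, nt)
  if (length(valid) != nt) stop("valid must have one flag per frame")
  stopifnot(frame_rate > 0)
  stimulus_frame <- as.integer(stimulus_frame)
  if (stimulus_frame < 1L || stimulus_frame > nt) {
    stop("stimulus_frame must lie within [1, T]")
  }
  if (!is.null(image_region)) {
    if (is.matrix(image_region)) {
      image_region <- array(image_region, dim = dim(frames))
    }
    if (!identical(dim(image_region), dim(frames))) {
      stop("image_region must match frame dimensions")
    }
    storage.mode(image_region) <- "logical"
  }
  structure(
    list(frames = frames, valid = as.logical(valid),
         frame_rate = as.numeric(frame_rate),
         stimulus_frame = stimulus_frame,
         image_region = image_region),
    class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<frame_stack> %d x %d px, %d frames (%d valid), %.2f Hz, stimulus frame %d\n",
              d[1L], d[2L], d[3L], sum(x$valid), x$frame_rate, x$stimulus_frame))
  invisible(x)
}

#' Frame timestamps
#'
#' Frame `k` (1-based) is stamped `(k - 1) / frame_rate` seconds, i.e. the
#' first frame is at time zero.
#'
#' @param stack a `frame_stack`.
#' @return numeric vector of times in seconds.
#' @export
frame_times <- function(stack) {
  (seq_len(dim(stack$frames)[3L]) - 1) / stack$frame_rate
}

# Image-containing mask for frame t (logical H x W).
frame_region <- function(stack, t) {
  if (!is.null(stack$image_region)) return(stack$image_region[, , t])
  stack$frames[, , t] > 0
}

#' Write / read a frame stack as a multi-frame 16-bit TIFF
#'
#' Intensities (arbitrary units) are quantized as
#' `round(value * gain)` into 16-bit samples; `gain` (stored alongside in
#' the JSON sidecar written by the cohort generator) must be supplied to
#' recover the original scale on read. Values outside `[0, 65535/gain]`
#' are clipped.
#'
#' @param stack a `frame_stack`.
#' @param path TIFF file path.
#' @param gain intensity units per 16-bit count (default 16).
#' @export
write_frame_stack <- function(stack, path, gain = 16) {
  stopifnot(gain > 0)
  nt <- dim(stack$frames)[3L]
  pages <- lapply(seq_len(nt), function(t) {
    m <- round(stack$frames[, , t] * gain)
    m[m < 0] <- 0; m[m > 65535] <- 65535
    m / 65535
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}

#' @rdname write_frame_stack
#' @param frame_rate,stimulus_frame,valid metadata to attach (TIFF pages
#'   carry none).
#' @export
read_frame_stack <- function(path, frame_rate, stimulus_frame,
                             valid = NULL, gain = 16) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  arr <- array(0, dim = c(dim(pages[[1L]])[1:2], length(pages)))
  for (t in seq_along(pages)) arr[, , t] <- pages[[t]] * 65535 / gain
  frame_stack(arr, frame_rate, stimulus_frame, valid = valid)
}

#' Drop acquisitions that lost half their frames
#'
#' Registration can discard frames; acquisitions retaining fewer than half
#' of the frames originally recorded are removed outright, since their RMS
#' summaries would rest on too little data.
#'
#' @param stacks list of `frame_stack` objects.
#' @param original_frame_count frame count of the raw recording.
#' @return the retained subset (possibly empty), in input order.
#' @export
exclude_short_acquisitions <- function(stacks, original_frame_count) {
  stopifnot(original_frame_count > 0)
  keep <- vapply(stacks, function(s) sum(s$valid) >= original_frame_count / 2, logical(1L))
  stacks[keep]
}
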
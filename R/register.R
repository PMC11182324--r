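# Integer-displacement search: displacement d (dx, dy) such that
# frame(x) ~ ref(x - d), scored by Pearson correlation over the overlap of
# `rows` (reference rows) with the displaced frame. Ties go to the
# smallest displacement (search order is by increasing |d|).
best_integer_shift <- function(frame, ref, rows = seq_len(nrow(ref)),
                               max_shift = 8L) {
  H <- nrow(ref); W <- ncol(ref)
  grid <- expand.grid(dx = -max_shift:max_shift, dy = -max_shift:max_shift)
  grid <- grid[order(grid$dx^2 + grid$dy^2), ]
  best <- c(0, 0); best_s <- -Inf
  for (k in seq_len(nrow(grid))) {
    dx <- grid$dx[k]; dy <- grid$dy[k]
    ry <- rows[rows + dy >= 1L & rows + dy <= H]
    rx <- which(seq_len(W) + dx >= 1L & seq_len(W) + dx <= W)
    if (length(ry) < 2L || length(rx) < 2L) next
    a <- frame[ry + dy, rx + dx, drop = FALSE]
    b <- ref[ry, rx, drop = FALSE]
    if (stats::sd(a) == 0 || stats::sd(b) == 0) next
    s <- stats::cor(as.vector(a), as.vector(b))
    if (s > best_s + 1e-12) { best_s <- s; best <- c(dx, dy) }
  }
  list(shift = best, score = best_s)
}

# Translate an image by an integer displacement, zero-filling: the content
# moves by -d (i.e. undoes a measured displacement d when called with d).
shift_rows <- function(img, rows, dx, dy) {
  H <- nrow(img); W <- ncol(img)
  out <- img
  out[rows, ] <- 0
  src_y <- rows + dy
  ok_y <- src_y >= 1L & src_y <= H
  src_x <- seq_len(W) + dx
  ok_x <- src_x >= 1L & src_x <= W
  if (any(ok_y) && any(ok_x)) {
    out[rows[ok_y], which(ok_x)] <- img[src_y[ok_y], src_x[ok_x]]
  }
  out
}

#' Correct residual intra-frame distortion
#'
#' Scanned imaging introduces within-frame distortion that registration
#' replicates into every frame. For each horizontal strip of the reference
#' frame, the displacement aligning each frame's strip to the reference is
#' measured; the median displacement over frames is taken as the shared
#' (reference-borne) distortion of that strip and its inverse is applied
#' to the corresponding strip of every frame. The median makes the
#' estimate robust to individual frames with residual motion.
#'
#' @param stack a [frame_stack()].
#' @param reference_frame 1-based index of the reference frame (must be
#'   valid).
#' @param strip_height strip height in px; the last strip may be partial.
#' @param max_shift integer search range, px.
#' @return corrected `frame_stack` with the per-strip median displacements
#'   in attribute `strip_shifts` (one row per strip: `dx`, `dy`).
#' @export
correct_intraframe_distortion <- function(stack, reference_frame,
                                          strip_height = 8L, max_shift = 8L) {
  stopifnot(inherits(stack, "frame_stack"))
  nt <- dim(stack$frames)[3L]
  if (reference_frame < 1L || reference_frame > nt || !stack$valid[reference_frame]) {
    stop("reference frame invalid")
  }
  H <- dim(stack$frames)[1L]
  ref <- stack$frames[, , reference_frame]
  starts <- seq(1L, H, by = strip_height)
  frames <- stack$frames
  use <- which(stack$valid)
  shifts <- matrix(0, length(starts), 2L, dimnames = list(NULL, c("dx", "dy")))
  for (si in seq_along(starts)) {
    rows <- starts[si]:min(H, starts[si] + strip_height - 1L)
    d <- t(vapply(use, function(t) {
      best_integer_shift(frames[, , t], ref, rows, max_shift)$shift
    }, numeric(2L)))
    med <- round(apply(d, 2L, stats::median))
    shifts[si, ] <- med
    if (any(med != 0)) {
      for (t in seq_len(nt)) {
        frames[, , t] <- shift_rows(frames[, , t], rows, med[1L], med[2L])
      }
    }
  }
  out <- frame_stack(frames, stack$frame_rate, stack$stimulus_frame,
                     valid = stack$valid, image_region = stack$image_region)
  attr(out, "strip_shifts") <- shifts
  out
}

# Bilinear sampling of img at (xs, ys); returns values (NA outside).
bilinear_sample <- function(img, xs, ys) {
  H <- nrow(img); W <- ncol(img)
  x0 <- floor(xs); y0 <- floor(ys)
  fx <- xs - x0; fy <- ys - y0
  ok <- x0 >= 1 & x0 + 1 <= W & y0 >= 1 & y0 + 1 <= H
  v <- rep(NA_real_, length(xs))
  if (any(ok)) {
    i00 <- (x0[ok] - 1) * H + y0[ok]
    v[ok] <- (1 - fx[ok]) * (1 - fy[ok]) * img[i00] +
      fx[ok] * (1 - fy[ok]) * img[i00 + H] +
      (1 - fx[ok]) * fy[ok] * img[i00 + 1] +
      fx[ok] * fy[ok] * img[i00 + H + 1]
  }
  v
}

# Apply an affine map to an image: out(x) = img(A (x - c) + c + b), with
# c the image center. p = c(dx, dy, a11, a12, a21, a22).
warp_affine <- function(img, p) {
  H <- nrow(img); W <- ncol(img)
  cx <- (W + 1) / 2; cy <- (H + 1) / 2
  xs <- rep(seq_len(W), each = H) - cx
  ys <- rep(seq_len(H), times = W) - cy
  sx <- p[3L] * xs + p[4L] * ys + cx + p[1L]
  sy <- p[5L] * xs + p[6L] * ys + cy + p[2L]
  matrix(bilinear_sample(img, sx, sy), H, W)
}

#' Full-frame affine registration to a reference frame
#'
#' Registers each frame to the reference by maximizing the Pearson
#' correlation over the frame under an affine transformation model,
#' removing residual full-frame drift (e.g. transverse chromatic
#' aberration, torsion). Initialization is an integer translation search;
#' refinement uses gradient-based optimization of the six affine
#' parameters. Frames whose optimization fails to converge or whose final
#' correlation stays below `min_cor` are flagged invalid with a warning.
#'
#' @param stack a [frame_stack()].
#' @param reference_frame 1-based reference frame index (must be valid).
#' @param max_shift translation search range for initialization, px.
#' @param min_cor minimum acceptable final correlation.
#' @return registered `frame_stack`; per-frame transforms (2 x 3 matrices
#'   `[A | b]` mapping centered output to source coordinates) in attribute
#'   `transforms`, final correlations in attribute `correlations`.
#' @export
affine_register_frames <- function(stack, reference_frame, max_shift = 8L,
                                   min_cor = 0.2) {
  stopifnot(inherits(stack, "frame_stack"))
  nt <- dim(stack$frames)[3L]
  if (reference_frame < 1L || reference_frame > nt || !stack$valid[reference_frame]) {
    stop("reference frame invalid")
  }
  ref <- stack$frames[, , reference_frame]
  rv <- as.vector(ref)
  frames <- stack$frames
  valid <- stack$valid
  transforms <- vector("list", nt)
  cors <- rep(NA_real_, nt)
  for (t in seq_len(nt)) {
    if (!valid[t]) next
    if (t == reference_frame) {
      transforms[[t]] <- cbind(diag(2), c(0, 0))
      cors[t] <- 1
      next
    }
    fr <- frames[, , t]
    init <- best_integer_shift(fr, ref, max_shift = max_shift)$shift
    obj <- function(p) {
      w <- warp_affine(fr, p)
      ok <- !is.na(w)
      if (sum(ok) < 0.3 * length(rv)) return(1)
      if (stats::sd(w[ok]) == 0) return(1)
      -stats::cor(w[ok], rv[ok])
    }
    fit <- stats::optim(c(init, 1, 0, 0, 1), obj, method = "BFGS",
                        control = list(parscale = c(1, 1, 0.01, 0.01, 0.01, 0.01),
                                       reltol = 1e-10, maxit = 200))
    cors[t] <- -fit$value
    if (fit$convergence != 0 || cors[t] < min_cor) {
      warning(sprintf("frame %d: registration did not converge (cor = %.3f); flagged invalid",
                      t, cors[t]))
      valid[t] <- FALSE
      next
    }
    p <- fit$par
    transforms[[t]] <- cbind(matrix(p[3:6], 2L, 2L, byrow = TRUE), p[1:2])
    frames[, , t] <- ifelse(is.na(w <- warp_affine(fr, p)), 0, w)
  }
  out <- frame_stack(frames, stack$frame_rate, stack$stimulus_frame,
                     valid = valid, image_region = stack$image_region)
  attr(out, "transforms") <- transforms
  attr(out, "correlations") <- cors
  out
}
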
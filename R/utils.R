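#' @keywords internal
"_PACKAGE"

# Run `expr` under a temporary RNG state seeded with `seed`; restores the
# caller's RNG afterwards. All stochastic generators in the package route
# through this so that identical seeds give identical outputs.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a base seed; keeps results < 2^31.
child_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  (as.double(seed) * 48271 + as.double(k)) %% 2147483647
}

#' Pixels sampled by a cylindrical column
#'
#' Integer pixel coordinates whose centers lie within `radius` of `center`.
#' This single helper defines the column geometry for both the synthetic
#' renderer and the signal extractor, so ground-truth amplitudes and
#' extracted amplitudes refer to the same photometric aperture.
#'
#' @param center numeric length-2, (x, y) in pixels (1-based, pixel centers
#'   at integers).
#' @param radius column radius in pixels.
#' @param dim image dimensions `c(height, width)`; pixels outside are dropped.
#' @return matrix with columns `x`, `y` (integer pixel indices).
#' @export
disc_pixels <- function(center, radius, dim) {
  stopifnot(length(center) == 2L, radius >= 0)
  x0 <- center[1L]; y0 <- center[2L]
  xr <- seq.int(max(1L, floor(x0 - radius)), min(dim[2L], ceiling(x0 + radius)))
  yr <- seq.int(max(1L, floor(y0 - radius)), min(dim[1L], ceiling(y0 + radius)))
  if (!length(xr) || !length(yr)) {
    return(matrix(integer(0), ncol = 2L, dimnames = list(NULL, c("x", "y"))))
  }
  g <- expand.grid(x = xr, y = yr, KEEP.OUT.ATTRS = FALSE)
  keep <- (g$x - x0)^2 + (g$y - y0)^2 <= radius^2
  as.matrix(g[keep, , drop = FALSE])
}

# Median nearest-neighbor spacing of a coordinate set (same metric the
# column-radius rule uses). coords: matrix/data.frame with x, y columns.
median_nn_spacing <- function(coords) {
  coords <- as_coords(coords)
  if (nrow(coords) < 2L) stop("need at least 2 coordinates to estimate spacing")
  d <- as.matrix(stats::dist(coords))
  diag(d) <- Inf
  stats::median(apply(d, 1L, min))
}

# Coerce coordinate input (matrix or data.frame with x/y or x_px/y_px
# columns) to a 2-column numeric matrix.
as_coords <- function(coords) {
  if (is.data.frame(coords)) {
    nms <- names(coords)
    xcol <- intersect(c("x", "x_px"), nms)[1L]
    ycol <- intersect(c("y", "y_px"), nms)[1L]
    if (is.na(xcol) || is.na(ycol)) stop("coordinate data.frame needs x/y (or x_px/y_px) columns")
    coords <- cbind(coords[[xcol]], coords[[ycol]])
  }
  coords <- as.matrix(coords)
  if (ncol(coords) != 2L) stop("coordinates must have two columns (x, y)")
  storage.mode(coords) <- "double"
  colnames(coords) <- c("x", "y")
  coords
}

#' Read / write cone-center coordinates
#'
#' Coordinate CSVs use columns `x_px`, `y_px` with 0-based pixel centers
#' (the common interchange convention of cone-detection tools). In memory
#' the package uses R's 1-based pixel centers; the offset is applied here.
#'
#' @param path CSV path.
#' @return `read_cone_coords`: a 2-column matrix (`x`, `y`), 1-based.
#' @export
read_cone_coords <- function(path) {
  df <- utils::read.csv(path)
  as_coords(df) + 1
}

#' @rdname read_cone_coords
#' @param coords coordinate matrix (1-based, as used in memory).
#' @export
write_cone_coords <- function(coords, path) {
  coords <- as_coords(coords)
  utils::write.csv(
    data.frame(x_px = coords[, "x"] - 1, y_px = coords[, "y"] - 1),
    path, row.names = FALSE)
  invisible(path)
}
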
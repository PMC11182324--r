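#' Specification of a synthetic cone mosaic
#'
#' Describes a jittered hexagonal cone lattice. Spacing and jitter are in
#' micrometers on the retina; the pixel grid is defined by the imaging
#' scale (`pixels_per_degree`) and the retinal magnification factor
#' (micrometers per degree of visual angle).
#'
#' @param spacing target center-to-center spacing, um. Must be positive.
#' @param jitter_sd isotropic Gaussian positional jitter SD, um.
#' @param field_size imaged field, degrees (square field assumed).
#' @param pixels_per_degree sampling density of the imaging system, px/deg.
#' @param retinal_magnification um of retina per degree (default 291).
#' @param seed RNG seed for the jitter.
#' @return an object of class `mosaic_spec`.
#' @export
mosaic_spec <- function(spacing = 5, jitter_sd = 0.3, field_size = 0.25,
                        pixels_per_degree = 600, retinal_magnification = 291,
                        seed = NULL) {
  if (!is.numeric(spacing) || spacing <= 0) stop("invalid mosaic spec: spacing must be > 0")
  if (jitter_sd < 0) stop("invalid mosaic spec: jitter_sd must be >= 0")
  stopifnot(field_size > 0, pixels_per_degree > 0, retinal_magnification > 0)
  structure(list(spacing = spacing, jitter_sd = jitter_sd,
                 field_size = field_size,
                 pixels_per_degree = pixels_per_degree,
                 retinal_magnification = retinal_magnification,
                 seed = seed),
            class = "mosaic_spec")
}

# um <-> px conversion factors for a mosaic spec.
px_per_um <- function(spec) spec$pixels_per_degree / spec$retinal_magnification

#' Generate a jittered hexagonal cone mosaic
#'
#' Lays down a hexagonal lattice (nearest-neighbor distance exactly
#' `spacing` when `jitter_sd = 0`) across the field, adds isotropic
#' Gaussian jitter, and returns cone centers in pixel units. A margin of
#' one spacing is kept clear of the field edge so that every cone's
#' sampling column fits inside the frame.
#'
#' @param spec a [mosaic_spec()].
#' @return 2-column matrix of cone centers (`x`, `y`, px, 1-based), with
#'   attributes `dim_px` (frame `c(H, W)`) and `um_per_px`.
#' @export
generate_mosaic <- function(spec) {
  stopifnot(inherits(spec, "mosaic_spec"))
  side_px <- ceiling(spec$field_size * spec$pixels_per_degree)
  k <- px_per_um(spec)                  # px per um
  side_um <- side_px / k
  margin <- spec$spacing + 3 * spec$jitter_sd
  s <- spec$spacing
  rowstep <- s * sqrt(3) / 2
  ys <- seq(margin, side_um - margin, by = rowstep)
  pts <- with_seed(spec$seed, {
    out <- vector("list", length(ys))
    for (j in seq_along(ys)) {
      off <- if (j %% 2 == 0) s / 2 else 0
      xs <- seq(margin + off, side_um - margin, by = s)
      out[[j]] <- cbind(xs, rep(ys[j], length(xs)))
    }
    p <- do.call(rbind, out)
    if (spec$jitter_sd > 0) {
      p <- p + matrix(stats::rnorm(length(p), 0, spec$jitter_sd), ncol = 2L)
    }
    p
  })
  coords <- pts * k + 0.5               # um -> px; pixel centers at integers
  colnames(coords) <- c("x", "y")
  attr(coords, "dim_px") <- c(side_px, side_px)
  attr(coords, "um_per_px") <- 1 / k
  coords
}

#' Synthetic OCT longitudinal reflectance profile
#'
#' Two Gaussian peaks playing the roles of the ellipsoid zone (EZ) and
#' interdigitation zone (IZ) bands, separated by the outer-segment length,
#' on a uniform depth grid with additive Gaussian noise. The IZ peak is
#' rendered dimmer (70% of EZ), as in clinical profiles.
#'
#' @param os_length EZ-to-IZ peak separation, um. Must be positive and
#'   resolvable on the grid (`> 2 * depth_step`).
#' @param peak_sd Gaussian width of each band, um.
#' @param noise_sd additive noise SD in units of the EZ peak height (1).
#' @param depth_step depth sampling interval, um.
#' @param seed RNG seed for the noise.
#' @return data.frame with columns `depth_um`, `reflectance`.
#' @export
generate_lrp <- function(os_length, peak_sd = 3, noise_sd = 0,
                         depth_step = 0.5, seed = NULL) {
  if (os_length <= 0) stop("os_length must be positive")
  stopifnot(depth_step > 0, peak_sd > 0, noise_sd >= 0)
  if (os_length <= 2 * depth_step) {
    stop("unresolvable peaks: os_length must exceed 2 * depth_step")
  }
  pad <- 5 * peak_sd
  depth <- seq(0, os_length + 2 * pad, by = depth_step)
  z_ez <- pad
  z_iz <- pad + os_length
  refl <- exp(-(depth - z_ez)^2 / (2 * peak_sd^2)) +
    0.7 * exp(-(depth - z_iz)^2 / (2 * peak_sd^2))
  refl <- with_seed(seed, refl + stats::rnorm(length(depth), 0, noise_sd))
  data.frame(depth_um = depth, reflectance = refl)
}

#' @rdname generate_lrp
#' @param path CSV path (`depth_um`, `reflectance`).
#' @param lrp data.frame as returned by `generate_lrp`.
#' @export
write_lrp <- function(lrp, path) {
  utils::write.csv(lrp[, c("depth_um", "reflectance")], path, row.names = FALSE)
  invisible(path)
}

#' @rdname generate_lrp
#' @export
read_lrp <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("depth_um", "reflectance") %in% names(df))) {
    stop("LRP CSV needs depth_um and reflectance columns")
  }
  df
}
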
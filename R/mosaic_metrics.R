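# Clip a convex polygon (matrix of vertices, counterclockwise not
# required) by the half-plane {x : a.x <= b}. Sutherland-Hodgman step.
clip_halfplane <- function(poly, a, b) {
  n <- nrow(poly)
  if (!n) return(poly)
  s <- poly %*% a - b                      # <= 0 inside
  out <- matrix(numeric(0), 0L, 2L)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    pi_in <- s[i] <= 1e-12; pj_in <- s[j] <= 1e-12
    if (pi_in) out <- rbind(out, poly[i, ])
    if (xor(pi_in, pj_in)) {
      t <- s[i] / (s[i] - s[j])
      out <- rbind(out, poly[i, ] + t * (poly[j, ] - poly[i, ]))
    }
  }
  out
}

# Voronoi cell of point i as a convex polygon, built by clipping a large
# bounding box with the perpendicular bisectors to all other points.
# Neighbors are visited nearest-first so that once half the distance to
# the next point exceeds the cell's farthest vertex, the rest cannot cut.
voronoi_cell <- function(coords, i, box_half = NULL) {
  p <- coords[i, ]
  d2 <- (coords[, 1L] - p[1L])^2 + (coords[, 2L] - p[2L])^2
  ord <- order(d2)
  ord <- ord[ord != i]
  if (is.null(box_half)) {
    span <- max(diff(range(coords[, 1L])), diff(range(coords[, 2L])), 1)
    box_half <- 10 * span
  }
  poly <- cbind(p[1L] + c(-1, 1, 1, -1) * box_half,
                p[2L] + c(-1, -1, 1, 1) * box_half)
  for (j in ord) {
    dj <- sqrt(d2[j])
    maxv <- sqrt(max((poly[, 1L] - p[1L])^2 + (poly[, 2L] - p[2L])^2))
    if (dj / 2 > maxv) break
    q <- coords[j, ]
    a <- q - p                              # bisector: a.x <= a.(p+q)/2
    poly <- clip_halfplane(poly, a, sum(a * (p + q) / 2))
    if (!nrow(poly)) break
  }
  poly
}

#' Bound nearest-neighbor distance of a cone mosaic
#'
#' Computes each cone's distance to its nearest neighbor, and averages
#' over the "bound" cones — those whose Voronoi cell lies entirely inside
#' the region of interest, so the metric is not biased by cones whose
#' true nearest neighbor may lie outside the imaged field.
#'
#' @param coords cone centers (px).
#' @param roi region of interest `c(xmin, xmax, ymin, ymax)` in px;
#'   defaults to the coordinate bounding box.
#' @param scale micrometers per pixel (default 1: report in px).
#' @return list of class `mosaic_metrics` with `mean_bound_nnd` (um),
#'   `n_bound_cones`, `per_cone_nnd` (um, all cones) and logical `bound`.
#' @export
bound_nnd <- function(coords, roi = NULL, scale = 1) {
  coords <- as_coords(coords)
  if (nrow(coords) < 2L) stop("bound NND needs at least 2 cones")
  stopifnot(scale > 0)
  if (is.null(roi)) {
    roi <- c(range(coords[, 1L]), range(coords[, 2L]))
  }
  d <- as.matrix(stats::dist(coords))
  diag(d) <- Inf
  nnd <- unname(apply(d, 1L, min)) * scale
  eps <- 1e-9 * max(abs(roi), 1)
  bound <- vapply(seq_len(nrow(coords)), function(i) {
    cell <- voronoi_cell(coords, i)
    nrow(cell) > 0L &&
      all(cell[, 1L] >= roi[1L] - eps & cell[, 1L] <= roi[2L] + eps &
          cell[, 2L] >= roi[3L] - eps & cell[, 2L] <= roi[4L] + eps)
  }, logical(1L))
  if (!any(bound)) {
    stop("no bound cones (", nrow(coords), " cones, none with a Voronoi cell inside the ROI)")
  }
  structure(list(mean_bound_nnd = mean(nnd[bound]),
                 n_bound_cones = sum(bound),
                 per_cone_nnd = nnd, bound = bound),
            class = "mosaic_metrics")
}

#' @export
print.mosaic_metrics <- function(x, ...) {
  cat(sprintf("<mosaic_metrics> mean bound NND %.3f um over %d bound cones (%d total)\n",
              x$mean_bound_nnd, x$n_bound_cones, length(x$per_cone_nnd)))
  invisible(x)
}

#' Z-score against normative statistics
#'
#' Standardizes a metric value against the control mean and SD for its
#' eccentricity. The signed value is returned; summary tables
#' conventionally report its magnitude (`abs = TRUE`).
#'
#' @param value observed metric value.
#' @param ref list or one-row data.frame with `mean` and `sd`.
#' @param abs return the absolute z-score.
#' @return dimensionless z-score.
#' @export
z_score <- function(value, ref, abs = FALSE) {
  if (!is.finite(ref$sd) || ref$sd <= 0) stop("normative sd must be positive")
  z <- (value - ref$mean) / ref$sd
  if (abs) base::abs(z) else z
}

#' Read a normative statistics table
#'
#' CSV with columns `metric` (one of `NND`, `OS_length`,
#' `iORG_amplitude`), `eccentricity_deg`, `mean`, `sd`.
#'
#' @param path CSV path.
#' @return data.frame.
#' @export
read_normative_stats <- function(path) {
  df <- utils::read.csv(path)
  need <- c("metric", "eccentricity_deg", "mean", "sd")
  if (!all(need %in% names(df))) {
    stop("normative table needs columns: ", paste(need, collapse = ", "))
  }
  if (any(df$sd <= 0)) stop("normative sd values must be positive")
  df
}

#' Look up normative statistics for one metric and eccentricity
#'
#' @param stats data.frame from [read_normative_stats()].
#' @param metric metric name.
#' @param eccentricity eccentricity in degrees (exact match).
#' @return one-row list with `mean` and `sd`.
#' @export
normative_ref <- function(stats, metric, eccentricity) {
  row <- stats[stats$metric == metric & stats$eccentricity_deg == eccentricity, ]
  if (nrow(row) != 1L) {
    stop("no unique normative entry for ", metric, " at ", eccentricity, " deg")
  }
  list(mean = row$mean, sd = row$sd)
}
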
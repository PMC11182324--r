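#' Cohort age summary
#'
#' Arithmetic mean and sample standard deviation (n - 1 denominator) of
#' participant ages.
#'
#' @param ages numeric vector of ages, years (n >= 2).
#' @return list with `mean`, `sd`, `n`.
#' @export
summarize_ages <- function(ages) {
  ages <- as.numeric(ages)
  if (length(ages) < 2L || any(!is.finite(ages))) {
    stop("need at least 2 finite ages")
  }
  list(mean = mean(ages), sd = stats::sd(ages), n = length(ages))
}

#' Ordinary least squares fit with prediction intervals
#'
#' Simple linear regression of `y` on `x` with the two-sided slope test
#' and pointwise prediction intervals for a new observation (the dashed
#' bands conventionally drawn around structure-function regressions).
#' Confidence intervals for the mean response are returned alongside.
#'
#' @param x,y numeric vectors (n >= 3; `x` not all equal).
#' @param level interval level (default 0.95).
#' @param newdata x values at which to evaluate the bands (default `x`).
#' @return list of class `regression_result`: `slope`, `intercept`,
#'   `r_squared`, `p_value`, `prediction_band` (data.frame `x`, `fit`,
#'   `lwr`, `upr`), `confidence_band`, and the underlying `lm` fit.
#' @export
linear_fit_with_pi <- function(x, y, level = 0.95, newdata = NULL) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 complete observations")
  if (stats::sd(x) == 0) stop("degenerate predictor: x values are all equal")
  stopifnot(level > 0, level < 1)
  fit <- stats::lm(y ~ x, data = data.frame(x = x, y = y))
  sm <- summary(fit)
  if (is.null(newdata)) newdata <- sort(unique(x))
  nd <- data.frame(x = newdata)
  pb <- stats::predict(fit, nd, interval = "prediction", level = level)
  cb <- stats::predict(fit, nd, interval = "confidence", level = level)
  structure(list(slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 r_squared = sm$r.squared,
                 p_value = sm$coefficients[2L, 4L],
                 level = level,
                 prediction_band = data.frame(x = newdata, pb),
                 confidence_band = data.frame(x = newdata, cb),
                 fit = fit),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("<regression_result> y = %.3gx + %.3g; r^2 = %.3g; p = %.3g\n",
              x$slope, x$intercept, x$r_squared, x$p_value))
  invisible(x)
}

#' Spearman rank correlation
#'
#' Rank correlation with average ranks on ties. P-values use the exact
#' null distribution for small samples (n <= 20, no ties) and the
#' t-approximation otherwise.
#'
#' @param x,y numeric vectors (n >= 4; neither constant).
#' @return list with `rho`, `p_value`, `n`.
#' @export
spearman_cor <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4L) stop("need at least 4 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("constant input")
  rho <- stats::cor(rank(x), rank(y))
  ties <- anyDuplicated(x) > 0L || anyDuplicated(y) > 0L
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = (n <= 20L && !ties)))
  list(rho = unname(rho), p_value = ct$p.value, n = n)
}

#' Pair iORG locations with microperimetry sensitivities
#'
#' Each iORG sampling location is paired with the retinal sensitivity
#' measured closest to it in eccentricity; ties go to the smaller
#' sensitivity eccentricity.
#'
#' @param iorg_eccentricities iORG location eccentricities, degrees.
#' @param sensitivities data.frame with `eccentricity_deg` and
#'   `sensitivity_db` (0-36 dB, 0 brightest).
#' @return data.frame with `iorg_eccentricity_deg`,
#'   `sensitivity_eccentricity_deg`, `sensitivity_db`, `delta_deg`.
#' @export
pair_sensitivity <- function(iorg_eccentricities, sensitivities) {
  stopifnot(length(iorg_eccentricities) > 0, nrow(sensitivities) > 0,
            all(c("eccentricity_deg", "sensitivity_db") %in% names(sensitivities)))
  if (any(sensitivities$sensitivity_db < 0 | sensitivities$sensitivity_db > 36)) {
    stop("sensitivities must lie in [0, 36] dB")
  }
  rows <- lapply(iorg_eccentricities, function(e) {
    d <- abs(sensitivities$eccentricity_deg - e)
    cand <- which(d == min(d))
    i <- cand[which.min(sensitivities$eccentricity_deg[cand])]
    data.frame(iorg_eccentricity_deg = e,
               sensitivity_eccentricity_deg = sensitivities$eccentricity_deg[i],
               sensitivity_db = sensitivities$sensitivity_db[i],
               delta_deg = d[i])
  })
  do.call(rbind, rows)
}

#' Empirical coverage of the prediction interval
#'
#' Simulates linear data, fits [linear_fit_with_pi()], draws a fresh
#' observation at every design point, and reports the fraction falling
#' inside the prediction band. Used to verify the nominal level of the
#' interval construction.
#'
#' @param n_obs observations per replicate.
#' @param n_reps replicates.
#' @param slope,intercept,sigma generating model.
#' @param level interval level.
#' @param seed RNG seed.
#' @return empirical coverage (fraction).
#' @export
pi_coverage <- function(n_obs = 50, n_reps = 1000, slope = 0.71,
                        intercept = 13.8, sigma = 3, level = 0.95,
                        seed = NULL) {
  with_seed(seed, {
    hits <- 0L; total <- 0L
    for (r in seq_len(n_reps)) {
      x <- stats::runif(n_obs, 0, 10)
      y <- intercept + slope * x + stats::rnorm(n_obs, 0, sigma)
      fitres <- linear_fit_with_pi(x, y, level = level, newdata = x)
      ynew <- intercept + slope * x + stats::rnorm(n_obs, 0, sigma)
      pb <- fitres$prediction_band
      hits <- hits + sum(ynew >= pb$lwr & ynew <= pb$upr)
      total <- total + n_obs
    }
    hits / total
  })
}

#' Read a cohort demographics table
#'
#' CSV with columns `subject_id`, `group` (`control` / `rp`),
#' `age_years`, `axial_length_mm`, `photon_density_um2`. The package
#' ships an example cohort table under `inst/extdata`.
#'
#' @param path CSV path.
#' @return data.frame.
#' @export
read_demographics <- function(path) {
  df <- utils::read.csv(path)
  need <- c("subject_id", "group", "age_years")
  if (!all(need %in% names(df))) {
    stop("demographics table needs columns: ", paste(need, collapse = ", "))
  }
  df
}
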
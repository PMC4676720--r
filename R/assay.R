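#' Fit a fluorescence standard curve
#'
#' Ordinary least-squares line through calibration points of known product
#' concentration versus fluorescence (6-aminoquinoline calibration in the
#' packaged workflow). The intercept is fitted, not forced through zero.
#'
#' @param points data.frame with columns `conc` (molar) and
#'   `fluorescence` (AU), at least 3 points with >= 2 distinct
#'   concentrations.
#' @return an object of class `standard_curve` with `slope` (AU per molar),
#'   `intercept` (AU), `r_squared` and the calibration points.
#' @examples
#' pts <- data.frame(conc = c(0, 5e-6, 10e-6, 20e-6),
#'                   fluorescence = c(5, 15, 25, 45))
#' fit_standard_curve(pts)
#' @export
fit_standard_curve <- function(points) {
  stopifnot(is.data.frame(points), all(c("conc", "fluorescence") %in%
                                         names(points)))
  if (nrow(points) < 3) stop("at least 3 calibration points are required")
  if (length(unique(points$conc)) < 2)
    stop("calibration points are degenerate: a single concentration")
  fit <- stats::lm(fluorescence ~ conc, data = points)
  s <- suppressWarnings(summary(fit))  # exact calibration lines are legitimate
  slope <- unname(stats::coef(fit)[2])
  if (slope <= 0) stop("standard-curve slope must be positive")
  structure(list(slope = slope, intercept = unname(stats::coef(fit)[1]),
                 r_squared = s$r.squared,
                 slope_se = s$coefficients[2, 2], points = points),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("Standard curve: slope %.4g AU/M, intercept %.4g AU, R2 %.5f (%d points)\n",
              x$slope, x$intercept, x$r_squared, nrow(x$points)))
  invisible(x)
}

#' Extract a specific activity from a fluorescence time course
#'
#' Converts fluorescence to product concentration through the inverse of the
#' standard curve, fits a linear slope over the requested time window, and
#' converts to moles of product per minute per mg enzyme using the reaction
#' volume.
#'
#' @param trace data.frame with columns `time_min` and `fluorescence_au`
#'   (e.g. from [generate_time_course()]).
#' @param curve a [fit_standard_curve()] result.
#' @param window numeric length-2 `(start, end)` in minutes; defaults to the
#'   full trace. At least 2 samples must fall inside.
#' @param enzyme_mass_mg enzyme mass in mg (> 0).
#' @param volume reaction volume in liters; defaults to the generating
#'   spec's volume when the trace carries one, else 20e-6.
#' @return specific activity, mol product per minute per mg enzyme.
#' @export
rate_from_timecourse <- function(trace, curve, window = NULL, enzyme_mass_mg,
                                 volume = NULL) {
  stopifnot(inherits(curve, "standard_curve"))
  if (enzyme_mass_mg <= 0) stop("enzyme mass must be positive")
  if (is.null(volume)) {
    sp <- attr(trace, "spec")
    volume <- if (!is.null(sp)) sp$volume else 20e-6
  }
  t <- trace$time_min
  if (is.null(window)) window <- range(t)
  keep <- t >= window[1] & t <= window[2]
  if (sum(keep) < 2) stop("time window contains fewer than 2 samples")
  P <- (trace$fluorescence_au[keep] - curve$intercept) / curve$slope
  slope_M_min <- unname(stats::coef(stats::lm(P ~ t[keep]))[2])
  slope_M_min * volume / enzyme_mass_mg
}
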
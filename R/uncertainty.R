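#' 1D parameter confidence interval
#'
#' A published one-dimensional maximum-likelihood confidence interval for a
#' single NTCP model parameter, carrying its confidence level as data (levels
#' differ between source studies and are never assumed).
#'
#' @param low,high interval endpoints in the parameter's units
#'   (`low <= high`; equal endpoints give a degenerate, zero-width interval).
#' @param confidence_level fraction in (0, 1), e.g. 0.68 or 0.95.
#' @return An object of class `parameter_interval`.
#' @export
parameter_interval <- function(low, high, confidence_level = 0.95) {
  if (!is.numeric(low) || !is.numeric(high) || low > high)
    stop("need numeric `low` <= `high`", call. = FALSE)
  if (confidence_level <= 0 || confidence_level >= 1)
    stop("`confidence_level` must lie in (0, 1)", call. = FALSE)
  structure(list(low = as.numeric(low), high = as.numeric(high),
                 confidence_level = confidence_level),
            class = "parameter_interval")
}

#' @export
print.parameter_interval <- function(x, ...) {
  cat(sprintf("<parameter_interval> [%g, %g] at %g%% confidence\n",
              x$low, x$high, 100 * x$confidence_level))
  invisible(x)
}

interval_grid <- function(interval, k) {
  if (interval$low == interval$high) return(interval$low)
  if (k < 2L)
    stop("`grid_points_per_axis` must be >= 2 for a non-degenerate interval",
         call. = FALSE)
  seq(interval$low, interval$high, length.out = k)
}

# uniform-dose NTCP over a (d50, slope) grid at one dose; returns matrix
uniform_ntcp_grid <- function(model, dose, d50s, slopes, convention) {
  if (model == "LKB") {
    outer(d50s, slopes, function(d50, m) stats::pnorm((dose - d50) / (m * d50)))
  } else {
    outer(d50s, slopes, function(d50, g)
      2^(-exp(rs_slope_multiplier(g, convention) * (1 - dose / d50))))
  }
}

#' NTCP-vs-EUD confidence band from 1D parameter intervals
#'
#' Propagates published 1D confidence intervals for `D50` and the slope
#' (`m` or `gamma`) into a band around the uniform-dose NTCP curve: a
#' rectangular grid over the two intervals is searched for the minimum and
#' maximum NTCP at every EUD value. The tissue-architecture parameter `n`/`s`
#' is not varied. Because the rectangle ignores parameter correlation, the
#' band can slightly under- or overestimate a joint confidence region; that
#' caveat is recorded in the returned object's `note`.
#'
#' @param model `"LKB"` or `"RS"`.
#' @param d50_interval,slope_interval [parameter_interval] objects for `D50`
#'   (Gy) and the slope parameter.
#' @param fixed_volume_param the `n`/`s` value of the parameter set (carried
#'   as metadata; uniform-dose response does not depend on it).
#' @param eud_grid positive increasing EUD values (Gy) at which to evaluate.
#' @param grid_points_per_axis grid resolution per parameter axis
#'   (default 101).
#' @param convention RS slope convention, see [rs_uniform_response()].
#' @return An object of class `confidence_band`: list with `eud_grid`,
#'   `ntcp_low`, `ntcp_center`, `ntcp_high`, `model`, `center_params`,
#'   `levels`, `note`. The center curve uses the interval midpoints.
#' @examples
#' b <- ntcp_confidence_band("LKB", parameter_interval(28, 32, 0.68),
#'                           parameter_interval(0.3, 0.45, 0.68),
#'                           fixed_volume_param = 0.99,
#'                           eud_grid = seq(5, 60, by = 5))
#' head(as.data.frame(b))
#' @export
ntcp_confidence_band <- function(model = c("LKB", "RS"), d50_interval,
                                 slope_interval, fixed_volume_param,
                                 eud_grid, grid_points_per_axis = 101L,
                                 convention = c("kallman", "expgamma")) {
  model <- match.arg(model)
  convention <- match.arg(convention)
  stopifnot(inherits(d50_interval, "parameter_interval"),
            inherits(slope_interval, "parameter_interval"))
  if (any(eud_grid <= 0) || is.unsorted(eud_grid, strictly = TRUE))
    stop("`eud_grid` must be positive and strictly increasing", call. = FALSE)
  d50s <- interval_grid(d50_interval, grid_points_per_axis)
  slopes <- interval_grid(slope_interval, grid_points_per_axis)
  c_d50 <- (d50_interval$low + d50_interval$high) / 2
  c_slope <- (slope_interval$low + slope_interval$high) / 2
  lo <- hi <- ctr <- numeric(length(eud_grid))
  for (i in seq_along(eud_grid)) {
    grid <- uniform_ntcp_grid(model, eud_grid[i], d50s, slopes, convention)
    lo[i] <- min(grid)
    hi[i] <- max(grid)
    ctr[i] <- uniform_ntcp_grid(model, eud_grid[i], c_d50, c_slope,
                                convention)[1L, 1L]
  }
  new_confidence_band(eud_grid, lo, ctr, hi, model,
                      center = c(d50 = c_d50, slope = c_slope,
                                 fixed = fixed_volume_param),
                      levels = c(d50 = d50_interval$confidence_level,
                                 slope = slope_interval$confidence_level))
}

new_confidence_band <- function(eud_grid, lo, ctr, hi, model, center, levels) {
  structure(
    list(eud_grid = eud_grid, ntcp_low = lo, ntcp_center = ctr,
         ntcp_high = hi, model = model, center_params = center,
         levels = levels,
         note = paste("rectangular 1D-interval propagation; joint parameter",
                      "correlation not modelled, band may slightly under- or",
                      "overestimate a joint confidence region")),
    class = "confidence_band"
  )
}

#' @export
print.confidence_band <- function(x, ...) {
  cat(sprintf(
    "<confidence_band> %s model, %d EUD points (%.3g-%.3g Gy), max width %.3g\n",
    x$model, length(x$eud_grid), min(x$eud_grid), max(x$eud_grid),
    max(x$ntcp_high - x$ntcp_low)))
  invisible(x)
}

#' @export
as.data.frame.confidence_band <- function(x, ...) {
  data.frame(eud_gy = x$eud_grid, ntcp_low = x$ntcp_low,
             ntcp_center = x$ntcp_center, ntcp_high = x$ntcp_high)
}

#' Confidence band evaluated on actual DVHs
#'
#' For heterogeneous irradiation (notably under the RS model) the NTCP
#' uncertainty computed for a homogeneous dose does not necessarily transfer
#' to every DVH with the same EUD. This variant computes, for each supplied
#' DVH, the min/max full-DVH NTCP over the parameter rectangle, and indexes
#' the result by that DVH's EUD (LKB: the gEUD with the center `n`; RS: the
#' uniform dose reproducing the center-parameter NTCP).
#'
#' @inheritParams ntcp_confidence_band
#' @param dvh_series list of [dvh] objects.
#' @return A `confidence_band` whose `eud_grid` holds each DVH's EUD, in
#'   input order (not necessarily sorted).
#' @export
band_for_dvh_series <- function(dvh_series, model = c("LKB", "RS"),
                                d50_interval, slope_interval,
                                fixed_volume_param,
                                grid_points_per_axis = 101L,
                                convention = c("kallman", "expgamma")) {
  model <- match.arg(model)
  convention <- match.arg(convention)
  if (is_dvh(dvh_series)) dvh_series <- list(dvh_series)
  stopifnot(all(vapply(dvh_series, is_dvh, TRUE)))
  d50s <- interval_grid(d50_interval, grid_points_per_axis)
  slopes <- interval_grid(slope_interval, grid_points_per_axis)
  c_d50 <- (d50_interval$low + d50_interval$high) / 2
  c_slope <- (slope_interval$low + slope_interval$high) / 2
  m <- length(dvh_series)
  lo <- hi <- ctr <- eud <- numeric(m)
  for (i in seq_len(m)) {
    dd <- dvh_series[[i]]
    if (model == "LKB") {
      e <- eud_lkb(dd, fixed_volume_param)
      vals <- outer(d50s, slopes, function(d50, mm)
        stats::pnorm((e - d50) / (mm * d50)))
      ctr[i] <- stats::pnorm((e - c_d50) / (c_slope * c_d50))
      eud[i] <- e
    } else {
      vals <- matrix(NA_real_, length(d50s), length(slopes))
      for (a in seq_along(d50s)) for (b in seq_along(slopes))
        vals[a, b] <- ntcp_rs(dd, rs_parameters(d50s[a], slopes[b],
                                                fixed_volume_param),
                              convention = convention)
      cpars <- rs_parameters(c_d50, c_slope, fixed_volume_param)
      ctr[i] <- ntcp_rs(dd, cpars, convention = convention)
      eud[i] <- if (ctr[i] > 0 && ctr[i] < 1)
        eud_rs(ctr[i], cpars, convention = convention) else NA_real_
    }
    lo[i] <- min(vals)
    hi[i] <- max(vals)
  }
  new_confidence_band(eud, lo, ctr, hi, model,
                      center = c(d50 = c_d50, slope = c_slope,
                                 fixed = fixed_volume_param),
                      levels = c(d50 = d50_interval$confidence_level,
                                 slope = slope_interval$confidence_level))
}

#' Write a confidence band as a plotting-ready table
#'
#' Tab-separated columns `eud_gy`, `ntcp_low`, `ntcp_center`, `ntcp_high`.
#'
#' @param band a `confidence_band`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_band <- function(band, path) {
  stopifnot(inherits(band, "confidence_band"))
  utils::write.table(as.data.frame(band), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
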
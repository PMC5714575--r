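#' Dose-volume histogram objects
#'
#' A `dvh` stores one structure's dose-volume histogram as parallel vectors of
#' bin doses (Gy, strictly increasing) and relative volumes (fraction of the
#' structure volume, 0-1). Two kinds exist: `"cumulative"` (volume receiving at
#' least each dose; non-increasing, starting at 1) and `"differential"`
#' (fractional volume `v_i` receiving approximately each bin dose `D_i`;
#' non-negative, summing to 1). The differential representation is the one the
#' dose-response models consume; conversions are exact finite differences with
#' the convention that the volume of a cumulative step is attributed to its
#' lower-edge dose.
#'
#' Export rounding in treatment planning systems can leave a cumulative curve
#' very slightly non-monotone; violations up to `1e-6` are repaired by clipping
#' (with a warning), larger violations are errors.
#'
#' @param dose numeric vector of bin doses in Gy, strictly increasing, >= 0.
#' @param volume numeric vector of relative volumes, same length as `dose`.
#' @param kind `"cumulative"` or `"differential"`.
#' @param structure character label for the structure (e.g. `"lung_paired"`).
#' @return An object of class `dvh`: a list with elements `structure`, `kind`,
#'   `dose`, `volume`.
#' @examples
#' d <- dvh(c(0, 10, 20), c(1, 0.4, 0), kind = "cumulative")
#' as_differential(d)
#' mean_dose(d)
#' @export
dvh <- function(dose, volume, kind = c("cumulative", "differential"),
                structure = "structure") {
  kind <- match.arg(kind)
  dose <- as.numeric(dose)
  volume <- as.numeric(volume)
  if (length(dose) != length(volume))
    stop("`dose` and `volume` must have the same length", call. = FALSE)
  if (length(dose) < 1L)
    stop("a DVH needs at least one bin", call. = FALSE)
  if (anyNA(dose) || anyNA(volume))
    stop("DVH for '", structure, "' contains missing values", call. = FALSE)
  if (any(dose < 0))
    stop("DVH for '", structure, "' has negative bin doses", call. = FALSE)
  if (is.unsorted(dose, strictly = TRUE))
    stop("DVH bin doses for '", structure, "' must be strictly increasing",
         call. = FALSE)

  if (kind == "cumulative") {
    inc <- diff(volume)
    if (any(inc > 1e-6))
      stop("cumulative DVH for '", structure,
           "' has increasing volume beyond tolerance (max increase ",
           format(max(inc)), ")", call. = FALSE)
    if (abs(volume[1L] - 1) > 1e-9)
      stop("cumulative DVH for '", structure,
           "' must start at relative volume 1 (whole structure receives >= 0 Gy)",
           call. = FALSE)
    if (any(inc > 0)) {
      warning("cumulative DVH for '", structure,
              "' repaired: monotonicity violations <= 1e-6 clipped",
              call. = FALSE)
      volume <- cummin(volume)
    }
    if (any(volume < -1e-9) || any(volume > 1 + 1e-9))
      stop("cumulative DVH volumes for '", structure, "' outside [0, 1]",
           call. = FALSE)
    volume <- pmin(pmax(volume, 0), 1)
  } else {
    if (any(volume < -1e-9))
      stop("differential DVH for '", structure, "' has negative volumes",
           call. = FALSE)
    volume <- pmax(volume, 0)
    if (abs(sum(volume) - 1) > 1e-6)
      stop("differential DVH volumes for '", structure,
           "' must sum to 1 (got ", format(sum(volume)), ")", call. = FALSE)
  }

  structure(
    list(structure = as.character(structure)[1L], kind = kind,
         dose = dose, volume = volume),
    class = "dvh"
  )
}

#' @export
print.dvh <- function(x, ...) {
  cat(sprintf("<dvh> %s (%s), %d bins, %.6g-%.6g Gy, mean dose %.4g Gy\n",
              x$structure, x$kind, length(x$dose),
              min(x$dose), max(x$dose), mean_dose(x)))
  invisible(x)
}

#' @export
format.dvh <- function(x, ...) {
  sprintf("<dvh %s/%s/%d bins>", x$structure, x$kind, length(x$dose))
}

is_dvh <- function(x) inherits(x, "dvh")

stopifnot_dvh <- function(x, arg = "dvh") {
  if (!is_dvh(x))
    stop("`", arg, "` must be a dvh object (see ?dvh)", call. = FALSE)
  invisible(x)
}

#' Convert between cumulative and differential DVH representations
#'
#' `as_differential()` differences a cumulative curve:
#' `v_i = V(D_i) - V(D_{i+1})`, the last bin keeping the residual volume
#' `V(D_M)`, so total volume is conserved exactly. `as_cumulative()` is the
#' inverse (reverse cumulative sum). Both are the identity on input already of
#' the requested kind.
#'
#' @param dvh a [dvh] object.
#' @return A [dvh] of the requested kind with the same bin doses.
#' @examples
#' d <- dvh(c(0, 10, 20), c(1, 0.4, 0), kind = "cumulative")
#' as_differential(d)$volume  # 0.6 0.4 0.0
#' @export
as_differential <- function(dvh) {
  stopifnot_dvh(dvh)
  if (dvh$kind == "differential") return(dvh)
  v <- c(-diff(dvh$volume), dvh$volume[length(dvh$volume)])
  out <- dvh
  out$kind <- "differential"
  out$volume <- v
  out
}

#' @rdname as_differential
#' @export
as_cumulative <- function(dvh) {
  stopifnot_dvh(dvh)
  if (dvh$kind == "cumulative") return(dvh)
  v <- rev(cumsum(rev(dvh$volume)))
  out <- dvh
  out$kind <- "cumulative"
  out$volume <- v
  out
}

#' Fractionation scheme for LQ (EQD2) correction
#'
#' Describes how a physical total dose was delivered, for conversion to the
#' equi-effective dose in 2 Gy fractions under the linear-quadratic model.
#'
#' @param n_fractions positive integer, number of fractions over which each
#'   bin's total dose was delivered.
#' @param alpha_beta tissue alpha/beta ratio in Gy (lung pneumonitis
#'   conventionally 3 Gy).
#' @param reference_dose_per_fraction reference fraction size in Gy
#'   (default 2, giving EQD2).
#' @return An object of class `fractionation_scheme`.
#' @examples
#' fractionation_scheme(20, alpha_beta = 3)
#' @export
fractionation_scheme <- function(n_fractions, alpha_beta = 3,
                                 reference_dose_per_fraction = 2) {
  n_fractions <- as.integer(n_fractions)
  if (is.na(n_fractions) || n_fractions < 1L)
    stop("`n_fractions` must be a positive integer", call. = FALSE)
  if (!is.numeric(alpha_beta) || alpha_beta <= 0)
    stop("`alpha_beta` must be > 0 Gy", call. = FALSE)
  if (!is.numeric(reference_dose_per_fraction) || reference_dose_per_fraction <= 0)
    stop("`reference_dose_per_fraction` must be > 0 Gy", call. = FALSE)
  structure(
    list(n_fractions = n_fractions, alpha_beta = alpha_beta,
         reference_dose_per_fraction = reference_dose_per_fraction),
    class = "fractionation_scheme"
  )
}

#' @export
print.fractionation_scheme <- function(x, ...) {
  cat(sprintf(
    "<fractionation_scheme> %d fractions, alpha/beta = %g Gy, reference d = %g Gy\n",
    x$n_fractions, x$alpha_beta, x$reference_dose_per_fraction))
  invisible(x)
}

#' LQ fractionation correction of a DVH (EQD2)
#'
#' Maps each bin's total physical dose `D` to the equi-effective dose in
#' fractions of the reference size under the linear-quadratic model,
#' `EQD2 = D * (d + alpha/beta) / (d_ref + alpha/beta)` with per-bin dose per
#' fraction `d = D / n_fractions`. Volumes are unchanged. The mapping is
#' strictly increasing for `D >= 0`, so bin ordering is preserved; it is the
#' identity for bins delivered at exactly the reference fraction size.
#'
#' @param dvh a [dvh] (either kind); bin doses are total course doses.
#' @param scheme a [fractionation_scheme].
#' @return A [dvh] of the same kind with EQD2 bin doses.
#' @examples
#' d <- dvh(c(0, 10, 40), c(0.2, 0.3, 0.5), kind = "differential")
#' eqd2_transform(d, fractionation_scheme(20, alpha_beta = 3))$dose
#' # 0, 10*(0.5+3)/5 = 7, 40 (2 Gy/fraction maps to itself)
#' @export
eqd2_transform <- function(dvh, scheme) {
  stopifnot_dvh(dvh)
  if (!inherits(scheme, "fractionation_scheme"))
    stop("`scheme` must be a fractionation_scheme", call. = FALSE)
  d_fx <- dvh$dose / scheme$n_fractions
  out <- dvh
  out$dose <- dvh$dose * (d_fx + scheme$alpha_beta) /
    (scheme$reference_dose_per_fraction + scheme$alpha_beta)
  out
}

#' Mean dose of a DVH
#'
#' Volume-weighted mean `sum(v_i * D_i)` over the differential representation;
#' for a lung DVH this is the mean lung dose (MLD). Invariant under
#' cumulative/differential conversion.
#'
#' @param dvh a [dvh] of either kind.
#' @return Mean dose in Gy.
#' @export
mean_dose <- function(dvh) {
  d <- as_differential(dvh)
  sum(d$volume * d$dose)
}

#' Rebin a DVH onto a new dose grid
#'
#' Linear interpolation of the cumulative curve at the requested bin doses.
#' DVHs from different planning systems are never resampled implicitly; this
#' is the explicit step to bring them onto a common grid.
#'
#' @param dvh a [dvh].
#' @param dose new strictly increasing dose grid (Gy). Doses beyond the
#'   original range extrapolate flat (volume 1 below, 0 above the last bin).
#' @return A cumulative [dvh] on the new grid.
#' @export
rebin_dvh <- function(dvh, dose) {
  cum <- as_cumulative(dvh)
  if (is.unsorted(dose, strictly = TRUE) || any(dose < 0))
    stop("`dose` must be a strictly increasing non-negative grid", call. = FALSE)
  v <- stats::approx(cum$dose, cum$volume, xout = dose, method = "linear",
                     yleft = 1, yright = 0, ties = "ordered")$y
  dvh(dose, v, kind = "cumulative", structure = cum$structure)
}

#' Volume receiving at least a given dose
#'
#' The classic Vx metric: relative volume receiving `>= dose` Gy, by linear
#' interpolation of the cumulative curve.
#'
#' @param dvh a [dvh].
#' @param dose dose threshold(s) in Gy.
#' @return Relative volume(s) in 0-1.
#' @export
volume_at_dose <- function(dvh, dose) {
  cum <- as_cumulative(dvh)
  stats::approx(cum$dose, cum$volume, xout = dose, method = "linear",
                yleft = 1, yright = 0, ties = "ordered")$y
}
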
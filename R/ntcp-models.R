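#' NTCP model parameter triples
#'
#' `lkb_parameters()` holds the Lyman-Kutcher-Burman triple `[D50, m, n]`:
#' `d50` is the uniform dose giving 50% complication probability (Gy), `m` the
#' normalized probit slope, and `n` the volume-effect exponent used in the EUD
#' reduction (`n = 1`: mean-dose organ, fully parallel; `n -> 0`: serial).
#'
#' `rs_parameters()` holds the relative seriality triple `[D50, gamma, s]`:
#' `gamma` is the normalized maximum dose-response gradient and `s` the
#' seriality (`s -> 0`: parallel organ, `s = 1`: serial).
#'
#' @param d50 dose for 50% response, Gy (> 0).
#' @param m LKB slope parameter (> 0).
#' @param n LKB volume-effect exponent (0 < n <= 1.5).
#' @return An object of class `lkb_parameters` or `rs_parameters`.
#' @examples
#' lkb_parameters(30.8, 0.37, 0.99)
#' rs_parameters(34, 0.9, 0.06)
#' @export
lkb_parameters <- function(d50, m, n) {
  if (!is.numeric(d50) || d50 <= 0) stop("`d50` must be > 0 Gy", call. = FALSE)
  if (!is.numeric(m) || m <= 0) stop("`m` must be > 0", call. = FALSE)
  if (!is.numeric(n) || n <= 0 || n > 1.5)
    stop("`n` must lie in (0, 1.5]", call. = FALSE)
  structure(list(d50 = as.numeric(d50), m = as.numeric(m), n = as.numeric(n)),
            class = "lkb_parameters")
}

#' @rdname lkb_parameters
#' @param gamma RS normalized slope (> 0).
#' @param s RS seriality parameter (> 0).
#' @export
rs_parameters <- function(d50, gamma, s) {
  if (!is.numeric(d50) || d50 <= 0) stop("`d50` must be > 0 Gy", call. = FALSE)
  if (!is.numeric(gamma) || gamma <= 0) stop("`gamma` must be > 0", call. = FALSE)
  if (!is.numeric(s) || s <= 0) stop("`s` must be > 0", call. = FALSE)
  structure(list(d50 = as.numeric(d50), gamma = as.numeric(gamma),
                 s = as.numeric(s)),
            class = "rs_parameters")
}

#' @export
print.lkb_parameters <- function(x, ...) {
  cat(sprintf("<lkb_parameters> D50 = %g Gy, m = %g, n = %g\n", x$d50, x$m, x$n))
  invisible(x)
}

#' @export
print.rs_parameters <- function(x, ...) {
  cat(sprintf("<rs_parameters> D50 = %g Gy, gamma = %g, s = %g\n",
              x$d50, x$gamma, x$s))
  invisible(x)
}

#' Generalized EUD of a DVH (LKB / Niemierko reduction)
#'
#' `EUD = (sum_i v_i * D_i^(1/n))^n` over the differential DVH. Equals the
#' mean dose when `n = 1` and the delivered dose for uniform whole-volume
#' irradiation for any `n`. Lies between the smallest and largest bin dose
#' with nonzero volume.
#'
#' @param dvh a [dvh] (converted to differential as needed).
#' @param n volume-effect exponent, > 0.
#' @return EUD in Gy.
#' @export
eud_lkb <- function(dvh, n) {
  if (!is.numeric(n) || length(n) != 1L || n <= 0)
    stop("`n` must be a single value > 0", call. = FALSE)
  d <- as_differential(dvh)
  sum(d$volume * d$dose^(1 / n))^n
}

#' LKB NTCP from an EUD
#'
#' The probit dose response `NTCP = Phi(t)` with
#' `t = (EUD - D50) / (m * D50)`, `Phi` the standard normal CDF (computed via
#' the complementary error function in [stats::pnorm()], not by numerical
#' integration). Strictly increasing in `eud`, strictly decreasing in `d50`
#' at fixed EUD.
#'
#' @param eud equivalent uniform dose, Gy (vectorized).
#' @param params an [lkb_parameters] object.
#' @return NTCP as a probability in (0, 1).
#' @examples
#' p <- lkb_parameters(30.8, 0.37, 0.99)
#' ntcp_lkb(30.8, p)                 # 0.5
#' ntcp_lkb(30.8 * 1.37, p)          # pnorm(1)
#' @export
ntcp_lkb <- function(eud, params) {
  stopifnot(inherits(params, "lkb_parameters"))
  if (any(eud < 0)) stop("`eud` must be >= 0 Gy", call. = FALSE)
  stats::pnorm((eud - params$d50) / (params$m * params$d50))
}

#' LKB NTCP of a DVH
#'
#' Composition of the EUD reduction and the probit response:
#' `ntcp_lkb(eud_lkb(dvh, params$n), params)`.
#'
#' @inheritParams ntcp_lkb
#' @param dvh a [dvh].
#' @return NTCP in (0, 1).
#' @export
ntcp_lkb_dvh <- function(dvh, params) {
  stopifnot(inherits(params, "lkb_parameters"))
  ntcp_lkb(eud_lkb(dvh, params$n), params)
}

#' Uniform-dose response of the relative seriality model
#'
#' The Poisson-type response to homogeneous whole-volume irradiation,
#' `P(D) = 2^(-exp(e * gamma * (1 - D/D50)))` in the Kallman convention where
#' the slope multiplier is the product of Euler's number and `gamma`
#' (`convention = "kallman"`, the default). The printed form of this response
#' is ambiguous in parts of the literature; `convention = "expgamma"` instead
#' uses `exp(gamma)` as the multiplier. `P(D50) = 0.5` exactly under either
#' convention, and `P` is strictly increasing in dose.
#'
#' @param dose dose in Gy (vectorized, >= 0).
#' @param params an [rs_parameters] object.
#' @param convention slope-multiplier convention, `"kallman"` (e * gamma) or
#'   `"expgamma"` (e^gamma).
#' @return Response probability in (0, 1).
#' @export
rs_uniform_response <- function(dose, params,
                                convention = c("kallman", "expgamma")) {
  stopifnot(inherits(params, "rs_parameters"))
  convention <- match.arg(convention)
  if (any(dose < 0)) stop("`dose` must be >= 0 Gy", call. = FALSE)
  k <- rs_slope_multiplier(params$gamma, convention)
  2^(-exp(k * (1 - dose / params$d50)))
}

rs_slope_multiplier <- function(gamma, convention) {
  switch(convention, kallman = exp(1) * gamma, expgamma = exp(gamma))
}

#' Relative seriality NTCP of a DVH
#'
#' `NTCP = (1 - prod_i (1 - P(D_i)^s)^(v_i))^(1/s)` over the `M` differential
#' bins, with `P` the uniform-dose response of [rs_uniform_response()]. For a
#' uniform whole-volume dose the expression collapses to `P(D)`.
#'
#' Evaluated in log space: the product is accumulated as
#' `sum_i v_i * log(1 - P_i^s)` using `log(1 - e^x)` computed stably, because
#' small seriality (`s << 1`, a parallel organ) drives `P^s` to 1 and the
#' naive product underflows.
#'
#' @param dvh a [dvh].
#' @param params an [rs_parameters].
#' @inheritParams rs_uniform_response
#' @return NTCP in \[0, 1\].
#' @export
ntcp_rs <- function(dvh, params, convention = c("kallman", "expgamma")) {
  stopifnot(inherits(params, "rs_parameters"))
  convention <- match.arg(convention)
  d <- as_differential(dvh)
  keep <- d$volume > 0
  dose <- d$dose[keep]
  v <- d$volume[keep]
  k <- rs_slope_multiplier(params$gamma, convention)
  # log P(D_i) = -exp(k (1 - D/D50)) * log 2, always <= 0
  logp <- -exp(k * (1 - dose / params$d50)) * log(2)
  # log(1 - P^s) with P^s = exp(s * log P)
  a <- sum(v * log1mexp(params$s * logp))
  if (a == 0) return(0)
  # NTCP = (1 - e^a)^(1/s)
  exp(log1mexp(a) / params$s)
}

# log(1 - exp(a)) for a <= 0, numerically stable on both ends
log1mexp <- function(a) {
  out <- numeric(length(a))
  lo <- a < -log(2)
  out[lo] <- log1p(-exp(a[lo]))
  out[!lo] <- log(-expm1(a[!lo]))
  out
}

#' EUD under the relative seriality model (inverse uniform response)
#'
#' The uniform whole-volume dose that would produce a given NTCP: the exact
#' analytic inverse of [rs_uniform_response()],
#' `D = D50 * (1 - log(-log(ntcp)/log 2) / (e * gamma))`. Roundtrips with the
#' forward response to floating-point accuracy.
#'
#' @param ntcp probability strictly inside (0, 1) (vectorized).
#' @param params an [rs_parameters].
#' @inheritParams rs_uniform_response
#' @return EUD in Gy (can be negative for NTCP values below the zero-dose
#'   response, which no physical DVH produces).
#' @examples
#' p <- rs_parameters(34, 0.9, 0.06)
#' eud_rs(0.5, p)                                  # exactly d50
#' rs_uniform_response(eud_rs(0.1, p), p)          # 0.1
#' @export
eud_rs <- function(ntcp, params, convention = c("kallman", "expgamma")) {
  stopifnot(inherits(params, "rs_parameters"))
  convention <- match.arg(convention)
  if (any(ntcp <= 0 | ntcp >= 1))
    stop("`ntcp` must lie strictly inside (0, 1)", call. = FALSE)
  k <- rs_slope_multiplier(params$gamma, convention)
  params$d50 * (1 - log(-log(ntcp) / log(2)) / k)
}
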
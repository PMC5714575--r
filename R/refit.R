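#' Paired treatment-plan DVHs and cohorts
#'
#' A `plan_pair` holds one treatment plan's lung DVH calculated with two dose
#' calculation algorithms: the reference algorithm (for which published NTCP
#' parameters are assumed valid) and the target algorithm (for which new
#' parameters are sought). Both DVHs describe the same delivered plan — the
#' monitor units are shared — so they differ only through the dose engines.
#' DVHs are expected to be fractionation-corrected (EQD2) before model
#' evaluation; see [eqd2_transform()].
#'
#' @param plan_id plan identifier.
#' @param treatment_type `"Tang"`, `"LGL"` or `"Lung"`.
#' @param reference_dvh,target_dvh [dvh] objects for the two algorithms.
#' @param lung_volume `"paired"` or `"ipsilateral"` — which lung volume the
#'   DVHs describe.
#' @return An object of class `plan_pair`.
#' @export
plan_pair <- function(plan_id, treatment_type = c("Tang", "LGL", "Lung"),
                      reference_dvh, target_dvh,
                      lung_volume = c("paired", "ipsilateral")) {
  treatment_type <- match.arg(treatment_type)
  lung_volume <- match.arg(lung_volume)
  stopifnot_dvh(reference_dvh, "reference_dvh")
  stopifnot_dvh(target_dvh, "target_dvh")
  structure(
    list(plan_id = as.character(plan_id), treatment_type = treatment_type,
         lung_volume = lung_volume, reference_dvh = reference_dvh,
         target_dvh = target_dvh),
    class = "plan_pair"
  )
}

#' @export
print.plan_pair <- function(x, ...) {
  cat(sprintf(
    "<plan_pair> %s (%s, %s lung): MLD ref %.3g Gy -> target %.3g Gy\n",
    x$plan_id, x$treatment_type, x$lung_volume,
    mean_dose(x$reference_dvh), mean_dose(x$target_dvh)))
  invisible(x)
}

#' @rdname plan_pair
#' @param pairs list of `plan_pair` objects.
#' @param reference_label,target_label algorithm labels (e.g. `"PB"`, `"CC"`).
#' @param pooled set `TRUE` to allow mixing treatment types in one cohort;
#'   by default a cohort must be homogeneous, because refitted parameters are
#'   treatment-type specific.
#' @export
ntcp_cohort <- function(pairs, reference_label = "reference",
                        target_label = "target", pooled = FALSE) {
  if (inherits(pairs, "plan_pair")) pairs <- list(pairs)
  if (!length(pairs) || !all(vapply(pairs, inherits, TRUE, "plan_pair")))
    stop("`pairs` must be a non-empty list of plan_pair objects", call. = FALSE)
  types <- unique(vapply(pairs, `[[`, "", "treatment_type"))
  if (length(types) > 1L && !pooled)
    stop("cohort mixes treatment types (", paste(types, collapse = ", "),
         "); pass pooled = TRUE to pool explicitly", call. = FALSE)
  structure(
    list(pairs = pairs, reference_label = as.character(reference_label),
         target_label = as.character(target_label), pooled = isTRUE(pooled)),
    class = "ntcp_cohort"
  )
}

#' @export
print.ntcp_cohort <- function(x, ...) {
  types <- unique(vapply(x$pairs, `[[`, "", "treatment_type"))
  cat(sprintf("<ntcp_cohort> %d plans (%s), %s -> %s\n",
              length(x$pairs), paste(types, collapse = "+"),
              x$reference_label, x$target_label))
  invisible(x)
}

# NTCP of one DVH under either model, from raw parameter values
ntcp_dvh_value <- function(dvh, model, d50, slope, fixed, convention) {
  if (model == "LKB")
    ntcp_lkb_dvh(dvh, lkb_parameters(d50, slope, fixed))
  else
    ntcp_rs(dvh, rs_parameters(d50, slope, fixed), convention = convention)
}

# Fast sum-of-squares objective closure for a cohort + original set.
# Reference NTCPs are fixed by the original parameters; for LKB the target
# EUDs depend only on the fixed n, so they are precomputed once.
make_refit_objective <- function(cohort, original, convention = "kallman") {
  model <- original$model
  op <- original$parameters
  fixed <- if (model == "LKB") op$n else op$s
  ref_ntcp <- vapply(cohort$pairs, function(p)
    ntcp_dvh_value(p$reference_dvh, model,
                   op$d50, if (model == "LKB") op$m else op$gamma,
                   fixed, convention), numeric(1))
  if (model == "LKB") {
    euds <- vapply(cohort$pairs, function(p) eud_lkb(p$target_dvh, fixed),
                   numeric(1))
    function(d50, slope) {
      t <- (euds - d50) / (slope * d50)
      sum((stats::pnorm(t) - ref_ntcp)^2)
    }
  } else {
    targets <- lapply(cohort$pairs, `[[`, "target_dvh")
    function(d50, slope) {
      pars <- rs_parameters(d50, slope, fixed)
      ntcp <- vapply(targets, ntcp_rs, numeric(1), params = pars,
                     convention = convention)
      sum((ntcp - ref_ntcp)^2)
    }
  }
}

#' Refitting objective: sum of squared NTCP differences
#'
#' The quantity the refit minimizes: over all plans in the cohort, the sum of
#' squared differences between the NTCP computed on the target-algorithm DVH
#' with candidate `(D50, slope)` — the tissue-architecture parameter `n`
#' (LKB) or `s` (RS) held at the original value — and the NTCP computed on
#' the reference-algorithm DVH with the original parameters. Deterministic.
#'
#' @param cohort an [ntcp_cohort].
#' @param original a [parameter_set] assumed valid for the reference
#'   algorithm.
#' @param candidate_d50 candidate D50, Gy.
#' @param candidate_slope candidate slope (`m` for LKB, `gamma` for RS).
#' @param convention RS slope convention, see [rs_uniform_response()].
#' @return Non-negative sum of squared NTCP differences.
#' @export
refit_residual <- function(cohort, original, candidate_d50, candidate_slope,
                           convention = c("kallman", "expgamma")) {
  convention <- match.arg(convention)
  stopifnot(inherits(cohort, "ntcp_cohort"), inherits(original, "parameter_set"))
  if (candidate_d50 <= 0 || candidate_slope <= 0)
    stop("candidate parameters must be positive", call. = FALSE)
  make_refit_objective(cohort, original, convention)(candidate_d50,
                                                     candidate_slope)
}

#' Refit control settings
#'
#' @param restarts number of deterministically jittered Nelder-Mead restarts
#'   around the original parameters (in addition to the start at the
#'   originals themselves).
#' @param reltol relative convergence tolerance on the objective.
#' @param maxit maximum simplex iterations per start.
#' @param jitter relative size of the restart perturbations.
#' @return A list of class `refit_control`.
#' @export
refit_control <- function(restarts = 5L, reltol = 1e-12, maxit = 2000L,
                          jitter = 0.15) {
  structure(list(restarts = as.integer(restarts), reltol = reltol,
                 maxit = as.integer(maxit), jitter = jitter),
            class = "refit_control")
}

#' Derive algorithm-specific NTCP parameters by refitting
#'
#' Finds `(D50, slope)` such that NTCP computed on the cohort's
#' target-algorithm DVHs reproduces, in the least-squares sense, the NTCP
#' computed on the reference-algorithm DVHs with the original published
#' parameters. The tissue-architecture parameter (`n` for LKB, `s` for RS) is
#' held at its original value structurally — it is never a free parameter.
#'
#' Optimization is a derivative-free Nelder-Mead simplex on the log of the
#' two free parameters (enforcing positivity), started at the original values
#' plus a fixed set of jittered restarts; the best solution is polished with
#' one further simplex run. The residual at the returned parameters never
#' exceeds the residual at the originals (the originals are one of the
#' candidate solutions).
#'
#' @inheritParams refit_residual
#' @param control a [refit_control] list.
#' @return An object of class `refit_result` with elements `model`,
#'   `original`, `fitted_d50`, `fitted_slope`, `fixed_volume_param`,
#'   `se_d50`/`se_slope` (`NA` until [estimate_standard_errors()] is run),
#'   `residual_rss`, `residual_rss_original`, `converged`, `n_plans`,
#'   `convention`.
#' @examples
#' tpl <- treatment_template_preset("Tang")
#' eff <- algorithm_effect_preset("PB-CC", "Tang")
#' coh <- generate_cohort(tpl, eff, n_plans = 10, seed = 7)
#' refit_parameters(coh, ntcp_parameter_sets("seppenwoolde_lkb"))
#' @export
refit_parameters <- function(cohort, original,
                             control = refit_control(),
                             convention = c("kallman", "expgamma")) {
  convention <- match.arg(convention)
  stopifnot(inherits(cohort, "ntcp_cohort"), inherits(original, "parameter_set"))
  if (length(cohort$pairs) < 2L)
    stop("refitting two parameters requires a cohort of at least 2 plans",
         call. = FALSE)
  model <- original$model
  op <- original$parameters
  start <- c(op$d50, if (model == "LKB") op$m else op$gamma)
  fixed <- if (model == "LKB") op$n else op$s
  obj <- make_refit_objective(cohort, original, convention)
  fn <- function(lt) obj(exp(lt[1L]), exp(lt[2L]))

  # start at the originals plus fixed multiplicative jitters: deterministic,
  # so refits are reproducible and invariant to plan order
  j <- control$jitter
  starts <- rbind(
    c(1, 1),
    c(1 - j, 1), c(1 + j, 1), c(1, 1 + j),
    c(1 - j, 1 + j), c(1 + j, 1 - j)
  )[seq_len(1L + control$restarts), , drop = FALSE]

  best <- list(par = log(start), value = obj(start[1L], start[2L]),
               convergence = 0L)
  for (i in seq_len(nrow(starts))) {
    fit <- stats::optim(log(start * starts[i, ]), fn, method = "Nelder-Mead",
                        control = list(reltol = control$reltol,
                                       maxit = control$maxit))
    if (fit$value < best$value) best <- fit
  }
  # polish: restart the simplex at the incumbent to escape premature collapse
  polish <- stats::optim(best$par, fn, method = "Nelder-Mead",
                         control = list(reltol = control$reltol,
                                        maxit = control$maxit))
  if (polish$value < best$value) best <- polish

  rss0 <- obj(start[1L], start[2L])
  fitted <- exp(best$par)
  converged <- isTRUE(best$convergence == 0L) || best$value <= 1e-12
  if (!converged)
    warning("refit did not report convergence after ", nrow(starts),
            " starts; inspect `residual_rss`", call. = FALSE)
  structure(
    list(model = model, original = original,
         fitted_d50 = fitted[1L], fitted_slope = fitted[2L],
         fixed_volume_param = fixed,
         se_d50 = NA_real_, se_slope = NA_real_,
         residual_rss = best$value, residual_rss_original = rss0,
         converged = converged, n_plans = length(cohort$pairs),
         reference_label = cohort$reference_label,
         target_label = cohort$target_label,
         convention = convention),
    class = "refit_result"
  )
}

#' @export
print.refit_result <- function(x, ...) {
  slope_name <- if (x$model == "LKB") "m" else "gamma"
  fixed_name <- if (x$model == "LKB") "n" else "s"
  se <- function(v) if (is.na(v)) "" else sprintf(" +/- %.3g", v)
  cat(sprintf("<refit_result> %s, %s -> %s, %d plans\n",
              x$model, x$reference_label, x$target_label, x$n_plans))
  cat(sprintf("  D50 = %.4g%s Gy  (original %.4g)\n", x$fitted_d50,
              se(x$se_d50), x$original$parameters$d50))
  cat(sprintf("  %s   = %.4g%s     (original %.4g)\n", slope_name,
              x$fitted_slope, se(x$se_slope),
              if (x$model == "LKB") x$original$parameters$m
              else x$original$parameters$gamma))
  cat(sprintf("  %s fixed at %.4g; RSS %.3g (original %.3g); converged: %s\n",
              fixed_name, x$fixed_volume_param, x$residual_rss,
              x$residual_rss_original, x$converged))
  invisible(x)
}

#' Standard errors of refitted parameters
#'
#' Two estimators for the purely mathematical uncertainty introduced by the
#' refitting procedure (not the clinical uncertainty of the original
#' parameters):
#'
#' * `"bootstrap"`: resample plans with replacement `n_boot` times, refit
#'   each resample, and report the standard deviation of the fitted
#'   parameters across resamples (a 68%-level, one-standard-error measure).
#' * `"jacobian"`: asymptotic errors from the curvature of the least-squares
#'   objective at the optimum — `cov = sigma^2 (J'J)^{-1}` with `J` the
#'   numerical Jacobian of per-plan NTCP residuals and
#'   `sigma^2 = RSS / (N - 2)`.
#'
#' @inheritParams refit_residual
#' @param result a converged [refit_result] for this cohort/original.
#' @param method `"bootstrap"` or `"jacobian"`.
#' @param n_boot bootstrap resamples (default 200; below 20 a warning is
#'   issued).
#' @param seed integer seed for the bootstrap resampling (recorded in the
#'   output; same seed, same inputs give identical SEs).
#' @return A list with `se_d50`, `se_slope`, `method`, and for the bootstrap
#'   `n_boot`, `seed` and the matrix of resampled fits (`samples`).
#' @export
estimate_standard_errors <- function(cohort, original, result,
                                     method = c("bootstrap", "jacobian"),
                                     n_boot = 200L, seed = 1L,
                                     convention = c("kallman", "expgamma")) {
  method <- match.arg(method)
  convention <- match.arg(convention)
  stopifnot(inherits(result, "refit_result"))
  if (!isTRUE(result$converged))
    stop("standard errors require a converged refit result", call. = FALSE)

  if (method == "jacobian") {
    model <- original$model
    op <- original$parameters
    fixed <- result$fixed_volume_param
    ref_ntcp <- vapply(cohort$pairs, function(p)
      ntcp_dvh_value(p$reference_dvh, model, op$d50,
                     if (model == "LKB") op$m else op$gamma,
                     fixed, convention), numeric(1))
    rfun <- function(theta) {
      vapply(cohort$pairs, function(p)
        ntcp_dvh_value(p$target_dvh, model, theta[1L], theta[2L],
                       fixed, convention), numeric(1)) - ref_ntcp
    }
    theta <- c(result$fitted_d50, result$fitted_slope)
    J <- pracma::jacobian(rfun, theta)
    n <- length(cohort$pairs)
    sigma2 <- result$residual_rss / max(1L, n - 2L)
    jtj <- crossprod(J)
    cov <- tryCatch(sigma2 * solve(jtj),
                    error = function(e) sigma2 * pracma::pinv(jtj))
    se <- sqrt(pmax(diag(cov), 0))
    return(list(se_d50 = se[1L], se_slope = se[2L], method = "jacobian"))
  }

  if (n_boot < 20L)
    warning("n_boot = ", n_boot, " is below the recommended minimum of 20",
            call. = FALSE)
  n <- length(cohort$pairs)
  # resamples start near the fitted optimum; a light control is enough
  ctrl <- refit_control(restarts = 1L, reltol = 1e-10, maxit = 1000L,
                        jitter = 0.05)
  fitted_set <- original
  fitted_set$parameters <- if (original$model == "LKB")
    lkb_parameters(result$fitted_d50, result$fitted_slope,
                   result$fixed_volume_param)
  else
    rs_parameters(result$fitted_d50, result$fitted_slope,
                  result$fixed_volume_param)
  samples <- withr::with_seed(as.integer(seed), {
    t(vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      coh_b <- ntcp_cohort(cohort$pairs[idx], cohort$reference_label,
                           cohort$target_label, pooled = TRUE)
      # original parameter set still defines the reference NTCPs; start the
      # search from the full-cohort fit
      fit_b <- refit_from(coh_b, original, start_at = fitted_set,
                          control = ctrl, convention = convention)
      c(fit_b$fitted_d50, fit_b$fitted_slope)
    }, numeric(2)))
  })
  se_d50 <- stats::sd(samples[, 1L])
  se_slope <- stats::sd(samples[, 2L])
  if (se_d50 == 0 && se_slope == 0)
    message("all bootstrap resamples refit to identical parameters; ",
            "standard errors are zero")
  list(se_d50 = se_d50, se_slope = se_slope, method = "bootstrap",
       n_boot = n_boot, seed = as.integer(seed), samples = samples)
}

# refit with a custom starting point (bootstrap helper): same machinery as
# refit_parameters but the simplex starts at `start_at`'s values
refit_from <- function(cohort, original, start_at, control, convention) {
  model <- original$model
  sp <- start_at$parameters
  start <- c(sp$d50, if (model == "LKB") sp$m else sp$gamma)
  obj <- make_refit_objective(cohort, original, convention)
  fn <- function(lt) obj(exp(lt[1L]), exp(lt[2L]))
  j <- control$jitter
  starts <- rbind(c(1, 1), c(1 - j, 1 + j))[seq_len(1L + control$restarts), ,
                                            drop = FALSE]
  best <- list(par = log(start), value = obj(start[1L], start[2L]))
  for (i in seq_len(nrow(starts))) {
    fit <- stats::optim(log(start * starts[i, ]), fn, method = "Nelder-Mead",
                        control = list(reltol = control$reltol,
                                       maxit = control$maxit))
    if (fit$value < best$value) best <- fit
  }
  fitted <- exp(best$par)
  list(fitted_d50 = fitted[1L], fitted_slope = fitted[2L],
       residual_rss = best$value)
}
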
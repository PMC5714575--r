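#' Per-plan dose and NTCP metrics for a paired cohort
#'
#' Evaluates mean lung dose, EUD and NTCP for every plan, both algorithms and
#' every requested parameter set. EUD is model-specific: the gEUD reduction
#' for LKB, and for RS the uniform dose that reproduces the plan's NTCP.
#'
#' @param cohort an [ntcp_cohort].
#' @param sets a named list of [parameter_set] objects (e.g. from
#'   [ntcp_parameter_sets()]), or a single set.
#' @param scheme optional [fractionation_scheme]; when supplied, DVHs are
#'   EQD2-corrected before any model evaluation. Leave `NULL` if the cohort's
#'   DVHs are already corrected.
#' @param convention RS slope convention, see [rs_uniform_response()].
#' @return A data frame with one row per (plan, algorithm, parameter set):
#'   columns `plan_id`, `treatment_type`, `algorithm`, `set`, `model`,
#'   `mld_gy`, `eud_gy`, `ntcp` (fraction in \[0, 1\]).
#' @export
compute_metrics <- function(cohort, sets, scheme = NULL,
                            convention = c("kallman", "expgamma")) {
  convention <- match.arg(convention)
  stopifnot(inherits(cohort, "ntcp_cohort"))
  if (inherits(sets, "parameter_set")) sets <- list(sets)
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    names(sets) <- vapply(sets, `[[`, "", "name")
  rows <- list()
  for (p in cohort$pairs) {
    for (alg in c("reference", "target")) {
      d <- if (alg == "reference") p$reference_dvh else p$target_dvh
      if (!is.null(scheme)) d <- eqd2_transform(d, scheme)
      lab <- if (alg == "reference") cohort$reference_label else
        cohort$target_label
      mld <- mean_dose(d)
      for (s in sets) {
        if (s$model == "LKB") {
          eud <- eud_lkb(d, s$parameters$n)
          ntcp <- ntcp_lkb(eud, s$parameters)
        } else {
          ntcp <- ntcp_rs(d, s$parameters, convention = convention)
          eud <- if (ntcp > 0 && ntcp < 1)
            eud_rs(ntcp, s$parameters, convention = convention) else NA_real_
        }
        rows[[length(rows) + 1L]] <- data.frame(
          plan_id = p$plan_id, treatment_type = p$treatment_type,
          algorithm = lab, set = s$name, model = s$model,
          mld_gy = mld, eud_gy = eud, ntcp = ntcp)
      }
    }
  }
  do.call(rbind, rows)
}

#' Cohort-level summary of algorithm differences
#'
#' For each treatment type and parameter set, summarizes how the target
#' algorithm's dose metrics differ from the reference algorithm's: mean and
#' SD of the per-plan relative MLD change, the maximum absolute NTCP
#' difference (percentage points), and the maximum relative NTCP difference —
#' the absolute difference divided by the reference (simpler) algorithm's
#' NTCP, in percent. Invariant to plan order.
#'
#' @param metrics a metrics table from [compute_metrics()] containing both
#'   algorithm labels for every plan.
#' @param reference_label,target_label the two algorithm labels to compare;
#'   defaults to the two labels present (reference = first).
#' @return A data frame with one row per (treatment type, set).
#' @export
summarize_algorithm_differences <- function(metrics, reference_label = NULL,
                                            target_label = NULL) {
  labs <- unique(metrics$algorithm)
  if (is.null(reference_label)) reference_label <- labs[1L]
  if (is.null(target_label))
    target_label <- setdiff(labs, reference_label)[1L]
  ref <- metrics[metrics$algorithm == reference_label, ]
  tgt <- metrics[metrics$algorithm == target_label, ]
  key <- function(d) paste(d$plan_id, d$set)
  miss <- c(setdiff(key(ref), key(tgt)), setdiff(key(tgt), key(ref)))
  if (length(miss))
    stop("unmatched (plan, set) rows between algorithms: ",
         paste(unique(miss), collapse = ", "), call. = FALSE)
  tgt <- tgt[match(key(ref), key(tgt)), ]
  rows <- list()
  for (tt in unique(ref$treatment_type)) {
    for (sname in unique(ref$set[ref$treatment_type == tt])) {
      i <- ref$treatment_type == tt & ref$set == sname
      mld_change <- 1 - tgt$mld_gy[i] / ref$mld_gy[i]
      dntcp <- abs(tgt$ntcp[i] - ref$ntcp[i])
      rel <- ifelse(ref$ntcp[i] > 0, dntcp / ref$ntcp[i], NA_real_)
      rows[[length(rows) + 1L]] <- data.frame(
        treatment_type = tt, set = sname,
        model = ref$model[i][1L], n_plans = sum(i),
        mld_change_mean_pct = 100 * mean(mld_change),
        mld_change_sd_pct = 100 * stats::sd(mld_change),
        max_abs_ntcp_diff_pp = 100 * max(dntcp),
        max_rel_ntcp_diff_pct = 100 * max(rel, na.rm = TRUE))
    }
  }
  do.call(rbind, rows)
}

#' Full study configuration
#'
#' Either construct programmatically or load from YAML with
#' `read_study_config()`. The default configuration shipped at
#' `system.file("extdata", "default_study.yaml", package = "ntcprefit")`
#' runs three synthetic treatment-type cohorts of 10 plans against all
#' applicable registry parameter sets.
#'
#' @param cohorts list of cohort specs, each a list with `treatment_type`,
#'   `change` (effect preset name), and optionally `n_plans` (default 10).
#' @param parameter_sets names from [ntcp_parameter_sets()]; each set is
#'   applied only to cohorts of the treatment types it is registered for.
#' @param alpha_beta,reference_dose_per_fraction LQ correction settings.
#' @param se_method,n_boot standard-error settings for the refits.
#' @param seed master seed; per-cohort seeds are derived deterministically.
#' @param convention RS slope convention.
#' @param output_dir optional directory; when set, [run_study()] writes
#'   tables there.
#' @return A list of class `study_config`.
#' @export
study_config <- function(cohorts,
                         parameter_sets = names(ntcp_parameter_sets()),
                         alpha_beta = 3, reference_dose_per_fraction = 2,
                         se_method = c("jacobian", "bootstrap", "none"),
                         n_boot = 200L, seed = 1L,
                         convention = c("kallman", "expgamma"),
                         output_dir = NULL) {
  se_method <- match.arg(se_method)
  convention <- match.arg(convention)
  parameter_sets <- unlist(parameter_sets)  # YAML lists arrive unflattened
  known <- names(ntcp_parameter_sets())
  bad <- setdiff(parameter_sets, known)
  if (length(bad))
    stop("unknown parameter set(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  structure(
    list(cohorts = cohorts, parameter_sets = parameter_sets,
         alpha_beta = alpha_beta,
         reference_dose_per_fraction = reference_dose_per_fraction,
         se_method = se_method, n_boot = as.integer(n_boot),
         seed = as.integer(seed), convention = convention,
         output_dir = output_dir),
    class = "study_config"
  )
}

#' @rdname study_config
#' @param file YAML file with the fields above.
#' @export
read_study_config <- function(file) {
  raw <- yaml::read_yaml(file)
  do.call(study_config, raw)
}

#' Run the full NTCP refitting study
#'
#' Orchestrates the pipeline: simulate each configured cohort -> EQD2-correct
#' the DVHs -> per-plan metrics under the original parameters -> refit
#' `(D50, slope)` per treatment type and parameter set -> standard errors ->
#' cohort difference summaries. Deterministic given the config seed. When
#' `output_dir` is set, writes `metrics.tsv`, `refit.tsv`, `summary.tsv` and
#' a `provenance.yaml` recording the config, seed, RS convention and package
#' version.
#'
#' @param config a [study_config] or path to a YAML config.
#' @return A list with `metrics` (data frame), `refit` (data frame mirroring
#'   the layout of published refit tables: one row per set, target algorithm
#'   and treatment type with `d50 +/- se`, `slope +/- se` and the fixed
#'   volume parameter), `summary` (from
#'   [summarize_algorithm_differences()]), and `cohorts`.
#' @export
run_study <- function(config) {
  if (is.character(config)) config <- read_study_config(config)
  stopifnot(inherits(config, "study_config"))
  registry <- ntcp_parameter_sets()
  metrics_all <- list(); refit_all <- list(); summary_all <- list()
  cohorts <- list()
  for (ci in seq_along(config$cohorts)) {
    spec <- config$cohorts[[ci]]
    tt <- spec$treatment_type
    n_plans <- if (is.null(spec$n_plans)) 10L else as.integer(spec$n_plans)
    template <- treatment_template_preset(tt)
    effect <- algorithm_effect_preset(spec$change, tt)
    coh_seed <- config$seed * 1000L + ci
    coh <- generate_cohort(template, effect, n_plans = n_plans,
                           seed = coh_seed, reference_label = "reference",
                           target_label = spec$change)
    scheme <- fractionation_scheme(template$n_fractions, config$alpha_beta,
                                   config$reference_dose_per_fraction)
    # EQD2-correct once so metrics and refits consume identical DVHs
    coh$pairs <- lapply(coh$pairs, function(p) {
      p$reference_dvh <- eqd2_transform(p$reference_dvh, scheme)
      p$target_dvh <- eqd2_transform(p$target_dvh, scheme)
      p
    })
    cohorts[[ci]] <- coh
    sets <- Filter(function(s) tt %in% s$used_on,
                   registry[config$parameter_sets])
    if (!length(sets)) next
    met <- compute_metrics(coh, sets, scheme = NULL,
                           convention = config$convention)
    metrics_all[[length(metrics_all) + 1L]] <- met
    summary_all[[length(summary_all) + 1L]] <-
      summarize_algorithm_differences(met, "reference", spec$change)
    for (s in sets) {
      fit <- refit_parameters(coh, s, convention = config$convention)
      se <- list(se_d50 = NA_real_, se_slope = NA_real_)
      if (config$se_method != "none") {
        se <- estimate_standard_errors(coh, s, fit,
                                       method = config$se_method,
                                       n_boot = config$n_boot,
                                       seed = coh_seed,
                                       convention = config$convention)
      }
      refit_all[[length(refit_all) + 1L]] <- data.frame(
        set = s$name, model = s$model, lung_volume = s$lung_volume,
        target_algorithm = spec$change, treatment_type = tt,
        d50_original = s$parameters$d50,
        slope_original = if (s$model == "LKB") s$parameters$m else
          s$parameters$gamma,
        d50_gy = fit$fitted_d50, d50_se = se$se_d50,
        slope = fit$fitted_slope, slope_se = se$se_slope,
        fixed_volume_param = fit$fixed_volume_param,
        residual_rss = fit$residual_rss, n_plans = fit$n_plans,
        converged = fit$converged)
    }
  }
  out <- list(metrics = do.call(rbind, metrics_all),
              refit = do.call(rbind, refit_all),
              summary = do.call(rbind, summary_all),
              cohorts = cohorts, config = config)
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    wt <- function(d, f) utils::write.table(
      d, file.path(config$output_dir, f), sep = "\t", row.names = FALSE,
      quote = FALSE)
    wt(out$metrics, "metrics.tsv")
    wt(out$refit, "refit.tsv")
    wt(out$summary, "summary.tsv")
    yaml::write_yaml(
      list(package = "ntcprefit",
           version = as.character(utils::packageVersion("ntcprefit")),
           seed = config$seed, rs_convention = config$convention,
           config = unclass(config)),
      file.path(config$output_dir, "provenance.yaml"))
  }
  out
}
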
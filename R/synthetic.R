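#' Treatment archetype template for synthetic lung DVHs
#'
#' Describes the statistical structure of a treatment type's lung DVH as a
#' three-component mixture, reflecting the physics of 3D-conformal thoracic
#' plans: an in-field component (lung inside the beams, dose near the
#' prescription, Gaussian with the penumbra width as spread, truncated at 0),
#' a penumbra component (uniform between 0 and the in-field dose), and a
#' low-dose bath (exponential fall-off, truncated at the prescription). The
#' differential DVH is the mixture discretized to `bin_width` bins, volumes
#' attributed to lower bin edges.
#'
#' Per plan, the component fractions, in-field dose and bath decay are
#' jittered by the relative spread `inter_plan_variability`, emulating
#' plan-to-plan anatomy differences; lung plans are the most variable because
#' their beam arrangements are individually optimized.
#'
#' @param treatment_type `"Tang"`, `"LGL"` or `"Lung"`.
#' @param prescription_dose prescription (maximum credible lung) dose, Gy.
#' @param n_fractions fractions the prescription is delivered in (used when a
#'   pipeline applies EQD2 correction).
#' @param in_field_fraction mean fraction of lung volume inside the beams.
#' @param penumbra_fraction mean fraction of lung volume in the penumbra.
#' @param in_field_dose mean dose of the in-field component, Gy.
#' @param penumbra_width Gaussian spread of the in-field dose, Gy.
#' @param bath_decay exponential dose scale of the low-dose bath, Gy.
#' @param inter_plan_variability relative SD applied to the jittered
#'   components.
#' @param bin_width DVH bin width, Gy.
#' @param lung_volume which lung volume the DVH describes.
#' @return An object of class `treatment_template`. The bath volume fraction
#'   is the derived remainder `1 - in_field_fraction - penumbra_fraction`.
#' @export
treatment_template <- function(treatment_type = c("Tang", "LGL", "Lung"),
                               prescription_dose, n_fractions,
                               in_field_fraction, penumbra_fraction,
                               in_field_dose = prescription_dose,
                               penumbra_width = prescription_dose * 0.08,
                               bath_decay = 3, inter_plan_variability = 0.1,
                               bin_width = 0.5,
                               lung_volume = c("paired", "ipsilateral")) {
  treatment_type <- match.arg(treatment_type)
  lung_volume <- match.arg(lung_volume)
  if (prescription_dose <= 0) stop("`prescription_dose` must be > 0 Gy",
                                   call. = FALSE)
  if (in_field_fraction < 0 || penumbra_fraction < 0 ||
      in_field_fraction + penumbra_fraction > 1)
    stop("component fractions must be >= 0 and sum to at most 1",
         call. = FALSE)
  if (bin_width <= 0 || penumbra_width <= 0 || bath_decay <= 0)
    stop("`bin_width`, `penumbra_width` and `bath_decay` must be > 0",
         call. = FALSE)
  structure(
    list(treatment_type = treatment_type,
         prescription_dose = prescription_dose,
         n_fractions = as.integer(n_fractions),
         in_field_fraction = in_field_fraction,
         penumbra_fraction = penumbra_fraction,
         bath_fraction = 1 - in_field_fraction - penumbra_fraction,
         in_field_dose = in_field_dose, penumbra_width = penumbra_width,
         bath_decay = bath_decay,
         inter_plan_variability = inter_plan_variability,
         bin_width = bin_width, lung_volume = lung_volume),
    class = "treatment_template"
  )
}

#' @export
print.treatment_template <- function(x, ...) {
  cat(sprintf(
    "<treatment_template> %s (%s lung): %g Gy/%d fx; in-field %g, penumbra %g, bath %g; variability %g\n",
    x$treatment_type, x$lung_volume, x$prescription_dose, x$n_fractions,
    x$in_field_fraction, x$penumbra_fraction, x$bath_fraction,
    x$inter_plan_variability))
  invisible(x)
}

#' Dose-calculation-algorithm effect on a DVH
#'
#' Parametrizes how a more accurate dose engine reshapes a pencil-beam DVH of
#' the same plan (same monitor units): the in-field dose drops
#' (`in_field_dose_scale < 1`, pencil beams overestimate dose in low-density
#' lung), part of the in-field volume moves into the penumbra
#' (`penumbra_mass_shift`, the true penumbra is wider in lung), and the
#' low-dose bath extends to higher doses (`bath_scale >= 1` multiplies the
#' bath's exponential dose scale — the better engine computes more dose
#' outside the field, so the volume receiving low-but-nonzero doses grows).
#' Total volume is conserved exactly.
#'
#' @param in_field_dose_scale multiplier on the in-field dose, in (0, 1].
#' @param penumbra_mass_shift fraction of in-field volume moved to the
#'   penumbra, in \[0, 1).
#' @param bath_scale multiplier (>= 1) on the bath dose scale.
#' @param label algorithm-change label, e.g. `"PB-CC"`.
#' @return An object of class `algorithm_effect`.
#' @export
algorithm_effect <- function(in_field_dose_scale = 1,
                             penumbra_mass_shift = 0, bath_scale = 1,
                             label = "effect") {
  if (in_field_dose_scale <= 0 || in_field_dose_scale > 1)
    stop("`in_field_dose_scale` must lie in (0, 1]", call. = FALSE)
  if (penumbra_mass_shift < 0 || penumbra_mass_shift >= 1)
    stop("`penumbra_mass_shift` must lie in [0, 1)", call. = FALSE)
  if (bath_scale < 1)
    stop("`bath_scale` must be >= 1", call. = FALSE)
  structure(
    list(in_field_dose_scale = in_field_dose_scale,
         penumbra_mass_shift = penumbra_mass_shift,
         bath_scale = bath_scale, label = as.character(label)),
    class = "algorithm_effect"
  )
}

#' @export
print.algorithm_effect <- function(x, ...) {
  cat(sprintf(
    "<algorithm_effect> %s: in-field dose x%g, penumbra shift %g, bath scale x%g\n",
    x$label, x$in_field_dose_scale, x$penumbra_mass_shift, x$bath_scale))
  invisible(x)
}

synthetic_presets_file <- function() {
  system.file("extdata", "synthetic_presets.yaml", package = "ntcprefit",
              mustWork = TRUE)
}

#' Shipped templates and algorithm-effect presets
#'
#' `treatment_template_preset()` returns the default template for a treatment
#' type; `algorithm_effect_preset()` the default effect for an algorithm
#' change and treatment type. The `"PB-CC"` presets emulate a change from a
#' correction-based pencil beam to a collapsed-cone class engine (cohort mean
#' relative MLD reductions near 8-10%); `"PBC-AAA"` presets the milder
#' pencil-beam-convolution to AAA change (near 4-5%). All values live in
#' `inst/extdata/synthetic_presets.yaml`.
#'
#' @param treatment_type `"Tang"`, `"LGL"` or `"Lung"`.
#' @param file optional alternative presets YAML.
#' @return A [treatment_template] / [algorithm_effect].
#' @export
treatment_template_preset <- function(treatment_type = c("Tang", "LGL", "Lung"),
                                      file = NULL) {
  treatment_type <- match.arg(treatment_type)
  raw <- yaml::read_yaml(if (is.null(file)) synthetic_presets_file() else file)
  t <- raw$templates[[treatment_type]]
  if (is.null(t)) stop("no template preset for ", treatment_type, call. = FALSE)
  do.call(treatment_template, c(list(treatment_type = treatment_type), t))
}

#' @rdname treatment_template_preset
#' @param change `"PB-CC"` or `"PBC-AAA"`.
#' @export
algorithm_effect_preset <- function(change = c("PB-CC", "PBC-AAA"),
                                    treatment_type = c("Tang", "LGL", "Lung"),
                                    file = NULL) {
  change <- match.arg(change)
  treatment_type <- match.arg(treatment_type)
  raw <- yaml::read_yaml(if (is.null(file)) synthetic_presets_file() else file)
  e <- raw$effects[[change]][[treatment_type]]
  if (is.null(e))
    stop("no effect preset for ", change, " / ", treatment_type, call. = FALSE)
  do.call(algorithm_effect, c(e, list(label = change)))
}

# draw one latent plan from the template, jittering components; retries keep
# fractions physical
draw_latent_plan <- function(template, max_retries = 20L) {
  cv <- template$inter_plan_variability
  for (i in seq_len(max_retries)) {
    f_in <- template$in_field_fraction * (1 + stats::rnorm(1, 0, cv))
    f_pen <- template$penumbra_fraction * (1 + stats::rnorm(1, 0, cv))
    mu <- template$in_field_dose * (1 + stats::rnorm(1, 0, cv / 4))
    decay <- template$bath_decay * (1 + stats::rnorm(1, 0, cv / 2))
    ok <- f_in >= 0 && f_pen >= 0 && f_in + f_pen <= 1 &&
      mu > 0 && decay > 0
    if (ok)
      return(list(f_in = f_in, f_pen = f_pen, f_bath = 1 - f_in - f_pen,
                  mu = mu, sigma = template$penumbra_width, decay = decay,
                  prescription = template$prescription_dose))
  }
  stop("could not draw physical component fractions after ", max_retries,
       " retries; reduce `inter_plan_variability`", call. = FALSE)
}

apply_effect_latent <- function(latent, effect) {
  shift_mass <- latent$f_in * effect$penumbra_mass_shift
  latent$f_in <- latent$f_in - shift_mass
  latent$f_pen <- latent$f_pen + shift_mass
  latent$mu <- latent$mu * effect$in_field_dose_scale
  latent$decay <- latent$decay * effect$bath_scale
  latent
}

# discretize the three-component mixture to a differential DVH
render_latent_dvh <- function(latent, bin_width, structure = "lung") {
  dmax <- max(latent$prescription, latent$mu + 4 * latent$sigma) * 1.05
  edges <- seq(0, ceiling(dmax / bin_width) * bin_width, by = bin_width)
  n <- length(edges) - 1L
  lo <- edges[-length(edges)]
  hi <- edges[-1L]

  # in-field: Normal(mu, sigma) truncated to >= 0
  z0 <- stats::pnorm(0, latent$mu, latent$sigma)
  cdf_in <- function(x) (stats::pnorm(x, latent$mu, latent$sigma) - z0) / (1 - z0)
  # penumbra: Uniform(0, mu)
  cdf_pen <- function(x) pmin(pmax(x / latent$mu, 0), 1)
  # bath: Exponential(scale = decay) truncated at the prescription dose
  pmaxd <- stats::pexp(latent$prescription, rate = 1 / latent$decay)
  cdf_bath <- function(x)
    stats::pexp(pmin(x, latent$prescription), rate = 1 / latent$decay) / pmaxd

  mass <- latent$f_in * (cdf_in(hi) - cdf_in(lo)) +
    latent$f_pen * (cdf_pen(hi) - cdf_pen(lo)) +
    latent$f_bath * (cdf_bath(hi) - cdf_bath(lo))
  mass <- pmax(mass, 0)
  mass <- mass / sum(mass)  # exact volume conservation
  dvh(lo, mass, kind = "differential", structure = structure)
}

#' Generate one synthetic paired-DVH plan
#'
#' Draws a single latent plan from the template (using the current state of
#' R's random number generator) and renders two DVHs from it: the reference
#' DVH directly, and the target DVH from the *same* latent plan transformed
#' by the algorithm effect — mirroring a plan recalculated with a second dose
#' engine at fixed monitor units. An identity effect therefore yields
#' bit-identical paired DVHs. Use [generate_cohort()] for a seeded stream.
#'
#' @param template a [treatment_template].
#' @param effect an [algorithm_effect].
#' @param plan_id identifier for the plan.
#' @return A [plan_pair] of differential DVHs in physical dose.
#' @export
generate_plan_pair <- function(template, effect = algorithm_effect(),
                               plan_id = "plan") {
  stopifnot(inherits(template, "treatment_template"),
            inherits(effect, "algorithm_effect"))
  latent <- draw_latent_plan(template)
  label <- paste0("lung_", template$lung_volume)
  plan_pair(
    plan_id = plan_id, treatment_type = template$treatment_type,
    reference_dvh = render_latent_dvh(latent, template$bin_width, label),
    target_dvh = render_latent_dvh(apply_effect_latent(latent, effect),
                                   template$bin_width, label),
    lung_volume = template$lung_volume
  )
}

#' Generate a seeded synthetic cohort of paired plans
#'
#' @inheritParams generate_plan_pair
#' @param n_plans number of plans (the emulated study design uses 10 per
#'   treatment type).
#' @param seed integer seed; the whole cohort comes from one seeded stream
#'   and is fully reproducible.
#' @param reference_label,target_label algorithm labels stored on the cohort.
#' @return An [ntcp_cohort] whose `seed`, `template` and `effect` are
#'   attached as attributes `"seed"`, `"template"`, `"effect"`.
#' @examples
#' coh <- generate_cohort(treatment_template_preset("Lung"),
#'                        algorithm_effect_preset("PB-CC", "Lung"),
#'                        n_plans = 10, seed = 1)
#' coh
#' @export
generate_cohort <- function(template, effect = algorithm_effect(),
                            n_plans = 10L, seed = 1L,
                            reference_label = "reference",
                            target_label = effect$label) {
  if (n_plans < 1L) stop("`n_plans` must be >= 1", call. = FALSE)
  pairs <- withr::with_seed(as.integer(seed), {
    lapply(seq_len(n_plans), function(i)
      generate_plan_pair(template, effect,
                         plan_id = sprintf("%s_%02d", template$treatment_type, i)))
  })
  coh <- ntcp_cohort(pairs, reference_label = reference_label,
                     target_label = target_label)
  attr(coh, "seed") <- as.integer(seed)
  attr(coh, "template") <- template
  attr(coh, "effect") <- effect
  coh
}

#' Monte-Carlo calibration of an algorithm effect
#'
#' Estimates the cohort-level mean and standard deviation of the relative
#' mean-lung-dose reduction `(MLD_ref - MLD_target) / MLD_ref` an effect
#' produces under a template. This is the oracle used to tune the shipped
#' presets so their cohort MLD shifts land in the ranges reported for real
#' pencil-beam-to-model-based algorithm changes.
#'
#' @inheritParams generate_cohort
#' @param n_plans Monte-Carlo sample size (default 200).
#' @return A list with `mean_reduction`, `sd_reduction` (fractions, e.g. 0.08
#'   for 8%) and `n_plans`.
#' @export
calibrate_effect <- function(template, effect, n_plans = 200L, seed = 1L) {
  coh <- generate_cohort(template, effect, n_plans = n_plans, seed = seed)
  red <- vapply(coh$pairs, function(p) {
    m_ref <- mean_dose(p$reference_dvh)
    1 - mean_dose(p$target_dvh) / m_ref
  }, numeric(1))
  list(mean_reduction = mean(red), sd_reduction = stats::sd(red),
       n_plans = as.integer(n_plans))
}

#' Write a generated cohort in the DVH exchange format
#'
#' Writes all reference and target DVHs to two exchange files plus a YAML
#' sidecar recording the seed, template and effect, so a cohort can be
#' regenerated or audited.
#'
#' @param cohort an [ntcp_cohort] from [generate_cohort()].
#' @param dir output directory (created if missing).
#' @param stem file-name stem.
#' @return The directory, invisibly.
#' @export
write_cohort <- function(cohort, dir, stem = "cohort") {
  stopifnot(inherits(cohort, "ntcp_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  relab <- function(d, p, alg) { d$structure <- paste(p$plan_id, alg, sep = "_"); d }
  refs <- lapply(cohort$pairs, function(p) relab(p$reference_dvh, p, "ref"))
  tgts <- lapply(cohort$pairs, function(p) relab(p$target_dvh, p, "target"))
  write_dvh(refs, file.path(dir, paste0(stem, "_reference.dvh")))
  write_dvh(tgts, file.path(dir, paste0(stem, "_target.dvh")))
  meta <- list(seed = attr(cohort, "seed"),
               reference_label = cohort$reference_label,
               target_label = cohort$target_label,
               n_plans = length(cohort$pairs),
               template = if (!is.null(attr(cohort, "template")))
                 unclass(attr(cohort, "template")),
               effect = if (!is.null(attr(cohort, "effect")))
                 unclass(attr(cohort, "effect")))
  yaml::write_yaml(meta, file.path(dir, paste0(stem, "_meta.yaml")))
  invisible(dir)
}
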
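# Fixtures and independent scalar oracles used across the suite.
# Oracles are deliberately naive (explicit loops, direct formulas) so they
# stay independent of the vectorized / log-space implementation paths.

uniform_dvh <- function(dose, structure = "uniform") {
  dvh(dose, 1, kind = "differential", structure = structure)
}

random_differential_dvh <- function(n_bins = 50, max_gap = 2) {
  dose <- cumsum(stats::runif(n_bins, 0.05, max_gap))
  v <- stats::runif(n_bins)
  dvh(dose, v / sum(v), kind = "differential", structure = "random")
}

random_cumulative_dvh <- function(n_bins = 50, max_gap = 2) {
  dose <- c(0, cumsum(stats::runif(n_bins - 1, 0.05, max_gap)))
  v <- c(1, sort(stats::runif(n_bins - 1), decreasing = TRUE))
  dvh(dose, v, kind = "cumulative", structure = "random")
}

# Eq.-style scalar loop for the gEUD reduction
oracle_eud <- function(dose, volume, n) {
  acc <- 0
  for (i in seq_along(dose)) acc <- acc + volume[i] * dose[i]^(1 / n)
  acc^n
}

# direct (non-log-space) relative seriality NTCP
oracle_ntcp_rs <- function(dose, volume, d50, gamma, s) {
  prd <- 1
  for (i in seq_along(dose)) {
    p <- 2^(-exp(exp(1) * gamma * (1 - dose[i] / d50)))
    prd <- prd * (1 - p^s)^volume[i]
  }
  (1 - prd)^(1 / s)
}

# hand-rolled refit objective: loop over plans, no shared precomputation
oracle_refit_residual <- function(cohort, original, d50, slope) {
  model <- original$model
  op <- original$parameters
  acc <- 0
  for (p in cohort$pairs) {
    if (model == "LKB") {
      ref <- ntcp_lkb(eud_lkb(p$reference_dvh, op$n), op)
      dd <- as_differential(p$target_dvh)
      eud <- oracle_eud(dd$dose, dd$volume, op$n)
      new <- stats::pnorm((eud - d50) / (slope * d50))
    } else {
      ref <- ntcp_rs(p$reference_dvh, op)
      dd <- as_differential(p$target_dvh)
      new <- oracle_ntcp_rs(dd$dose, dd$volume, d50, slope, op$s)
    }
    acc <- acc + (new - ref)^2
  }
  acc
}

# cohort whose target DVHs equal (identity) or dose-scale (k) the references
derived_cohort <- function(base_cohort, k = 1) {
  pairs <- lapply(base_cohort$pairs, function(p) {
    d <- p$reference_dvh
    d$dose <- d$dose * k
    p$target_dvh <- d
    p
  })
  ntcp_cohort(pairs, base_cohort$reference_label,
              if (k == 1) "identity" else sprintf("scaled_%g", k))
}

small_cohort <- function(treatment_type = "Lung", n_plans = 6, seed = 11,
                         change = "PB-CC") {
  generate_cohort(treatment_template_preset(treatment_type),
                  algorithm_effect_preset(change, treatment_type),
                  n_plans = n_plans, seed = seed)
}
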
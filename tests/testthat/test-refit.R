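test_that("refit_residual equals a hand-rolled loop over plans", {
  coh <- small_cohort("Lung", n_plans = 3, seed = 2)
  for (nm in c("seppenwoolde_lkb", "seppenwoolde_rs")) {
    s <- ntcp_parameter_sets(nm)
    sl <- if (s$model == "LKB") s$parameters$m else s$parameters$gamma
    for (cand in list(c(s$parameters$d50, sl), c(25, 0.5), c(40, 1.2))) {
      expect_equal(refit_residual(coh, s, cand[1], cand[2]),
                   oracle_refit_residual(coh, s, cand[1], cand[2]),
                   tolerance = 1e-10)
    }
  }
  # identity cohort at the original parameters has zero residual
  id <- derived_cohort(coh, 1)
  s <- ntcp_parameter_sets("seppenwoolde_lkb")
  expect_equal(refit_residual(id, s, s$parameters$d50, s$parameters$m), 0)
})

test_that("identity cohorts refit to the original parameters", {
  id <- derived_cohort(small_cohort("Tang", n_plans = 5, seed = 4), 1)
  for (nm in c("seppenwoolde_lkb", "gagliardi_rs")) {
    s <- ntcp_parameter_sets(nm)
    fit <- refit_parameters(id, s)
    sl0 <- if (s$model == "LKB") s$parameters$m else s$parameters$gamma
    expect_equal(fit$fitted_d50, s$parameters$d50, tolerance = 1e-4)
    expect_equal(fit$fitted_slope, sl0, tolerance = 1e-4)
    expect_lt(fit$residual_rss, 1e-12)
    expect_true(fit$converged)
    # the tissue parameter is copied, never fitted
    expect_identical(fit$fixed_volume_param,
                     if (s$model == "LKB") s$parameters$n else s$parameters$s)
  }
})

test_that("uniform dose scaling is recovered exactly (closed-form oracle)", {
  base <- small_cohort("LGL", n_plans = 6, seed = 8)
  sc <- derived_cohort(base, 0.9)
  for (nm in c("seppenwoolde_lkb", "seppenwoolde_rs")) {
    s <- ntcp_parameter_sets(nm)
    fit <- refit_parameters(sc, s)
    sl0 <- if (s$model == "LKB") s$parameters$m else s$parameters$gamma
    expect_equal(fit$fitted_d50, 0.9 * s$parameters$d50, tolerance = 1e-3)
    expect_equal(fit$fitted_slope, sl0, tolerance = 1e-3)
  }
})

test_that("fitted residual never exceeds the original-parameter residual", {
  for (seed in c(3, 17)) {
    coh <- small_cohort("Lung", n_plans = 8, seed = seed)
    for (nm in c("seppenwoolde_lkb", "seppenwoolde_rs")) {
      s <- ntcp_parameter_sets(nm)
      fit <- refit_parameters(coh, s)
      expect_lte(fit$residual_rss, fit$residual_rss_original)
      # a softer dose engine needs a lower D50
      expect_lt(fit$fitted_d50, s$parameters$d50)
      # perturbing away from the optimum increases the residual
      expect_gt(refit_residual(coh, s, fit$fitted_d50 * 1.05,
                               fit$fitted_slope), fit$residual_rss)
      expect_gt(refit_residual(coh, s, fit$fitted_d50,
                               fit$fitted_slope * 1.1), fit$residual_rss)
    }
  }
})

test_that("refits are invariant to plan order and cohort duplication", {
  coh <- small_cohort("Tang", n_plans = 6, seed = 5)
  s <- ntcp_parameter_sets("seppenwoolde_lkb")
  fit <- refit_parameters(coh, s)
  rev_coh <- ntcp_cohort(rev(coh$pairs), coh$reference_label,
                         coh$target_label)
  fit_rev <- refit_parameters(rev_coh, s)
  expect_equal(fit_rev$fitted_d50, fit$fitted_d50, tolerance = 1e-8)
  expect_equal(fit_rev$fitted_slope, fit$fitted_slope, tolerance = 1e-8)
  dup <- ntcp_cohort(c(coh$pairs, coh$pairs), coh$reference_label,
                     coh$target_label)
  fit_dup <- refit_parameters(dup, s)
  expect_equal(fit_dup$fitted_d50, fit$fitted_d50, tolerance = 1e-6)
  expect_equal(fit_dup$fitted_slope, fit$fitted_slope, tolerance = 1e-6)
})

test_that("cohort and refit preconditions are enforced", {
  coh <- small_cohort("Tang", n_plans = 2, seed = 1)
  one <- ntcp_cohort(coh$pairs[1], "a", "b")
  expect_error(refit_parameters(one, ntcp_parameter_sets("seppenwoolde_lkb")),
               "at least 2")
  # mixing treatment types requires the explicit pooling flag
  mix <- c(small_cohort("Tang", 2, 1)$pairs, small_cohort("Lung", 2, 1)$pairs)
  expect_error(ntcp_cohort(mix), "pooled")
  expect_s3_class(ntcp_cohort(mix, pooled = TRUE), "ntcp_cohort")
  expect_error(refit_residual(coh, ntcp_parameter_sets("seppenwoolde_lkb"),
                              -5, 0.3), "positive")
})

test_that("bootstrap SEs are seeded-reproducible; identity cohorts give zero", {
  coh <- small_cohort("LGL", n_plans = 6, seed = 10)
  s <- ntcp_parameter_sets("seppenwoolde_lkb")
  fit <- refit_parameters(coh, s)
  se1 <- estimate_standard_errors(coh, s, fit, "bootstrap", n_boot = 40,
                                  seed = 99)
  se2 <- estimate_standard_errors(coh, s, fit, "bootstrap", n_boot = 40,
                                  seed = 99)
  expect_identical(se1$se_d50, se2$se_d50)
  expect_identical(se1$se_slope, se2$se_slope)
  expect_gt(se1$se_d50, 0)
  id <- derived_cohort(coh, 1)
  fit_id <- refit_parameters(id, s)
  se_id <- suppressMessages(
    estimate_standard_errors(id, s, fit_id, "bootstrap", n_boot = 30,
                             seed = 1))
  expect_lt(se_id$se_d50, 1e-8)
  expect_lt(se_id$se_slope, 1e-8)
  expect_warning(
    estimate_standard_errors(coh, s, fit, "bootstrap", n_boot = 10, seed = 1),
    "below the recommended")
})

test_that("bootstrap and curvature-based SEs agree to within a factor of two", {
  coh <- small_cohort("LGL", n_plans = 10, seed = 23)
  for (nm in c("seppenwoolde_lkb", "seppenwoolde_rs")) {
    s <- ntcp_parameter_sets(nm)
    fit <- refit_parameters(coh, s)
    sj <- estimate_standard_errors(coh, s, fit, "jacobian")
    sb <- estimate_standard_errors(coh, s, fit, "bootstrap", n_boot = 60,
                                   seed = 7)
    expect_gt(sj$se_d50, 0)
    expect_lt(max(sj$se_d50, sb$se_d50) / min(sj$se_d50, sb$se_d50), 2)
    expect_lt(max(sj$se_slope, sb$se_slope) / min(sj$se_slope, sb$se_slope), 2)
  }
})
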
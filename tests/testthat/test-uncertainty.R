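test_that("degenerate intervals give a zero-width band equal to the center curve", {
  for (model in c("LKB", "RS")) {
    b <- ntcp_confidence_band(
      model,
      parameter_interval(30, 30, 0.68), parameter_interval(0.37, 0.37, 0.68),
      fixed_volume_param = 0.99, eud_grid = seq(1, 60, by = 1))
    expect_equal(b$ntcp_low, b$ntcp_high, tolerance = 1e-15)
    expect_equal(b$ntcp_low, b$ntcp_center, tolerance = 1e-15)
  }
})

test_that("grid search equals an independent exhaustive double loop", {
  d50_iv <- parameter_interval(28, 32, 0.68)
  m_iv <- parameter_interval(0.3, 0.45, 0.68)
  euds <- seq(2, 60, by = 2)
  b <- ntcp_confidence_band("LKB", d50_iv, m_iv, 0.99, euds,
                            grid_points_per_axis = 101)
  d50s <- seq(28, 32, length.out = 101)
  ms <- seq(0.3, 0.45, length.out = 101)
  for (i in seq_along(euds)) {
    vals <- numeric(0)
    for (a in d50s) for (mm in ms)
      vals <- c(vals, pnorm((euds[i] - a) / (mm * a)))
    expect_equal(b$ntcp_low[i], min(vals), tolerance = 1e-12)
    expect_equal(b$ntcp_high[i], max(vals), tolerance = 1e-12)
  }
  # LKB extremes sit on the rectangle boundary: corner-only search agrees
  corners <- expand.grid(d50 = c(28, 32), m = c(0.3, 0.45))
  for (i in seq_along(euds)) {
    cv <- mapply(function(a, mm) pnorm((euds[i] - a) / (mm * a)),
                 corners$d50, corners$m)
    expect_equal(b$ntcp_high[i], max(cv), tolerance = 1e-9)
    expect_equal(b$ntcp_low[i], min(cv), tolerance = 1e-9)
  }
})

test_that("the band contains the center curve and widening never narrows it", {
  euds <- seq(5, 70, by = 5)
  b1 <- ntcp_confidence_band("RS", parameter_interval(32, 36, 0.68),
                             parameter_interval(0.8, 1.0, 0.68), 0.06, euds,
                             grid_points_per_axis = 41)
  expect_true(all(b1$ntcp_low <= b1$ntcp_center + 1e-12))
  expect_true(all(b1$ntcp_center <= b1$ntcp_high + 1e-12))
  wider_d50 <- ntcp_confidence_band("RS", parameter_interval(30, 38, 0.68),
                                    parameter_interval(0.8, 1.0, 0.68), 0.06,
                                    euds, grid_points_per_axis = 41)
  wider_slope <- ntcp_confidence_band("RS", parameter_interval(32, 36, 0.68),
                                      parameter_interval(0.7, 1.1, 0.68), 0.06,
                                      euds, grid_points_per_axis = 41)
  for (w in list(wider_d50, wider_slope)) {
    expect_true(all(w$ntcp_low <= b1$ntcp_low + 1e-12))
    expect_true(all(w$ntcp_high >= b1$ntcp_high - 1e-12))
  }
})

test_that("the upper envelope reaches 0.5 at the low-D50 corner's midpoint dose", {
  # NTCP is decreasing in D50, so at EUD = d50_low the maximum over the
  # rectangle is attained at that corner and equals 0.5 (slope-independent)
  b <- ntcp_confidence_band("LKB", parameter_interval(28, 32, 0.68),
                            parameter_interval(0.37, 0.37, 0.68), 0.99,
                            eud_grid = 28, grid_points_per_axis = 51)
  expect_equal(b$ntcp_high, 0.5, tolerance = 1e-12)
})

test_that("DVH-series bands agree with the uniform-dose band for uniform DVHs", {
  d50_iv <- parameter_interval(32, 36, 0.68)
  g_iv <- parameter_interval(0.8, 1.0, 0.68)
  u <- uniform_dvh(25)
  bd <- band_for_dvh_series(list(u), "RS", d50_iv, g_iv, 0.06,
                            grid_points_per_axis = 21)
  bu <- ntcp_confidence_band("RS", d50_iv, g_iv, 0.06, eud_grid = 25,
                             grid_points_per_axis = 21)
  expect_equal(bd$ntcp_low, bu$ntcp_low, tolerance = 1e-12)
  expect_equal(bd$ntcp_high, bu$ntcp_high, tolerance = 1e-12)
  # two different DVHs with the same EUD need not share a band width under RS
  het <- dvh(c(10, 45), c(0.5, 0.5), "differential")
  bh <- band_for_dvh_series(list(het), "RS", d50_iv, g_iv, 0.06,
                            grid_points_per_axis = 21)
  expect_true(is.finite(bh$ntcp_low) && is.finite(bh$ntcp_high))
  expect_lte(bh$ntcp_low, bh$ntcp_high)
})

test_that("band validation and export behave", {
  expect_error(ntcp_confidence_band("LKB", parameter_interval(28, 32),
                                    parameter_interval(0.3, 0.45), 0.99,
                                    eud_grid = seq(5, 20, 5),
                                    grid_points_per_axis = 1),
               "grid_points_per_axis")
  expect_error(parameter_interval(5, 3), "low")
  expect_error(parameter_interval(3, 5, 1.2), "confidence_level")
  b <- ntcp_confidence_band("LKB", parameter_interval(28, 32),
                            parameter_interval(0.3, 0.45), 0.99,
                            eud_grid = seq(5, 20, 5))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_band(b, f)
  tab <- read.delim(f)
  expect_identical(names(tab), c("eud_gy", "ntcp_low", "ntcp_center",
                                 "ntcp_high"))
  expect_equal(nrow(tab), 4)
})
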
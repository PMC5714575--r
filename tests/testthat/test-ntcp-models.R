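test_that("LKB response hits its analytic anchor points", {
  p <- lkb_parameters(30.80, 0.37, 0.99)
  expect_equal(ntcp_lkb(p$d50, p), 0.5, tolerance = 1e-12)
  expect_equal(ntcp_lkb(p$d50 * (1 + p$m), p), pnorm(1), tolerance = 1e-12)
  # against numerical integration of the Gaussian integral
  t <- (20 - p$d50) / (p$m * p$d50)
  quad <- integrate(dnorm, -Inf, t, rel.tol = 1e-12)$value
  expect_equal(ntcp_lkb(20, p), quad, tolerance = 1e-9)
  expect_error(ntcp_lkb(-1, p), ">= 0")
})

test_that("gEUD reduces correctly and stays within the dose range", {
  expect_equal(eud_lkb(uniform_dvh(20), 0.5), 20, tolerance = 1e-12)
  d <- dvh(c(10, 20), c(0.5, 0.5), "differential")
  expect_equal(eud_lkb(d, 1), 15, tolerance = 1e-12)
  expect_equal(eud_lkb(d, 0.99), oracle_eud(d$dose, d$volume, 0.99),
               tolerance = 1e-12)
  expect_error(eud_lkb(d, 0), "> 0")
  withr::with_seed(5, {
    for (i in 1:20) {
      r <- random_differential_dvh(40)
      n <- runif(1, 0.05, 1.5)
      e <- eud_lkb(r, n)
      nz <- r$dose[r$volume > 0]
      expect_gte(e, min(nz) - 1e-9)
      expect_lte(e, max(nz) + 1e-9)
    }
  })
})

test_that("LKB DVH composition equals its parts, mean-dose limit at n = 1", {
  p <- lkb_parameters(17, 0.33, 0.91)
  withr::with_seed(9, {
    d3 <- random_differential_dvh(3)
    expect_equal(ntcp_lkb_dvh(d3, p),
                 pnorm((oracle_eud(d3$dose, d3$volume, 0.91) - 17) /
                         (0.33 * 17)),
                 tolerance = 1e-12)
    p1 <- lkb_parameters(17, 0.33, 1)
    r <- random_differential_dvh(40)
    expect_equal(ntcp_lkb_dvh(r, p1), ntcp_lkb(mean_dose(r), p1),
                 tolerance = 1e-12)
  })
  expect_equal(ntcp_lkb_dvh(uniform_dvh(17), p), 0.5, tolerance = 1e-12)
})

test_that("RS uniform response matches its closed form at the anchors", {
  p <- rs_parameters(34, 0.9, 0.06)
  expect_identical(rs_uniform_response(34, p), 0.5)
  # zero dose: independently evaluated scalar expression
  expect_equal(rs_uniform_response(0, p), 2^(-exp(exp(1) * 0.9)),
               tolerance = 1e-15)
  expect_gt(rs_uniform_response(1e4, p), 1 - 1e-12)
  # strictly increasing in dose
  doses <- seq(0, 120, by = 0.5)
  expect_true(all(diff(rs_uniform_response(doses, p)) > 0))
})

test_that("RS DVH response matches the direct product formula and its limits", {
  p <- rs_parameters(30.1, 0.966, 0.012)
  expect_equal(ntcp_rs(uniform_dvh(30.1), p), 0.5, tolerance = 1e-12)
  withr::with_seed(13, {
    d3 <- random_differential_dvh(3, max_gap = 15)
    expect_equal(ntcp_rs(d3, p),
                 oracle_ntcp_rs(d3$dose, d3$volume, 30.1, 0.966, 0.012),
                 tolerance = 1e-10)
  })
  # s = 1 on a two-bin DVH reduces to the closed-form product expression
  p1 <- rs_parameters(30, 1, 1)
  d2 <- dvh(c(15, 35), c(0.4, 0.6), "differential")
  want <- 1 - (1 - rs_uniform_response(15, p1))^0.4 *
    (1 - rs_uniform_response(35, p1))^0.6
  expect_equal(ntcp_rs(d2, p1), want, tolerance = 1e-12)
  # single-bin, s = 1: equals the uniform response
  expect_equal(ntcp_rs(uniform_dvh(22), p1), rs_uniform_response(22, p1),
               tolerance = 1e-12)
})

test_that("RS EUD inversion is the exact inverse of the uniform response", {
  p <- rs_parameters(34, 0.9, 0.06)
  expect_identical(eud_rs(0.5, p), 34)
  # bisection oracle for a non-trivial probability
  root <- uniroot(function(d) rs_uniform_response(d, p) - 0.1,
                  c(1, 200), tol = 1e-12)$root
  expect_equal(eud_rs(0.1, p), root, tolerance = 1e-9)
  for (D in seq(2, 80, by = 6)) {
    expect_equal(eud_rs(rs_uniform_response(D, p), p), D,
                 tolerance = 1e-9 * D)
    # roundtrip through the DVH response for uniform irradiation
    expect_equal(eud_rs(ntcp_rs(uniform_dvh(D), p), p), D,
                 tolerance = 1e-8 * D)
  }
  expect_error(eud_rs(0, p), "strictly inside")
  expect_error(eud_rs(1, p), "strictly inside")
})

test_that("both NTCP models respond monotonically to dose scaling and d50", {
  lkb <- lkb_parameters(30.8, 0.37, 0.99)
  rs <- rs_parameters(34, 0.9, 0.06)
  withr::with_seed(21, {
    base <- random_differential_dvh(40)
    ks <- c(0.5, 0.8, 1, 1.2, 1.5)
    scaled <- lapply(ks, function(k) {
      d <- base; d$dose <- d$dose * k; d
    })
    expect_true(all(diff(vapply(scaled, ntcp_lkb_dvh, 0, params = lkb)) > 0))
    expect_true(all(diff(vapply(scaled, ntcp_rs, 0, params = rs)) > 0))
    # decreasing in d50 at fixed dose distribution
    d50s <- c(20, 25, 30, 35, 40)
    expect_true(all(diff(vapply(d50s, function(x)
      ntcp_lkb(25, lkb_parameters(x, 0.37, 0.99)), 0)) < 0))
    expect_true(all(diff(vapply(d50s, function(x)
      ntcp_rs(base, rs_parameters(x, 0.9, 0.06)), 0)) < 0))
  })
})

test_that("the RS slope-convention flag changes the slope but not the midpoint", {
  p <- rs_parameters(34, 0.9, 0.06)
  expect_equal(rs_uniform_response(34, p, convention = "expgamma"), 0.5)
  expect_false(isTRUE(all.equal(
    rs_uniform_response(20, p, convention = "expgamma"),
    rs_uniform_response(20, p, convention = "kallman"))))
  # inversion respects the convention
  expect_equal(rs_uniform_response(
    eud_rs(0.2, p, convention = "expgamma"), p, convention = "expgamma"),
    0.2, tolerance = 1e-12)
})

test_that("parameter constructors reject out-of-range values", {
  expect_error(lkb_parameters(0, 0.37, 0.99), "d50")
  expect_error(lkb_parameters(30, -1, 0.99), "m")
  expect_error(lkb_parameters(30, 0.37, 2), "n")
  expect_error(rs_parameters(30, 0, 0.06), "gamma")
  expect_error(rs_parameters(30, 0.9, 0), "s")
})
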
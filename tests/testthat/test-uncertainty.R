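test_that("numeric gradient recovers linear and constant maps", {
  params <- tibble::tibble(parameter = "theta", value = 2, se = 1)
  expect_equal(numeric_gradient(function(th) 3 * th[["theta"]], params)[["theta"]],
               3, tolerance = 1e-8)
  expect_equal(numeric_gradient(function(th) 7, params)[["theta"]], 0)
  expect_error(numeric_gradient(function(th) NaN, params), "not finite")
})

test_that("gradient of the cost map w.r.t. the SUTI cost is the
           SUTI-only count", {
  params <- param_vector(fixture_risks(), fixture_costs())
  obj <- function(th) {
    450 * th[["bacteriuria_risk"]] *
      ((th[["suti_risk"]] - th[["bsi_risk"]]) * th[["suti_cost"]] +
         th[["bsi_risk"]] * th[["bsi_cost"]])
  }
  grad <- numeric_gradient(obj, params)
  expect_equal(grad[["suti_cost"]], 23.868, tolerance = 1e-6)
  expect_equal(grad[["bsi_cost"]], 4.212, tolerance = 1e-6)
})

test_that("delta variance matches the analytic multilinear gradient sum", {
  set.seed(7)
  for (i in 1:5) {
    p <- random_valid_params()
    params <- param_vector(p$risks, p$costs)
    obj <- function(th) {
      p$scenario$admissions * p$scenario$prop_catheterized *
        th[["bacteriuria_risk"]] *
        ((th[["suti_risk"]] - th[["bsi_risk"]]) * th[["suti_cost"]] +
           th[["bsi_risk"]] * th[["bsi_cost"]])
    }
    analytic <- analytic_cost_gradient(p$scenario, p$risks, p$costs)
    expected <- sum(analytic^2 * params$se^2)
    expect_equal(delta_variance(obj, params), expected,
                 tolerance = 1e-6)
  }
})

test_that("delta variance is exact for linear maps and zero without noise", {
  params <- tibble::tibble(parameter = "theta", value = 5, se = 2)
  expect_equal(delta_variance(function(th) 4 * th[["theta"]], params),
               4^2 * 2^2, tolerance = 1e-9)
  params0 <- param_vector(
    risk_params(bacteriuria_risk_se = 0, suti_risk_se = 0, bsi_risk_se = 0),
    cost_params(suti_cost_se = 0, bsi_cost_se = 0)
  )
  obj <- function(th) {
    450 * th[["bacteriuria_risk"]] *
      ((th[["suti_risk"]] - th[["bsi_risk"]]) * th[["suti_cost"]] +
         th[["bsi_risk"]] * th[["bsi_cost"]])
  }
  expect_equal(delta_variance(obj, params0), 0)
})

test_that("log-scale intervals are multiplicatively symmetric and collapse
           when the SE is zero", {
  ci <- lognormal_ci(37850, 27500, 0.95)
  expect_equal(ci[["ci_high"]] / 37850, 37850 / ci[["ci_low"]],
               tolerance = 1e-12)
  expect_equal(lognormal_ci(100, 0), c(ci_low = 100, ci_high = 100))
  expect_warning(deg <- lognormal_ci(0, 10), "degenerate")
  expect_equal(unname(deg), c(0, 0))
  expect_error(lognormal_ci(10, 1, level = 1.2), "between 0 and 1")
})

test_that("interval width grows with each input SE and the log-scale CI
           approaches the normal CI as CV shrinks", {
  widths <- vapply(c(0.1, 0.5, 1, 2), function(k) {
    ci <- lognormal_ci(1000, 100 * k)
    ci[["ci_high"]] - ci[["ci_low"]]
  }, numeric(1))
  expect_true(all(diff(widths) > 0))
  point <- 1000; se <- 1 # CV = 0.001
  ci <- lognormal_ci(point, se)
  z <- qnorm(0.975)
  expect_equal(ci[["ci_low"]], point - z * se, tolerance = 1e-5)
  expect_equal(ci[["ci_high"]], point + z * se, tolerance = 1e-5)
})

test_that("estimate objects carry a coherent point/SE/interval and tidy into
           the per-parameter variance decomposition", {
  est <- estimate_with_ci(fixture_scenario(), fixture_risks(),
                          fixture_costs(), quantity = "current_cost")
  expect_s3_class(est, "cauti_estimate")
  expect_lte(est$ci_low, est$point)
  expect_gte(est$ci_high, est$point)
  expect_gt(est$ci_low, 0)
  td <- tidy(est)
  expect_equal(nrow(td), 5)
  expect_equal(sqrt(sum(td$se_contribution^2)), est$se)
  gl <- glance(est)
  expect_equal(gl$point, est$point)
  # all SEs zero -> interval collapses onto the point
  est0 <- estimate_with_ci(
    fixture_scenario(),
    risk_params(bacteriuria_risk_se = 0, suti_risk_se = 0, bsi_risk_se = 0),
    cost_params(suti_cost_se = 0, bsi_cost_se = 0),
    quantity = "current_cost"
  )
  expect_equal(est0$ci_low, est0$point)
  expect_equal(est0$ci_high, est0$point)
  # zero-savings point: degenerate interval, no error
  s0 <- estimate_with_ci(fixture_scenario(), fixture_risks(),
                         fixture_costs(), no_intervention(), "savings")
  expect_equal(s0$point, 0)
  expect_equal(c(s0$ci_low, s0$ci_high), c(0, 0))
})

test_that("the savings SE propagates the shared bacteriuria-risk dependence
           through one partial, not two", {
  sc <- fixture_scenario(); r <- fixture_risks(); cc <- fixture_costs()
  est <- estimate_with_ci(sc, r, cc, intervention(0.4, 0.4), "savings")
  # analytic: savings is (pre - post) and both factor through R almost
  # linearly; the R-partial of the difference must be far smaller than the
  # sum of the absolute partials of the two terms
  pre <- estimate_with_ci(sc, r, cc, no_intervention(), "current_cost")
  post <- estimate_with_ci(sc, r, cc, intervention(0.4, 0.4),
                           "projected_cost")
  g_r <- abs(est$gradient[["bacteriuria_risk"]])
  expect_lt(g_r, abs(pre$gradient[["bacteriuria_risk"]]) +
              abs(post$gradient[["bacteriuria_risk"]]))
  # and the savings SE is below the naive independent-difference SE
  expect_lt(est$se, sqrt(pre$se^2 + post$se^2))
})

test_that("Monte-Carlo propagation is seed-deterministic and matches the
           delta SE in the small-CV regime", {
  sc <- fixture_scenario()
  a <- monte_carlo_propagation(sc, fixture_risks(), fixture_costs(),
                               quantity = "current_cost", n_draws = 2000,
                               seed = 11)
  b <- monte_carlo_propagation(sc, fixture_risks(), fixture_costs(),
                               quantity = "current_cost", n_draws = 2000,
                               seed = 11)
  expect_identical(a, b)
  expect_error(monte_carlo_propagation(sc, fixture_risks(), fixture_costs(),
                                       quantity = "current_cost",
                                       n_draws = 10, seed = 1),
               "at least 1000")
  # SEs scaled down by 20x: first-order delta becomes accurate
  k <- 0.05
  risks_small <- risk_params(bacteriuria_risk_se = 0.0153 * k,
                             suti_risk_se = 0.0408 * k,
                             bsi_risk_se = 0.0010 * k)
  costs_small <- cost_params(suti_cost_se = 911 * k, bsi_cost_se = 3824 * k)
  mc <- monte_carlo_propagation(sc, risks_small, costs_small,
                                quantity = "current_cost", n_draws = 1e5,
                                seed = 3)
  dm <- estimate_with_ci(sc, risks_small, costs_small,
                         quantity = "current_cost")
  expect_equal(mc$se, dm$se, tolerance = 0.05)
  expect_equal(mc$mean, dm$point, tolerance = 0.01)
  # all SEs zero -> zero spread
  mc0 <- monte_carlo_propagation(
    sc,
    risk_params(bacteriuria_risk_se = 0, suti_risk_se = 0, bsi_risk_se = 0),
    cost_params(suti_cost_se = 0, bsi_cost_se = 0),
    quantity = "current_cost", n_draws = 1000, seed = 5
  )
  expect_equal(mc0$se, 0)
})
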
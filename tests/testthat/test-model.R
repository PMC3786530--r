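test_that("post-intervention bacteriuria risk has the right endpoints", {
  expect_equal(post_intervention_bacteriuria_risk(0.26, 0), 0.26)
  expect_equal(post_intervention_bacteriuria_risk(0.26, 1), 0)
  expect_equal(post_intervention_bacteriuria_risk(0, 0.5), 0)
  expect_error(post_intervention_bacteriuria_risk(1, 0.5), "\\[0, 1\\)")
  expect_error(post_intervention_bacteriuria_risk(0.26, 1.5), "\\[0, 1\\]")
})

test_that("post-intervention risk matches the competing-hazard closed form", {
  # frozen from the competing-exponential simulation oracle (n = 1e6), which
  # gives 0.1741 +/- 0.0004 for a 40% duration reduction at baseline 26%
  expect_equal(post_intervention_bacteriuria_risk(0.26, 0.4),
               0.156 / 0.896, tolerance = 1e-12)
  expect_equal(post_intervention_bacteriuria_risk(0.26, 0.4), 0.1741071,
               tolerance = 1e-6)
})

test_that("post-intervention risk is monotone nonincreasing in the
           duration reduction and bounded by the baseline risk", {
  for (R in c(0.01, 0.1, 0.26, 0.5, 0.9, 0.99)) {
    fds <- seq(0, 1, by = 0.05)
    vals <- vapply(fds, function(f) post_intervention_bacteriuria_risk(R, f),
                   numeric(1))
    expect_true(all(diff(vals) <= 1e-12))
    expect_true(all(vals >= 0 & vals <= R))
    expect_equal(vals[[1]], R)
    expect_equal(vals[[length(vals)]], 0)
  }
})

test_that("expected counts reproduce the trajectory factorization", {
  counts <- expected_counts(fixture_scenario(), fixture_risks())
  expect_equal(counts$n_catheterized, 450)
  expect_equal(counts$n_bacteriuria, 117)
  expect_equal(counts$n_suti_only, 23.868)
  expect_equal(counts$n_bsi, 4.212)
  # trajectory ordering invariant
  expect_lte(counts$n_bsi + counts$n_suti_only, counts$n_bacteriuria)
  expect_lte(counts$n_bacteriuria, counts$n_catheterized)
})

test_that("zero admissions give zero counts and zero cost", {
  counts <- expected_counts(hospital_scenario(0, 0.5), fixture_risks())
  expect_true(all(unlist(counts) == 0))
  expect_equal(expected_cost(counts, fixture_costs()), 0)
})

test_that("expected cost is the SUTI/BSI-weighted count sum", {
  counts <- expected_counts(fixture_scenario(), fixture_risks())
  expect_equal(expected_cost(counts, fixture_costs()),
               911 * 23.868 + 3824 * 4.212)
  expect_equal(expected_cost(counts, cost_params(0, 0, 0, 0)), 0)
})

test_that("expected cost is linear in costs and admissions", {
  set.seed(41)
  for (i in 1:5) {
    p <- random_valid_params()
    base <- scenario_cost(p$scenario, p$risks, p$costs)
    doubled_n <- hospital_scenario(2 * p$scenario$admissions,
                                   p$scenario$prop_catheterized)
    expect_equal(scenario_cost(doubled_n, p$risks, p$costs), 2 * base)
    tripled_costs <- cost_params(3 * p$costs$suti_cost, p$costs$suti_cost_se,
                                 3 * p$costs$bsi_cost, p$costs$bsi_cost_se)
    expect_equal(scenario_cost(p$scenario, p$risks, tripled_costs), 3 * base)
  }
})

test_that("savings is nonnegative, monotone in both reductions, and bounded
           by current cost", {
  sc <- fixture_scenario(); r <- fixture_risks(); cc <- fixture_costs()
  current <- scenario_cost(sc, r, cc)
  expect_equal(savings(sc, r, cc, no_intervention()), 0)
  fs <- seq(0, 1, by = 0.2)
  by_fp <- vapply(fs, function(f) savings(sc, r, cc, intervention(f, 0.3)),
                  numeric(1))
  by_fd <- vapply(fs, function(f) savings(sc, r, cc, intervention(0.3, f)),
                  numeric(1))
  expect_true(all(diff(by_fp) >= -1e-9))
  expect_true(all(diff(by_fd) >= -1e-9))
  expect_true(all(by_fp <= current + 1e-9))
  expect_equal(savings(sc, r, cc, intervention(1, 0)), current)
})

test_that("hazard consistency check reports the implied overall risk", {
  # 5%/day over 6.68 days implies 25.04%, within 4% of the stated 26%
  expect_silent(implied <- hazard_consistency_check(fixture_risks()))
  expect_equal(implied, 0.05 / (0.05 + 1 / 6.68))
  # a zero per-day hazard implies zero overall risk (and warns about the
  # mismatch with the stated 26% baseline)
  expect_warning(
    implied0 <- hazard_consistency_check(risk_params(per_day_bact_risk = 0)),
    "differs"
  )
  expect_equal(implied0, 0)
  # asymptote: risk -> 1 as duration grows
  long <- risk_params(per_day_bact_risk = 0.05, mean_duration_days = 1e9)
  expect_equal(suppressWarnings(hazard_consistency_check(long)), 1,
               tolerance = 1e-6)
  # a large mismatch warns but does not error
  off <- risk_params(bacteriuria_risk = 0.5, per_day_bact_risk = 0.05,
                     mean_duration_days = 6.68)
  expect_warning(hazard_consistency_check(off), "differs")
})
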
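# shared fixtures: the hypothetical 3000-admission hospital with the packaged
# literature defaults
fixture_scenario <- function() hospital_scenario(3000, 0.15)
fixture_risks <- function() default_risk_params()
fixture_costs <- function() default_cost_params()

# analytic partial derivatives of the current-cost map
#   C(theta) = N p R ((qS - qB) cS + qB cB)
# used as the independent check on the numeric delta-method machinery
analytic_cost_gradient <- function(scenario, risks, costs) {
  np <- scenario$admissions * scenario$prop_catheterized
  R <- risks$bacteriuria_risk
  qS <- risks$suti_risk
  qB <- risks$bsi_risk
  cS <- costs$suti_cost
  cB <- costs$bsi_cost
  c(
    bacteriuria_risk = np * ((qS - qB) * cS + qB * cB),
    suti_risk = np * R * cS,
    bsi_risk = np * R * (cB - cS),
    suti_cost = np * R * (qS - qB),
    bsi_cost = np * R * qB
  )
}

# random-but-valid parameter draws for property sweeps
random_valid_params <- function() {
  qS <- runif(1, 0.05, 0.6)
  list(
    risks = risk_params(
      bacteriuria_risk = runif(1, 0.05, 0.6),
      bacteriuria_risk_se = runif(1, 0, 0.05),
      suti_risk = qS,
      suti_risk_se = runif(1, 0, 0.05),
      bsi_risk = runif(1, 0, qS),
      bsi_risk_se = runif(1, 0, 0.01),
      per_day_bact_risk = runif(1, 0.01, 0.2),
      mean_duration_days = runif(1, 2, 12)
    ),
    costs = cost_params(
      suti_cost = runif(1, 100, 3000),
      suti_cost_se = runif(1, 0, 3000),
      bsi_cost = runif(1, 3000, 10000),
      bsi_cost_se = runif(1, 0, 10000)
    ),
    scenario = hospital_scenario(round(runif(1, 500, 20000)),
                                 runif(1, 0.02, 0.6))
  )
}
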
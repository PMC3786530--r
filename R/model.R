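#' Bacteriuria risk after a reduction in catheterization duration
#'
#' Shortening the mean catheterization time lowers the chance that bacteriuria
#' develops before the catheter is removed. Under constant per-day hazards of
#' bacteriuria and of catheter removal, the pre-intervention risk R satisfies
#' R = lambda_b / (lambda_b + lambda_r); scaling mean duration by
#' (1 - f_d) multiplies the removal hazard by 1 / (1 - f_d), which scales the
#' odds R / (1 - R) by (1 - f_d). The post-intervention risk is therefore
#' \deqn{R' = \frac{(1 - f_d)\,R}{1 - f_d R}.}
#'
#' @param risk Pre-intervention bacteriuria risk among the catheterized, in
#'   `[0, 1)`.
#' @param duration_reduction Fractional reduction in mean catheterization
#'   duration, in `[0, 1]`.
#' @return The post-intervention bacteriuria risk, in `[0, risk]`.
#' @examples
#' post_intervention_bacteriuria_risk(0.26, 0.40)
#' @export
post_intervention_bacteriuria_risk <- function(risk, duration_reduction) {
  check_scalar(risk, "risk")
  if (risk < 0 || risk >= 1) {
    stop("`risk` must lie in [0, 1), got ", risk, ".", call. = FALSE)
  }
  check_proportion(duration_reduction, "duration_reduction")
  (1 - duration_reduction) * risk / (1 - duration_reduction * risk)
}

#' Expected patient counts along the infection trajectories
#'
#' Factorizes the expected number of patients on each costed trajectory:
#' catheterized, bacteriuric, SUTI without BSI, and BSI. An intervention
#' reduces the catheterized count by its placement reduction and the
#' bacteriuria risk through [post_intervention_bacteriuria_risk()]; the
#' conditional SUTI and BSI risks are unchanged by intervention. Counts are
#' expectations and therefore real-valued, not rounded.
#'
#' @param scenario A [hospital_scenario].
#' @param risks A [risk_params].
#' @param intervention An [intervention]; the default `no_intervention()`
#'   gives current-state counts.
#' @return A one-row tibble with columns `n_catheterized`, `n_bacteriuria`,
#'   `n_suti_only`, `n_bsi`.
#' @examples
#' hospital_scenario(3000, 0.15) |> expected_counts(default_risk_params())
#' @export
expected_counts <- function(scenario, risks, intervention = no_intervention()) {
  scenario <- as_scenario(scenario)
  risks <- as_risk_params(risks)
  intervention <- as_intervention(intervention)

  n_cath <- scenario$admissions * scenario$prop_catheterized *
    (1 - intervention$placement_reduction)
  r_eff <- post_intervention_bacteriuria_risk(
    risks$bacteriuria_risk, intervention$duration_reduction
  )
  n_bact <- n_cath * r_eff
  tibble::tibble(
    n_catheterized = n_cath,
    n_bacteriuria = n_bact,
    n_suti_only = n_bact * (risks$suti_risk - risks$bsi_risk),
    n_bsi = n_bact * risks$bsi_risk
  )
}

#' Expected annual CAUTI cost from trajectory counts
#'
#' Total expected cost is the per-patient SUTI cost times the expected number
#' of patients with SUTI but no BSI, plus the per-patient BSI cost times the
#' expected number with BSI. Asymptomatic bacteriuria is costless, and a
#' patient with both SUTI and BSI is costed at the BSI cost alone.
#'
#' @param counts A tibble from [expected_counts()] (columns `n_suti_only` and
#'   `n_bsi`).
#' @param costs A [cost_params].
#' @return Expected annual cost in USD (scalar).
#' @examples
#' hospital_scenario(3000, 0.15) |>
#'   expected_counts(default_risk_params()) |>
#'   expected_cost(default_cost_params())
#' @export
expected_cost <- function(counts, costs) {
  costs <- as_cost_params(costs)
  if (!is.data.frame(counts) ||
      !all(c("n_suti_only", "n_bsi") %in% names(counts))) {
    stop("`counts` must be a data frame with columns `n_suti_only`, `n_bsi` ",
         "(see `expected_counts()`).", call. = FALSE)
  }
  sum(costs$suti_cost * counts$n_suti_only + costs$bsi_cost * counts$n_bsi)
}

#' Expected annual cost for a scenario under an intervention
#'
#' Convenience composition of [expected_counts()] and [expected_cost()].
#'
#' @inheritParams expected_counts
#' @param costs A [cost_params].
#' @return Expected annual cost in USD (scalar).
#' @export
scenario_cost <- function(scenario, risks, costs,
                          intervention = no_intervention()) {
  expected_cost(expected_counts(scenario, risks, intervention), costs)
}

#' Projected annual savings from an intervention
#'
#' Current-state expected cost minus post-intervention expected cost.
#' Nonnegative for any placement/duration reductions in `[0, 1]`.
#'
#' @inheritParams scenario_cost
#' @return Projected annual savings in USD (scalar).
#' @examples
#' savings(hospital_scenario(3000, 0.15), default_risk_params(),
#'         default_cost_params(), intervention(0.40, 0.40))
#' @export
savings <- function(scenario, risks, costs, intervention) {
  scenario_cost(scenario, risks, costs, no_intervention()) -
    scenario_cost(scenario, risks, costs, intervention)
}

#' Consistency check between the per-day and overall bacteriuria risks
#'
#' With a constant per-day bacteriuria hazard lambda_b and a constant removal
#' hazard 1/d (d the mean catheterization duration), the implied overall risk
#' of bacteriuria before removal is lambda_b / (lambda_b + 1/d). This
#' diagnostic computes that implied risk from `per_day_bact_risk` and
#' `mean_duration_days` and warns (without erroring) if it differs from the
#' stated overall `bacteriuria_risk` by more than 10% relative.
#'
#' @param risks A [risk_params].
#' @return The implied overall bacteriuria risk (scalar), invisibly compared
#'   against `risks$bacteriuria_risk`.
#' @examples
#' hazard_consistency_check(default_risk_params())
#' @export
hazard_consistency_check <- function(risks) {
  risks <- as_risk_params(risks)
  lambda_b <- risks$per_day_bact_risk
  implied <- if (lambda_b == 0) 0 else {
    lambda_b / (lambda_b + 1 / risks$mean_duration_days)
  }
  stated <- risks$bacteriuria_risk
  if (stated > 0) {
    rel <- abs(implied - stated) / stated
    if (rel > 0.10) {
      warning(sprintf(
        paste0("per-day risk %.3f over %.2f days implies an overall ",
               "bacteriuria risk of %.3f, which differs from the stated ",
               "%.3f by %.0f%% relative"),
        lambda_b, risks$mean_duration_days, implied, stated, 100 * rel
      ), call. = FALSE)
    }
  }
  implied
}

# hazard of bacteriuria per day implied by overall risk R and mean duration d:
# R = lambda_b / (lambda_b + 1/d)  =>  lambda_b = R / (d (1 - R))
bacteriuria_hazard <- function(risk, mean_duration_days) {
  if (risk >= 1) stop("overall bacteriuria risk must be < 1.", call. = FALSE)
  risk / (mean_duration_days * (1 - risk))
}
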
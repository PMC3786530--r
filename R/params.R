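#' Catheterization-conditional infection risk parameters
#'
#' Bundles the risk inputs of the CAUTI cost model: the overall risk of
#' bacteriuria among catheterized patients (with its standard error), the
#' conditional risks of symptomatic UTI (SUTI) and bloodstream infection (BSI)
#' among catheterized patients who develop bacteriuria, and the per-day
#' bacteriuria hazard together with the mean catheterization duration. All
#' proportions are on the \eqn{[0,1]} scale; percentage inputs must be divided
#' by 100 before they reach this constructor.
#'
#' The per-day risk and mean duration are used only by the hazard consistency
#' diagnostic and the cohort microsimulator; the cost pipeline itself works
#' from the overall bacteriuria risk.
#'
#' @param bacteriuria_risk Overall risk of bacteriuria among the catheterized.
#' @param bacteriuria_risk_se Standard error of `bacteriuria_risk`.
#' @param suti_risk Risk of SUTI among catheterized patients with bacteriuria.
#' @param suti_risk_se Standard error of `suti_risk`.
#' @param bsi_risk Risk of BSI among catheterized patients with bacteriuria.
#'   Must not exceed `suti_risk`: BSI is assumed to follow SUTI, so the
#'   SUTI-but-no-BSI probability `suti_risk - bsi_risk` must be nonnegative.
#' @param bsi_risk_se Standard error of `bsi_risk`.
#' @param per_day_bact_risk Per-day risk of bacteriuria while catheterized.
#' @param mean_duration_days Mean catheterization duration in days.
#' @return An object of class `risk_params`.
#' @examples
#' default_risk_params()
#' risk_params(bacteriuria_risk = 0.20, suti_risk = 0.30, bsi_risk = 0.02)
#' @export
risk_params <- function(bacteriuria_risk = 0.26,
                        bacteriuria_risk_se = 0.0153,
                        suti_risk = 0.24,
                        suti_risk_se = 0.0408,
                        bsi_risk = 0.036,
                        bsi_risk_se = 0.0010,
                        per_day_bact_risk = 0.05,
                        mean_duration_days = 6.68) {
  check_proportion(bacteriuria_risk, "bacteriuria_risk")
  check_proportion(suti_risk, "suti_risk")
  check_proportion(bsi_risk, "bsi_risk")
  check_proportion(per_day_bact_risk, "per_day_bact_risk")
  check_nonnegative(bacteriuria_risk_se, "bacteriuria_risk_se")
  check_nonnegative(suti_risk_se, "suti_risk_se")
  check_nonnegative(bsi_risk_se, "bsi_risk_se")
  check_positive(mean_duration_days, "mean_duration_days")
  if (bsi_risk > suti_risk) {
    stop("`bsi_risk` (", bsi_risk, ") must not exceed `suti_risk` (",
         suti_risk, "): BSI is assumed to be preceded by SUTI.",
         call. = FALSE)
  }
  structure(
    list(
      bacteriuria_risk = bacteriuria_risk,
      bacteriuria_risk_se = bacteriuria_risk_se,
      suti_risk = suti_risk,
      suti_risk_se = suti_risk_se,
      bsi_risk = bsi_risk,
      bsi_risk_se = bsi_risk_se,
      per_day_bact_risk = per_day_bact_risk,
      mean_duration_days = mean_duration_days
    ),
    class = "risk_params"
  )
}

#' Per-patient infection cost parameters
#'
#' Per-patient attributable hospital costs of a symptomatic UTI and of a
#' bloodstream infection, in US dollars, with their standard errors. A patient
#' who develops both SUTI and BSI is costed at the BSI cost only.
#'
#' @param suti_cost Per-patient SUTI cost (USD).
#' @param suti_cost_se Standard error of `suti_cost`.
#' @param bsi_cost Per-patient BSI cost (USD).
#' @param bsi_cost_se Standard error of `bsi_cost`.
#' @return An object of class `cost_params`.
#' @examples
#' default_cost_params()
#' @export
cost_params <- function(suti_cost = 911,
                        suti_cost_se = 911,
                        bsi_cost = 3824,
                        bsi_cost_se = 3824) {
  check_nonnegative(suti_cost, "suti_cost")
  check_nonnegative(suti_cost_se, "suti_cost_se")
  check_nonnegative(bsi_cost, "bsi_cost")
  check_nonnegative(bsi_cost_se, "bsi_cost_se")
  structure(
    list(
      suti_cost = suti_cost,
      suti_cost_se = suti_cost_se,
      bsi_cost = bsi_cost,
      bsi_cost_se = bsi_cost_se
    ),
    class = "cost_params"
  )
}

#' Hospital scenario
#'
#' The two hospital-specific inputs: annual admissions and the proportion of
#' admitted patients who receive a urinary catheter.
#'
#' @param admissions Annual admissions (nonnegative count).
#' @param prop_catheterized Proportion of admissions catheterized, in [0, 1].
#' @return An object of class `hospital_scenario`.
#' @examples
#' hospital_scenario(admissions = 3000, prop_catheterized = 0.15)
#' @export
hospital_scenario <- function(admissions, prop_catheterized) {
  check_nonnegative(admissions, "admissions")
  check_proportion(prop_catheterized, "prop_catheterized")
  structure(
    list(admissions = admissions, prop_catheterized = prop_catheterized),
    class = "hospital_scenario"
  )
}

#' Catheter-use intervention
#'
#' An intervention characterized by a fractional reduction in catheter
#' placement (the proportion catheterized) and a fractional reduction in mean
#' catheterization duration. `intervention(0, 0)` is the null intervention and
#' yields current-state (pre-intervention) quantities.
#'
#' @param placement_reduction Fractional reduction in placement, in [0, 1].
#' @param duration_reduction Fractional reduction in mean duration, in [0, 1].
#' @return An object of class `intervention`.
#' @examples
#' intervention(0.40, 0.40)
#' no_intervention()
#' @export
intervention <- function(placement_reduction = 0, duration_reduction = 0) {
  check_proportion(placement_reduction, "placement_reduction")
  check_proportion(duration_reduction, "duration_reduction")
  structure(
    list(
      placement_reduction = placement_reduction,
      duration_reduction = duration_reduction
    ),
    class = "intervention"
  )
}

#' @rdname intervention
#' @export
no_intervention <- function() intervention(0, 0)

#' Literature default parameters
#'
#' Default risk and cost parameters assembled from published meta-analytic
#' risk estimates and microcosting-based, inflation-adjusted per-patient
#' costs: bacteriuria risk 26.0% (SE 1.53%) among the catheterized, SUTI risk
#' 24.0% (SE 4.08%) and BSI risk 3.6% (SE 0.10%) among those with bacteriuria,
#' per-day bacteriuria risk 5.0% over a 6.68-day mean catheterization, and
#' per-patient costs of $911 (SE $911) for SUTI and $3824 (SE $3824) for BSI.
#'
#' @return `default_risk_params()` returns a [risk_params] object;
#'   `default_cost_params()` returns a [cost_params] object.
#' @export
default_risk_params <- function() risk_params()

#' @rdname default_risk_params
#' @export
default_cost_params <- function() cost_params()

#' @export
print.risk_params <- function(x, ...) {
  cat("<risk_params>\n")
  cat(sprintf("  bacteriuria risk (catheterized): %.1f%% (SE %.2f%%)\n",
              100 * x$bacteriuria_risk, 100 * x$bacteriuria_risk_se))
  cat(sprintf("  SUTI risk (bacteriuric):         %.1f%% (SE %.2f%%)\n",
              100 * x$suti_risk, 100 * x$suti_risk_se))
  cat(sprintf("  BSI risk (bacteriuric):          %.1f%% (SE %.2f%%)\n",
              100 * x$bsi_risk, 100 * x$bsi_risk_se))
  cat(sprintf("  per-day bacteriuria risk:        %.1f%%\n",
              100 * x$per_day_bact_risk))
  cat(sprintf("  mean catheterization:            %.2f days\n",
              x$mean_duration_days))
  invisible(x)
}

#' @export
print.cost_params <- function(x, ...) {
  cat("<cost_params>\n")
  cat(sprintf("  SUTI: $%s (SE $%s)\n", format(x$suti_cost, big.mark = ","),
              format(x$suti_cost_se, big.mark = ",")))
  cat(sprintf("  BSI:  $%s (SE $%s)\n", format(x$bsi_cost, big.mark = ","),
              format(x$bsi_cost_se, big.mark = ",")))
  invisible(x)
}

#' @export
print.hospital_scenario <- function(x, ...) {
  cat("<hospital_scenario>\n")
  cat(sprintf("  admissions: %s/year, %.1f%% catheterized\n",
              format(x$admissions, big.mark = ","),
              100 * x$prop_catheterized))
  invisible(x)
}

#' @export
print.intervention <- function(x, ...) {
  cat(sprintf("<intervention> placement -%.0f%%, duration -%.0f%%\n",
              100 * x$placement_reduction, 100 * x$duration_reduction))
  invisible(x)
}

# input checks ---------------------------------------------------------------

check_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop("`", name, "` must be a single finite number.", call. = FALSE)
  }
}

check_proportion <- function(x, name) {
  check_scalar(x, name)
  if (x < 0 || x > 1) {
    stop("`", name, "` must lie in [0, 1], got ", x, ".", call. = FALSE)
  }
}

check_nonnegative <- function(x, name) {
  check_scalar(x, name)
  if (x < 0) stop("`", name, "` must be >= 0, got ", x, ".", call. = FALSE)
}

check_positive <- function(x, name) {
  check_scalar(x, name)
  if (x <= 0) stop("`", name, "` must be > 0, got ", x, ".", call. = FALSE)
}

check_fraction_vec <- function(x, name) {
  if (!is.numeric(x) || length(x) == 0L || anyNA(x)) {
    stop("`", name, "` must be a nonempty numeric vector.", call. = FALSE)
  }
  if (any(x < 0 | x > 1)) {
    stop("`", name, "` values must lie in [0, 1].", call. = FALSE)
  }
  if (is.unsorted(x, strictly = FALSE)) {
    stop("`", name, "` must be sorted ascending.", call. = FALSE)
  }
  invisible(x)
}

as_risk_params <- function(x) {
  if (inherits(x, "risk_params")) return(x)
  stop("expected a `risk_params` object; see `risk_params()`.", call. = FALSE)
}

as_cost_params <- function(x) {
  if (inherits(x, "cost_params")) return(x)
  stop("expected a `cost_params` object; see `cost_params()`.", call. = FALSE)
}

as_scenario <- function(x) {
  if (inherits(x, "hospital_scenario")) return(x)
  stop("expected a `hospital_scenario` object; see `hospital_scenario()`.",
       call. = FALSE)
}

as_intervention <- function(x) {
  if (is.null(x)) return(no_intervention())
  if (inherits(x, "intervention")) return(x)
  stop("expected an `intervention` object; see `intervention()`.",
       call. = FALSE)
}
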
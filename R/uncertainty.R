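#' The vector of uncertain model parameters
#'
#' Collects the five uncertain inputs of the cost model — bacteriuria risk,
#' conditional SUTI and BSI risks, and the two per-patient costs — with their
#' standard errors, in a fixed order. The per-day bacteriuria risk and the
#' mean catheterization duration carry no standard errors and are treated as
#' fixed. Parameters are treated as mutually independent.
#'
#' @param risks A [risk_params].
#' @param costs A [cost_params].
#' @return A five-row tibble with columns `parameter`, `value`, `se`.
#' @examples
#' param_vector(default_risk_params(), default_cost_params())
#' @export
param_vector <- function(risks, costs) {
  risks <- as_risk_params(risks)
  costs <- as_cost_params(costs)
  tibble::tibble(
    parameter = c("bacteriuria_risk", "suti_risk", "bsi_risk",
                  "suti_cost", "bsi_cost"),
    value = c(risks$bacteriuria_risk, risks$suti_risk, risks$bsi_risk,
              costs$suti_cost, costs$bsi_cost),
    se = c(risks$bacteriuria_risk_se, risks$suti_risk_se, risks$bsi_risk_se,
           costs$suti_cost_se, costs$bsi_cost_se)
  )
}

#' Central-difference gradient of a scalar objective
#'
#' Numerical partial derivatives of `objective` with respect to each
#' parameter in `params`, by central differences with a relative step
#' (absolute floor `1e-9` for parameters near zero).
#'
#' @param objective A function taking a named numeric vector of parameter
#'   values and returning a finite scalar.
#' @param params A tibble as returned by [param_vector()] (columns
#'   `parameter` and `value`; `se` is ignored here).
#' @param step Relative step size (default `1e-6`).
#' @return A named numeric vector of partial derivatives.
#' @export
numeric_gradient <- function(objective, params, step = 1e-6) {
  stopifnot(is.function(objective), is.data.frame(params))
  check_positive(step, "step")
  values <- stats::setNames(params$value, params$parameter)
  f0 <- objective(values)
  if (!is.finite(f0)) {
    stop("objective is not finite at the supplied parameter values.",
         call. = FALSE)
  }
  grad <- vapply(seq_along(values), function(i) {
    h <- max(step * abs(values[[i]]), 1e-9)
    up <- values; up[[i]] <- values[[i]] + h
    dn <- values; dn[[i]] <- values[[i]] - h
    fu <- objective(up)
    fd <- objective(dn)
    if (!is.finite(fu) || !is.finite(fd)) {
      stop("objective is not finite when perturbing `",
           names(values)[[i]], "`.", call. = FALSE)
    }
    (fu - fd) / (2 * h)
  }, numeric(1))
  stats::setNames(grad, names(values))
}

#' Delta-method variance of a scalar objective
#'
#' First-order (delta-method) variance under independence:
#' \eqn{\sum_i (\partial T/\partial \theta_i)^2 \mathrm{SE}_i^2}. For savings,
#' pass the full pre-minus-post map as one objective so that the shared
#' dependence of both cost terms on the bacteriuria risk is propagated
#' through a single partial derivative rather than double-counted.
#'
#' @inheritParams numeric_gradient
#' @return The approximate variance of the objective (scalar).
#' @export
delta_variance <- function(objective, params, step = 1e-6) {
  grad <- numeric_gradient(objective, params, step = step)
  sum(grad^2 * params$se^2)
}

#' Log-scale (multiplicative) confidence interval
#'
#' Confidence interval for a positive quantity, symmetric on the log scale:
#' `point * exp(-z * cv)` to `point * exp(+z * cv)` with `cv = se / point` and
#' `z` the standard-normal quantile at `(1 + level) / 2`. The interval
#' satisfies `ci_high / point == point / ci_low` and always stays positive,
#' which suits heavily right-skewed cost estimates whose input coefficients of
#' variation are large.
#'
#' @param point Point estimate; must be positive for a meaningful interval.
#' @param se Standard error (nonnegative).
#' @param level Coverage level in (0, 1); default 0.95.
#' @return A named numeric vector `c(ci_low, ci_high)`. For `point <= 0` the
#'   degenerate interval `c(0, 0)` is returned with a warning.
#' @examples
#' lognormal_ci(37850, 27500)
#' @export
lognormal_ci <- function(point, se, level = 0.95) {
  check_scalar(point, "point")
  check_nonnegative(se, "se")
  check_scalar(level, "level")
  if (level <= 0 || level >= 1) {
    stop("`level` must lie strictly between 0 and 1.", call. = FALSE)
  }
  if (point <= 0) {
    warning("point estimate is not positive; returning a degenerate (0, 0) ",
            "interval.", call. = FALSE)
    return(c(ci_low = 0, ci_high = 0))
  }
  z <- stats::qnorm((1 + level) / 2)
  half <- z * se / point
  c(ci_low = point * exp(-half), ci_high = point * exp(half))
}

# closed-form expected cost as a plain function of the five uncertain
# parameters (vectorized so Monte-Carlo draws evaluate in one pass)
cost_value <- function(bact_risk, suti_risk, bsi_risk, suti_cost, bsi_cost,
                       admissions, prop_cath, placement_reduction,
                       duration_reduction) {
  r_eff <- (1 - duration_reduction) * bact_risk /
    (1 - duration_reduction * bact_risk)
  admissions * prop_cath * (1 - placement_reduction) * r_eff *
    ((suti_risk - bsi_risk) * suti_cost + bsi_risk * bsi_cost)
}

# build the scalar objective theta -> quantity for the delta method / MC
quantity_objective <- function(scenario, intervention, quantity) {
  f_p <- intervention$placement_reduction
  f_d <- intervention$duration_reduction
  N <- scenario$admissions
  p <- scenario$prop_catheterized
  switch(quantity,
    current_cost = function(th) {
      cost_value(th[["bacteriuria_risk"]], th[["suti_risk"]],
                 th[["bsi_risk"]], th[["suti_cost"]], th[["bsi_cost"]],
                 N, p, 0, 0)
    },
    projected_cost = function(th) {
      cost_value(th[["bacteriuria_risk"]], th[["suti_risk"]],
                 th[["bsi_risk"]], th[["suti_cost"]], th[["bsi_cost"]],
                 N, p, f_p, f_d)
    },
    savings = function(th) {
      cost_value(th[["bacteriuria_risk"]], th[["suti_risk"]],
                 th[["bsi_risk"]], th[["suti_cost"]], th[["bsi_cost"]],
                 N, p, 0, 0) -
        cost_value(th[["bacteriuria_risk"]], th[["suti_risk"]],
                   th[["bsi_risk"]], th[["suti_cost"]], th[["bsi_cost"]],
                   N, p, f_p, f_d)
    },
    stop("`quantity` must be one of \"current_cost\", \"projected_cost\", ",
         "\"savings\".", call. = FALSE)
  )
}

#' Point estimate with delta-method SE and log-scale confidence interval
#'
#' Computes the requested quantity (current cost, projected post-intervention
#' cost, or savings), its delta-method standard error from the five uncertain
#' input parameters, and a log-scale confidence interval. The savings
#' objective is differentiated as a single pre-minus-post map, so the shared
#' dependence of both terms on the bacteriuria risk is handled correctly.
#'
#' @inheritParams scenario_cost
#' @param quantity One of `"current_cost"`, `"projected_cost"`, `"savings"`.
#' @param level Confidence level (default 0.95).
#' @return An object of class `cauti_estimate` with fields `point`, `se`,
#'   `ci_low`, `ci_high`, `level`, `quantity`, and the per-parameter gradient.
#'   Use [generics::tidy()] for the per-parameter variance decomposition and
#'   [generics::glance()] for a one-row summary.
#' @examples
#' estimate_with_ci(hospital_scenario(3000, 0.15), default_risk_params(),
#'                  default_cost_params(), intervention(0.4, 0.4), "savings")
#' @export
estimate_with_ci <- function(scenario, risks, costs,
                             intervention = no_intervention(),
                             quantity = c("current_cost", "projected_cost",
                                          "savings"),
                             level = 0.95) {
  scenario <- as_scenario(scenario)
  risks <- as_risk_params(risks)
  costs <- as_cost_params(costs)
  intervention <- as_intervention(intervention)
  quantity <- match.arg(quantity)

  params <- param_vector(risks, costs)
  objective <- quantity_objective(scenario, intervention, quantity)
  point <- objective(stats::setNames(params$value, params$parameter))
  grad <- numeric_gradient(objective, params)
  se <- sqrt(sum(grad^2 * params$se^2))
  if (point > 0 && se > 0) {
    ci <- lognormal_ci(point, se, level)
  } else if (point > 0) {
    ci <- c(ci_low = point, ci_high = point)
  } else {
    # zero (or negative) point: no meaningful multiplicative interval
    ci <- c(ci_low = 0, ci_high = 0)
  }
  structure(
    list(point = point, se = se,
         ci_low = unname(ci[["ci_low"]]), ci_high = unname(ci[["ci_high"]]),
         level = level, quantity = quantity,
         gradient = grad, params = params),
    class = "cauti_estimate"
  )
}

#' @export
print.cauti_estimate <- function(x, ...) {
  cat(sprintf("<cauti_estimate: %s>\n", x$quantity))
  cat(sprintf("  $%s (%.0f%% CI: $%s-$%s; SE $%s)\n",
              format(round(x$point), big.mark = ","), 100 * x$level,
              format(round(x$ci_low), big.mark = ","),
              format(round(x$ci_high), big.mark = ","),
              format(round(x$se), big.mark = ",")))
  invisible(x)
}

#' Tidy the per-parameter variance decomposition of an estimate
#'
#' @param x A `cauti_estimate`.
#' @param ... Unused.
#' @return A tibble with one row per uncertain parameter: its value, SE,
#'   partial derivative of the estimated quantity, and the parameter's
#'   contribution to the delta-method SE (`se_contribution`, whose squares sum
#'   to the total variance).
#' @export
tidy.cauti_estimate <- function(x, ...) {
  dplyr::mutate(
    dplyr::rename(x$params, term = "parameter", estimate = "value",
                  std.error = "se"),
    gradient = unname(x$gradient),
    se_contribution = abs(.data$gradient) * .data$std.error
  )
}

#' One-row summary of an estimate
#'
#' @param x A `cauti_estimate`.
#' @param ... Unused.
#' @return A one-row tibble with `quantity`, `point`, `se`, `ci_low`,
#'   `ci_high`, `level`.
#' @export
glance.cauti_estimate <- function(x, ...) {
  tibble::tibble(quantity = x$quantity, point = x$point, se = x$se,
                 ci_low = x$ci_low, ci_high = x$ci_high, level = x$level)
}

#' Monte-Carlo propagation of parameter uncertainty
#'
#' Verification oracle for the delta method: draws the five uncertain
#' parameters independently from domain-respecting distributions — gamma for
#' the per-patient costs (moment-matched to mean and SE; support strictly
#' positive) and logit-normal for the three risk proportions (mean and SE
#' matched numerically; support in (0, 1)) — evaluates the closed-form
#' quantity for each draw, and summarizes the draws. Draws in which the BSI
#' risk exceeds the SUTI risk are clipped (BSI set equal to SUTI) and the
#' clipped fraction is reported.
#'
#' With the default inputs the cost coefficients of variation equal 1, far
#' outside the small-CV regime where the first-order delta method is
#' accurate, so the empirical SD and the delta SE are not expected to agree
#' closely there; agreement within a few percent emerges when all SEs are
#' scaled down.
#'
#' @inheritParams estimate_with_ci
#' @param n_draws Number of parameter draws (>= 1000).
#' @param seed Integer seed; identical seeds give identical output.
#' @return A one-row tibble: `quantity`, `mean`, `se` (empirical SD of the
#'   draws), percentile `ci_low`/`ci_high` at `level`, `clipped_frac`,
#'   `n_draws`.
#' @export
monte_carlo_propagation <- function(scenario, risks, costs,
                                    intervention = no_intervention(),
                                    quantity = c("current_cost",
                                                 "projected_cost", "savings"),
                                    n_draws = 10000, seed,
                                    level = 0.95) {
  scenario <- as_scenario(scenario)
  risks <- as_risk_params(risks)
  costs <- as_cost_params(costs)
  intervention <- as_intervention(intervention)
  quantity <- match.arg(quantity)
  if (!is.numeric(n_draws) || n_draws < 1000) {
    stop("`n_draws` must be at least 1000.", call. = FALSE)
  }
  if (missing(seed)) stop("`seed` is required for reproducibility.",
                          call. = FALSE)

  draws <- with_local_seed(seed, {
    R <- draw_logit_normal(n_draws, risks$bacteriuria_risk,
                           risks$bacteriuria_risk_se)
    qS <- draw_logit_normal(n_draws, risks$suti_risk, risks$suti_risk_se)
    qB <- draw_logit_normal(n_draws, risks$bsi_risk, risks$bsi_risk_se)
    cS <- draw_gamma(n_draws, costs$suti_cost, costs$suti_cost_se)
    cB <- draw_gamma(n_draws, costs$bsi_cost, costs$bsi_cost_se)
    list(R = R, qS = qS, qB = qB, cS = cS, cB = cB)
  })
  clipped <- draws$qB > draws$qS
  draws$qB <- pmin(draws$qB, draws$qS)

  f_p <- intervention$placement_reduction
  f_d <- intervention$duration_reduction
  N <- scenario$admissions
  p <- scenario$prop_catheterized
  vals <- switch(quantity,
    current_cost = cost_value(draws$R, draws$qS, draws$qB, draws$cS,
                              draws$cB, N, p, 0, 0),
    projected_cost = cost_value(draws$R, draws$qS, draws$qB, draws$cS,
                                draws$cB, N, p, f_p, f_d),
    savings = cost_value(draws$R, draws$qS, draws$qB, draws$cS, draws$cB,
                         N, p, 0, 0) -
      cost_value(draws$R, draws$qS, draws$qB, draws$cS, draws$cB,
                 N, p, f_p, f_d)
  )
  qs <- stats::quantile(vals, probs = c((1 - level) / 2, (1 + level) / 2),
                        names = FALSE)
  tibble::tibble(
    quantity = quantity,
    mean = mean(vals),
    se = stats::sd(vals),
    ci_low = qs[[1]],
    ci_high = qs[[2]],
    clipped_frac = mean(clipped),
    n_draws = as.integer(n_draws)
  )
}

# draw helpers ---------------------------------------------------------------

# gamma moment-matched to (mean, sd); sd = 0 degenerates to the mean
draw_gamma <- function(n, mean, sd) {
  if (mean == 0 || sd == 0) return(rep(mean, n))
  shape <- (mean / sd)^2
  stats::rgamma(n, shape = shape, scale = sd^2 / mean)
}

# logit-normal moment-matched to (mean, sd) by numeric quadrature + optim
draw_logit_normal <- function(n, mean, sd) {
  if (sd == 0 || mean <= 0 || mean >= 1) return(rep(mean, n))
  ms <- logit_normal_match(mean, sd)
  stats::plogis(stats::rnorm(n, ms[["mu"]], ms[["sigma"]]))
}

# mean/sd of plogis(mu + sigma Z), Z ~ N(0,1), by fixed-grid quadrature
logit_normal_moments <- function(mu, sigma) {
  z <- seq(-8, 8, length.out = 401)
  w <- stats::dnorm(z)
  w <- w / sum(w)
  g <- stats::plogis(mu + sigma * z)
  m <- sum(w * g)
  v <- sum(w * (g - m)^2)
  c(mean = m, sd = sqrt(v))
}

logit_normal_match <- function(mean, sd) {
  obj <- function(par) {
    mom <- logit_normal_moments(par[[1]], exp(par[[2]]))
    (mom[["mean"]] - mean)^2 / mean^2 + (mom[["sd"]] - sd)^2 / sd^2
  }
  start <- c(stats::qlogis(mean), log(max(sd / (mean * (1 - mean)), 1e-3)))
  fit <- stats::optim(start, obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  c(mu = fit$par[[1]], sigma = exp(fit$par[[2]]))
}

# run code under a temporary RNG state so callers' streams are untouched
with_local_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(list = ".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}
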
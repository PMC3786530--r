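CONFIG_KEYS <- c(
  "admissions", "prop_catheterized",
  "bacteriuria_risk", "bacteriuria_risk_se",
  "suti_risk", "suti_risk_se",
  "bsi_risk", "bsi_risk_se",
  "suti_cost", "suti_cost_se",
  "bsi_cost", "bsi_cost_se",
  "per_day_bact_risk", "mean_duration_days",
  "placement_reduction", "duration_reduction",
  "ci_level"
)

#' Load a run configuration from a YAML or JSON file
#'
#' Reads a flat key/value configuration, validates it, and fills absent risk,
#' cost, and intervention keys with their defaults (the packaged literature
#' values for risks and costs; zero reductions; 95% confidence level).
#' `admissions` and `prop_catheterized` are required. Unknown keys trigger a
#' warning that lists them and are ignored.
#'
#' Recognized keys: `admissions`, `prop_catheterized`, `bacteriuria_risk`,
#' `bacteriuria_risk_se`, `suti_risk`, `suti_risk_se`, `bsi_risk`,
#' `bsi_risk_se`, `suti_cost`, `suti_cost_se`, `bsi_cost`, `bsi_cost_se`,
#' `per_day_bact_risk`, `mean_duration_days`, `placement_reduction`,
#' `duration_reduction`, `ci_level`.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `run_config`: a list with components `scenario`
#'   ([hospital_scenario]), `risks` ([risk_params]), `costs` ([cost_params]),
#'   `intervention` ([intervention]), `ci_level`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("no such file: '", path, "'.", call. = FALSE)
  raw <- tryCatch({
    if (grepl("\\.json$", path, ignore.case = TRUE)) {
      jsonlite::read_json(path, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(path)
    }
  }, error = function(e) {
    stop("could not parse config '", path, "': ", conditionMessage(e),
         call. = FALSE)
  })
  if (!is.list(raw) || is.null(names(raw))) {
    stop("config '", path, "' must be a flat key/value mapping.",
         call. = FALSE)
  }
  config_from_list(raw)
}

#' Build a run configuration from a named list
#'
#' The programmatic counterpart of [load_config()]; the same keys, defaults,
#' and validation apply.
#'
#' @param values A named list of configuration values.
#' @return A `run_config` list; see [load_config()].
#' @export
config_from_list <- function(values) {
  unknown <- setdiff(names(values), CONFIG_KEYS)
  if (length(unknown) > 0) {
    warning("ignoring unknown config keys: ",
            paste(unknown, collapse = ", "), call. = FALSE)
    values <- values[setdiff(names(values), unknown)]
  }
  missing_req <- setdiff(c("admissions", "prop_catheterized"), names(values))
  if (length(missing_req) > 0) {
    stop("missing required config keys: ",
         paste(missing_req, collapse = ", "), call. = FALSE)
  }
  get_num <- function(key, default) {
    v <- if (!is.null(values[[key]])) values[[key]] else default
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop("config key `", key, "` must be a single finite number.",
           call. = FALSE)
    }
    as.numeric(v)
  }
  defaults_r <- default_risk_params()
  defaults_c <- default_cost_params()
  scenario <- hospital_scenario(
    admissions = get_num("admissions", NA),
    prop_catheterized = get_num("prop_catheterized", NA)
  )
  risks <- risk_params(
    bacteriuria_risk = get_num("bacteriuria_risk", defaults_r$bacteriuria_risk),
    bacteriuria_risk_se = get_num("bacteriuria_risk_se",
                                  defaults_r$bacteriuria_risk_se),
    suti_risk = get_num("suti_risk", defaults_r$suti_risk),
    suti_risk_se = get_num("suti_risk_se", defaults_r$suti_risk_se),
    bsi_risk = get_num("bsi_risk", defaults_r$bsi_risk),
    bsi_risk_se = get_num("bsi_risk_se", defaults_r$bsi_risk_se),
    per_day_bact_risk = get_num("per_day_bact_risk",
                                defaults_r$per_day_bact_risk),
    mean_duration_days = get_num("mean_duration_days",
                                 defaults_r$mean_duration_days)
  )
  costs <- cost_params(
    suti_cost = get_num("suti_cost", defaults_c$suti_cost),
    suti_cost_se = get_num("suti_cost_se", defaults_c$suti_cost_se),
    bsi_cost = get_num("bsi_cost", defaults_c$bsi_cost),
    bsi_cost_se = get_num("bsi_cost_se", defaults_c$bsi_cost_se)
  )
  interv <- intervention(
    placement_reduction = get_num("placement_reduction", 0),
    duration_reduction = get_num("duration_reduction", 0)
  )
  ci_level <- get_num("ci_level", 0.95)
  if (ci_level <= 0 || ci_level >= 1) {
    stop("config key `ci_level` must lie strictly between 0 and 1.",
         call. = FALSE)
  }
  structure(
    list(scenario = scenario, risks = risks, costs = costs,
         intervention = interv, ci_level = ci_level),
    class = "run_config"
  )
}

#' Flatten a run configuration back to a named list
#'
#' Inverse of [config_from_list()]; `config_from_list(dump_config(x))`
#' reproduces `x`.
#'
#' @param config A `run_config`.
#' @return A named list with the full set of config keys.
#' @export
dump_config <- function(config) {
  stopifnot(inherits(config, "run_config"))
  list(
    admissions = config$scenario$admissions,
    prop_catheterized = config$scenario$prop_catheterized,
    bacteriuria_risk = config$risks$bacteriuria_risk,
    bacteriuria_risk_se = config$risks$bacteriuria_risk_se,
    suti_risk = config$risks$suti_risk,
    suti_risk_se = config$risks$suti_risk_se,
    bsi_risk = config$risks$bsi_risk,
    bsi_risk_se = config$risks$bsi_risk_se,
    suti_cost = config$costs$suti_cost,
    suti_cost_se = config$costs$suti_cost_se,
    bsi_cost = config$costs$bsi_cost,
    bsi_cost_se = config$costs$bsi_cost_se,
    per_day_bact_risk = config$risks$per_day_bact_risk,
    mean_duration_days = config$risks$mean_duration_days,
    placement_reduction = config$intervention$placement_reduction,
    duration_reduction = config$intervention$duration_reduction,
    ci_level = config$ci_level
  )
}

#' Full cost report for a configured scenario
#'
#' Runs the whole estimation pipeline for one configuration: current-cost,
#' projected-cost, and savings estimates (each with delta-method SE and
#' log-scale CI), the savings fraction, and an echo of the inputs. This is the
#' computation behind the command-line `estimate` subcommand; every number in
#' the report is reproducible by calling the underlying functions directly.
#'
#' @param config A `run_config` from [load_config()] or [config_from_list()].
#' @return A list of class `cauti_report`: `inputs` (named list),
#'   `current_cost`, `projected_cost`, `savings` (each a `cauti_estimate`),
#'   and `savings_fraction`. When current cost is zero, the savings fraction
#'   is `NA` and intervals are degenerate.
#' @examples
#' cfg <- config_from_list(list(admissions = 3000, prop_catheterized = 0.15,
#'                              placement_reduction = 0.29,
#'                              duration_reduction = 0.37))
#' run_estimate(cfg)
#' @export
run_estimate <- function(config) {
  stopifnot(inherits(config, "run_config"))
  current <- estimate_with_ci(config$scenario, config$risks, config$costs,
                              no_intervention(), "current_cost",
                              config$ci_level)
  projected <- estimate_with_ci(config$scenario, config$risks, config$costs,
                                config$intervention, "projected_cost",
                                config$ci_level)
  sav <- estimate_with_ci(config$scenario, config$risks, config$costs,
                          config$intervention, "savings", config$ci_level)
  frac <- if (current$point > 0) sav$point / current$point else NA_real_
  structure(
    list(
      inputs = dump_config(config),
      current_cost = current,
      projected_cost = projected,
      savings = sav,
      savings_fraction = frac
    ),
    class = "cauti_report"
  )
}

#' @export
print.cauti_report <- function(x, ...) {
  fmt <- function(e) {
    sprintf("$%s (%.0f%% CI: $%s-$%s)",
            format(round(e$point), big.mark = ","), 100 * e$level,
            format(round(e$ci_low), big.mark = ","),
            format(round(e$ci_high), big.mark = ","))
  }
  inp <- x$inputs
  cat("CAUTI cost report\n")
  cat("=================\n")
  cat(sprintf("Hospital: %s admissions/year, %.1f%% catheterized\n",
              format(inp$admissions, big.mark = ","),
              100 * inp$prop_catheterized))
  cat(sprintf("Intervention: placement -%.0f%%, duration -%.0f%%\n",
              100 * inp$placement_reduction, 100 * inp$duration_reduction))
  cat(sprintf("Current annual CAUTI cost:   %s\n", fmt(x$current_cost)))
  cat(sprintf("Projected post-intervention: %s\n", fmt(x$projected_cost)))
  cat(sprintf("Projected annual savings:    %s\n", fmt(x$savings)))
  if (!is.na(x$savings_fraction)) {
    cat(sprintf("Savings fraction:            %.1f%% of current cost\n",
                100 * x$savings_fraction))
  }
  invisible(x)
}

#' Serialize a report to JSON
#'
#' Writes the report with raw (unrounded) floats; estimates use the keys
#' `point`, `se`, `ci_low`, `ci_high`, `level`.
#'
#' @param report A `cauti_report` from [run_estimate()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "cauti_report"))
  as_est <- function(e) {
    list(point = e$point, se = e$se, ci_low = e$ci_low, ci_high = e$ci_high,
         level = e$level)
  }
  jsonlite::write_json(
    list(
      inputs = report$inputs,
      current_cost = as_est(report$current_cost),
      projected_cost = as_est(report$projected_cost),
      savings = as_est(report$savings),
      savings_fraction = report$savings_fraction
    ),
    path, digits = NA, auto_unbox = TRUE, null = "null", na = "null",
    pretty = TRUE
  )
  invisible(path)
}
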
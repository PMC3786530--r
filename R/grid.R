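#' Projected savings across a grid of interventions
#'
#' Evaluates projected annual savings, with delta-method standard errors and
#' log-scale confidence intervals, over every combination of placement and
#' duration reductions. The default grid spans 0%-50% in 10% steps on both
#' axes.
#'
#' @inheritParams estimate_with_ci
#' @param placement_fracs Ascending placement reductions in [0, 1].
#' @param duration_fracs Ascending duration reductions in [0, 1].
#' @return A tibble of class `cauti_grid`, one row per cell, with columns
#'   `placement_reduction`, `duration_reduction`, `savings`, `se`, `ci_low`,
#'   `ci_high`. The current-cost baseline estimate is attached as attribute
#'   `"baseline"` (a `cauti_estimate`); `glance()` reports it.
#' @examples
#' g <- savings_grid(hospital_scenario(3000, 0.15), default_risk_params(),
#'                   default_cost_params(),
#'                   placement_fracs = c(0, 0.4), duration_fracs = c(0, 0.4))
#' glance(g)
#' @export
savings_grid <- function(scenario, risks, costs,
                         placement_fracs = seq(0, 0.5, by = 0.1),
                         duration_fracs = seq(0, 0.5, by = 0.1),
                         level = 0.95) {
  scenario <- as_scenario(scenario)
  risks <- as_risk_params(risks)
  costs <- as_cost_params(costs)
  check_fraction_vec(placement_fracs, "placement_fracs")
  check_fraction_vec(duration_fracs, "duration_fracs")

  cells <- tidyr::expand_grid(
    placement_reduction = placement_fracs,
    duration_reduction = duration_fracs
  )
  est <- purrr::pmap(cells, function(placement_reduction, duration_reduction) {
    e <- estimate_with_ci(
      scenario, risks, costs,
      intervention(placement_reduction, duration_reduction),
      quantity = "savings", level = level
    )
    tibble::tibble(savings = e$point, se = e$se,
                   ci_low = e$ci_low, ci_high = e$ci_high)
  })
  out <- dplyr::bind_cols(cells, dplyr::bind_rows(est))
  baseline <- estimate_with_ci(scenario, risks, costs, no_intervention(),
                               quantity = "current_cost", level = level)
  structure(out, baseline = baseline, level = level,
            class = c("cauti_grid", class(out)))
}

#' @export
print.cauti_grid <- function(x, ...) {
  b <- attr(x, "baseline")
  cat(sprintf("# Savings grid (%d cells); baseline current cost $%s\n",
              nrow(x), format(round(b$point), big.mark = ",")))
  NextMethod()
}

#' One-row summary of a savings grid
#'
#' @param x A `cauti_grid`.
#' @param ... Unused.
#' @return A one-row tibble with the grid dimensions and the baseline
#'   current-cost estimate (`current_cost`, `current_se`, `current_ci_low`,
#'   `current_ci_high`, `level`).
#' @export
glance.cauti_grid <- function(x, ...) {
  b <- attr(x, "baseline")
  tibble::tibble(
    n_cells = nrow(x),
    n_placement = dplyr::n_distinct(x$placement_reduction),
    n_duration = dplyr::n_distinct(x$duration_reduction),
    current_cost = b$point,
    current_se = b$se,
    current_ci_low = b$ci_low,
    current_ci_high = b$ci_high,
    level = b$level
  )
}

#' @export
tidy.cauti_grid <- function(x, ...) {
  tibble::as_tibble(x)
}

#' Savings as a fraction of current cost
#'
#' @inheritParams scenario_cost
#' @return Projected savings divided by current expected cost, in [0, 1].
#' @examples
#' savings_fraction(hospital_scenario(3000, 0.15), default_risk_params(),
#'                  default_cost_params(), intervention(0.29, 0.37))
#' @export
savings_fraction <- function(scenario, risks, costs, intervention) {
  current <- scenario_cost(scenario, risks, costs, no_intervention())
  if (current <= 0) {
    stop("current expected cost is zero; the savings fraction is undefined.",
         call. = FALSE)
  }
  savings(scenario, risks, costs, intervention) / current
}

#' Write a savings grid to CSV or JSON
#'
#' CSV uses the long format (one row per cell, columns `placement_reduction`,
#' `duration_reduction`, `savings`, `se`, `ci_low`, `ci_high`); JSON nests the
#' same cells under `cells` together with the baseline estimate and level.
#' Both round-trip losslessly through [read_grid()].
#'
#' @param result A `cauti_grid` from [savings_grid()].
#' @param path Output file path.
#' @param format `"csv"` or `"json"`; default guessed from the file
#'   extension.
#' @return `path`, invisibly.
#' @export
write_grid <- function(result, path, format = c("auto", "csv", "json")) {
  if (!inherits(result, "cauti_grid")) {
    stop("`result` must be a `cauti_grid` from `savings_grid()`.",
         call. = FALSE)
  }
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  b <- attr(result, "baseline")
  cells <- tibble::as_tibble(result)
  tryCatch({
    if (format == "csv") {
      utils::write.csv(cells, path, row.names = FALSE)
    } else {
      jsonlite::write_json(
        list(
          level = attr(result, "level"),
          baseline = glance(b),
          cells = cells
        ),
        path, digits = NA, auto_unbox = TRUE, dataframe = "columns"
      )
    }
  }, error = function(e) {
    stop("failed to write grid to '", path, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(path)
}

#' Read a savings grid written by [write_grid()]
#'
#' @param path File path (`.csv` or `.json`).
#' @return A tibble of grid cells (the baseline is restored from JSON files
#'   as the `"baseline_glance"` attribute; CSV stores cells only).
#' @export
read_grid <- function(path) {
  if (!file.exists(path)) stop("no such file: '", path, "'.", call. = FALSE)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    out <- tibble::as_tibble(obj$cells)
    attr(out, "baseline_glance") <- tibble::as_tibble(obj$baseline)
    attr(out, "level") <- obj$level
    out
  } else {
    tibble::as_tibble(utils::read.csv(path))
  }
}

#' Heatmap of projected savings across the intervention grid
#'
#' @param object A `cauti_grid` from [savings_grid()].
#' @param ... Unused.
#' @return A ggplot2 object: savings (fill and label) by placement reduction
#'   (x) and duration reduction (y).
#' @export
autoplot.cauti_grid <- function(object, ...) {
  ggplot2::ggplot(
    tibble::as_tibble(object),
    ggplot2::aes(
      x = factor(.data$placement_reduction),
      y = factor(.data$duration_reduction),
      fill = .data$savings
    )
  ) +
    ggplot2::geom_tile(color = "white") +
    ggplot2::geom_text(
      ggplot2::aes(label = scales_dollar(.data$savings)),
      size = 3
    ) +
    ggplot2::scale_fill_gradient(low = "#fff5eb", high = "#d94801",
                                 labels = scales_dollar) +
    ggplot2::labs(
      x = "Reduction in catheter placement",
      y = "Reduction in catheterization duration",
      fill = "Projected\nsavings (USD)",
      title = "Projected annual savings in CAUTI-attributable costs"
    ) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.cauti_grid
#' @param result A `cauti_grid`.
#' @export
plot_savings_grid <- function(result, ...) autoplot.cauti_grid(result, ...)

# minimal dollar formatter (avoids a scales dependency for one label)
scales_dollar <- function(x) paste0("$", format(round(x), big.mark = ","))
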
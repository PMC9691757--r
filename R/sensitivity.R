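#' Perturb one model parameter
#'
#' Returns a copy of the parameter set with a single field scaled by a
#' multiplier, for one-way sensitivity analysis. Two names are composite:
#'
#' * `"cdces_capacity"` scales annual session capacity (applied through the
#'   `weeks_per_year` factor, equivalent to scaling the product);
#' * `"coverage"` scales every element of `coverage_by_year`, clamped to 1.
#'
#' Scaling `routine_minutes` changes only the session-to-contact conversion
#' ratio, never the annual session capacity, which is expressed in sessions.
#'
#' @param params A [clinic_parameters()] object.
#' @param parameter Name of the field to scale (any numeric scalar field of
#'   `clinic_parameters`, or `"cdces_capacity"` / `"coverage"`).
#' @param multiplier Positive scale factor.
#' @return A validated `clinic_parameters` copy.
#' @examples
#' perturb(clinic_parameters(), "routine_rate", 1.5)$routine_rate  # 84
#' @export
perturb <- function(params, parameter, multiplier) {
  params <- validate_clinic_parameters(params)
  if (!is.numeric(multiplier) || length(multiplier) != 1L ||
      !is.finite(multiplier) || multiplier <= 0)
    stop("'multiplier' must be a single positive number", call. = FALSE)
  scalar_fields <- setdiff(names(unclass(params)), "coverage_by_year")
  if (identical(parameter, "cdces_capacity")) {
    params$weeks_per_year <- params$weeks_per_year * multiplier
  } else if (identical(parameter, "coverage")) {
    params$coverage_by_year <- pmin(1, params$coverage_by_year * multiplier)
  } else if (parameter %in% scalar_fields) {
    params[[parameter]] <- params[[parameter]] * multiplier
  } else {
    stop("unknown perturbable parameter: '", parameter, "'", call. = FALSE)
  }
  validate_clinic_parameters(params)
}

# Break-even (display cents) of a scenario on a parameter set; augmented uses
# year 1, the reporting convention.
scenario_break_even <- function(params, scenario) {
  if (scenario == "capacity-neutral")
    run_capacity_neutral(params)$break_even_rate_display
  else
    run_augmented_capacity(params)$years[[1]]$break_even_rate_display
}

#' One-way sensitivity analysis of the break-even rate
#'
#' Re-runs an adoption scenario with one parameter at a time scaled by each
#' multiplier and records the resulting minimum (break-even) telemedicine
#' reimbursement rate, rounded half-up to cents. Rows whose rate differs from
#' the baseline are flagged, exposing which parameters the break-even rate is
#' actually sensitive to: in the capacity-neutral scenario only the routine
#' reimbursement rate, the routine visit duration, and the HbA1c outcome
#' value move it; in the augmented scenario only CDCES salary, CDCES
#' capacity, visit durations, and the outcome value do.
#'
#' @param params A [clinic_parameters()] object (the baseline).
#' @param scenario `"capacity-neutral"` or `"augmented"`.
#' @param parameters Character vector of parameter names (see [perturb()]).
#' @param multipliers Positive multipliers applied to each parameter in turn
#'   (default 0.5 and 1.5, i.e. a 50% decrease and increase).
#' @return A `sensitivity_result` data frame with columns `scenario`,
#'   `parameter`, `multiplier`, `break_even_rate` (USD per contact, cents),
#'   and `changed_from_baseline`; the baseline rate is attached as attribute
#'   `baseline`.
#' @examples
#' one_way_sensitivity(clinic_parameters(), "capacity-neutral",
#'                     parameters = "routine_rate")
#' @export
one_way_sensitivity <- function(params, scenario = c("capacity-neutral",
                                                     "augmented"),
                                parameters, multipliers = c(0.5, 1.5)) {
  scenario <- match.arg(scenario)
  params <- validate_clinic_parameters(params)
  baseline <- scenario_break_even(params, scenario)
  grid <- expand.grid(multiplier = multipliers, parameter = parameters,
                      stringsAsFactors = FALSE)[, c("parameter", "multiplier")]
  rates <- mapply(function(p, m)
    scenario_break_even(perturb(params, p, m), scenario),
    grid$parameter, grid$multiplier)
  out <- data.frame(scenario = scenario,
                    parameter = grid$parameter,
                    multiplier = grid$multiplier,
                    break_even_rate = as.numeric(rates),
                    changed_from_baseline = as.numeric(rates) != baseline,
                    stringsAsFactors = FALSE)
  attr(out, "baseline") <- baseline
  class(out) <- c("sensitivity_result", class(out))
  out
}

#' Default sensitivity analysis over both scenarios
#'
#' Convenience wrapper running [one_way_sensitivity()] with the standard
#' parameter set for each scenario: routine rate and routine duration for the
#' capacity-neutral scenario; CDCES salary and capacity for the augmented
#' scenario; plus the parameters the break-even rate is expected to be
#' insensitive to, so the flags demonstrate the claim.
#'
#' @param params A [clinic_parameters()] object.
#' @param multipliers Positive multipliers (default 0.5 and 1.5).
#' @return A `sensitivity_result` data frame combining both scenarios.
#' @export
default_sensitivity <- function(params = clinic_parameters(),
                                multipliers = c(0.5, 1.5)) {
  cn <- one_way_sensitivity(params, "capacity-neutral",
                            c("routine_rate", "routine_minutes",
                              "n_patients", "cdces_salary", "cdces_capacity",
                              "repurposed_visits_per_patient"),
                            multipliers)
  aug <- one_way_sensitivity(params, "augmented",
                             c("cdces_salary", "cdces_capacity",
                               "n_patients", "routine_rate", "coverage"),
                             multipliers)
  out <- rbind(as.data.frame(cn), as.data.frame(aug))
  attr(out, "baseline") <- c(`capacity-neutral` = attr(cn, "baseline"),
                             augmented = attr(aug, "baseline"))
  class(out) <- c("sensitivity_result", class(out))
  out
}

#' @export
print.sensitivity_result <- function(x, ...) {
  cat("One-way sensitivity of the minimum telemedicine reimbursement rate\n")
  b <- attr(x, "baseline")
  if (!is.null(b))
    cat("  baseline:", paste(sprintf("%s $%.2f",
                                     names(b) %||% x$scenario[1], b),
                             collapse = ", "), "\n")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
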
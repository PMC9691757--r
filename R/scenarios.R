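#' Telemedicine contacts freed by repurposing routine appointments
#'
#' Each repurposed routine appointment frees capacity for
#' `floor(routine_minutes / tele_minutes)` message-based contacts ("up to"
#' that many: a partial contact cannot be delivered, hence the floor). A
#' 30-minute education slot converts to six 5-minute contacts.
#'
#' @param repurposed_appointments Routine appointments per year converted to
#'   telemedicine capacity.
#' @param routine_minutes,tele_minutes Appointment durations in minutes;
#'   `tele_minutes` must be positive.
#' @return Telemedicine contacts per year.
#' @examples
#' freed_contacts(100, 30, 5)  # 600
#' @export
freed_contacts <- function(repurposed_appointments, routine_minutes,
                           tele_minutes) {
  stopifnot(is_nonneg_number(repurposed_appointments),
            is_nonneg_number(routine_minutes))
  repurposed_appointments * contact_ratio(routine_minutes, tele_minutes)
}

# Whole telemedicine contacts per routine session slot.
contact_ratio <- function(routine_minutes, tele_minutes) {
  if (!is_nonneg_number(tele_minutes) || tele_minutes <= 0)
    stop("'tele_minutes' must be > 0", call. = FALSE)
  floor(routine_minutes / tele_minutes)
}

#' Revenue lost by repurposing routine appointments
#'
#' The education revenue forgone when routine visits are converted to
#' telemedicine capacity: repurposed appointments times the routine rate.
#'
#' @param repurposed_appointments Appointments per year repurposed.
#' @param routine_rate Reimbursement (USD) per routine visit.
#' @return USD per year.
#' @examples
#' revenue_gap(100, 56)  # 5600
#' @export
revenue_gap <- function(repurposed_appointments, routine_rate) {
  stopifnot(is_nonneg_number(repurposed_appointments),
            is_nonneg_number(routine_rate))
  repurposed_appointments * routine_rate
}

#' Offset a revenue gap by the value of improved outcomes
#'
#' Subtracts the clinic's valuation of a 0.5% HbA1c improvement (per patient
#' per year, scaled by the full population) from a revenue gap, floored at
#' zero: an outcome value exceeding the gap cannot make the break-even rate
#' negative.
#'
#' @param gap Revenue gap or additional labor cost (USD per year).
#' @param hba1c_value_per_patient USD per patient per year.
#' @param n_patients Patients in the practice.
#' @return Net gap in USD per year, never negative.
#' @examples
#' apply_outcome_offset(5600, 28, 100)  # 2800
#' @export
apply_outcome_offset <- function(gap, hba1c_value_per_patient, n_patients) {
  stopifnot(is_nonneg_number(gap), is_nonneg_number(hba1c_value_per_patient),
            is_nonneg_number(n_patients))
  max(0, gap - hba1c_value_per_patient * n_patients)
}

#' Break-even telemedicine reimbursement rate
#'
#' The minimum per-contact rate at which telemedicine revenue offsets the net
#' revenue gap (capacity-neutral scenario) or the additional labor cost
#' (augmented-capacity scenario): `net_gap / contacts`. Undefined without
#' contacts — zero contacts is an error, not a silent zero.
#'
#' @param net_gap USD per year to be recouped.
#' @param contacts Telemedicine contacts delivered per year; must be positive.
#' @return Unrounded USD per contact; round with `round_half_up(x, 2)` for
#'   display.
#' @examples
#' round_half_up(break_even_rate(5600, 600), 2)  # 9.33
#' @export
break_even_rate <- function(net_gap, contacts) {
  stopifnot(is_nonneg_number(net_gap))
  if (!is_nonneg_number(contacts) || contacts <= 0)
    stop("break-even rate is undefined with zero telemedicine contacts",
         call. = FALSE)
  net_gap / contacts
}

#' Brute-force break-even search on the cent grid
#'
#' Independent check of the closed-form break-even rate: scans per-contact
#' rates from zero upward in one-cent steps and returns the smallest rate at
#' which the scenario's net margin change versus the base case is
#' non-negative. The evaluator must be monotone nondecreasing in the rate.
#'
#' @param scenario_evaluator Function mapping a vector of per-contact rates
#'   (USD) to net margin change versus base case (USD per year).
#' @param step Grid resolution in USD (default one cent).
#' @param upper_bound Largest rate scanned.
#' @return Smallest rate on the grid with non-negative margin change.
#' @examples
#' ev <- function(rate) rate * 600 - 5600
#' break_even_rate_brute_force(ev, upper_bound = 56)  # 9.34
#' @export
break_even_rate_brute_force <- function(scenario_evaluator, step = 0.01,
                                        upper_bound = 100) {
  grid <- seq(0L, round(upper_bound / step)) * step
  margins <- scenario_evaluator(grid)
  if (length(margins) != length(grid))
    margins <- vapply(grid, scenario_evaluator, numeric(1))
  hit <- which(margins >= 0)
  if (length(hit) == 0L)
    stop("no break-even rate found below the upper bound", call. = FALSE)
  grid[hit[1L]]
}

#' Capacity-neutral adoption scenario
#'
#' The clinic repurposes `repurposed_visits_per_patient` routine education
#' visits per patient per year as flexible, algorithm-enabled telemedicine
#' capacity. Total clinic capacity and CDCES labor cost are unchanged; the
#' cost of adoption is the education revenue forgone. Computes the remaining
#' routine revenue, the revenue gap (optionally offset by the HbA1c outcome
#' value), the telemedicine contacts freed, the break-even per-contact rate,
#' potential RPM revenue at the billed rate, and the resulting margin change
#' versus the base case.
#'
#' With nothing repurposed the scenario degenerates to the base case: the gap
#' and margin are zero and the break-even rate is `NA` (undefined without
#' contacts).
#'
#' @param params A [clinic_parameters()] object.
#' @return A `capacity_neutral_result` list; `break_even_rate` is unrounded
#'   with a `break_even_rate_display` companion rounded to cents.
#' @examples
#' run_capacity_neutral(clinic_parameters())
#' @export
run_capacity_neutral <- function(params) {
  params <- validate_clinic_parameters(params)
  repurposed <- params$n_patients * params$repurposed_visits_per_patient
  remaining_visits <- params$routine_visits_per_year -
    params$repurposed_visits_per_patient
  remaining_revenue <- education_revenue(params$n_patients, remaining_visits,
                                         params$routine_rate)
  gap <- revenue_gap(repurposed, params$routine_rate)
  net_gap <- apply_outcome_offset(gap, params$hba1c_value_per_patient,
                                  params$n_patients)
  freed <- freed_contacts(repurposed, params$routine_minutes,
                          params$tele_minutes)
  be <- if (freed > 0) break_even_rate(net_gap, freed) else NA_real_
  rpm_revenue <- freed * params$rpm_rate
  structure(
    list(remaining_visits_per_patient = remaining_visits,
         remaining_revenue = remaining_revenue,
         revenue_gap = gap,
         outcome_offset = gap - net_gap,
         net_gap = net_gap,
         repurposed_appointments = repurposed,
         freed_contacts = freed,
         break_even_rate = be,
         break_even_rate_display = round_half_up(be, 2),
         rpm_revenue = rpm_revenue,
         margin = rpm_revenue - net_gap,
         params = params),
    class = "capacity_neutral_result")
}

#' @export
print.capacity_neutral_result <- function(x, ...) {
  cat("Capacity-neutral scenario\n")
  cat(sprintf("  %-46s %s\n", "In-person visits per patient per year",
              fmt_number(x$remaining_visits_per_patient)))
  cat(sprintf("  %-46s %s\n", "Marginal reimbursement revenue",
              fmt_currency(x$remaining_revenue)))
  cat(sprintf("  %-46s %s\n", "Revenue gap", fmt_currency(x$net_gap)))
  cat(sprintf("  %-46s %s\n", "Appointments repurposed for telehealth",
              fmt_number(x$repurposed_appointments)))
  cat(sprintf("  %-46s %s\n", "Total telemedicine appointments freed up",
              fmt_number(x$freed_contacts)))
  cat(sprintf("  %-46s %s\n", "Minimum reimbursement rate per contact",
              fmt_currency(x$break_even_rate, 2)))
  cat(sprintf("  %-46s %s\n", "Potential marginal RPM reimbursement revenue",
              fmt_currency(x$rpm_revenue)))
  cat(sprintf("  %-46s %s\n", "Margin", fmt_currency(x$margin)))
  invisible(x)
}

#' Annual telemedicine contact demand at a coverage fraction
#'
#' The clinic reviews data for `coverage` of its patients in each review
#' period; per-period demand is rounded to the nearest whole patient before
#' annualizing. 75% coverage of 100 patients monthly is 75 contacts per month,
#' 900 per year.
#'
#' @param n_patients Patients in the practice.
#' @param coverage Fraction of patients contacted per review period, in
#'   `[0, 1]`.
#' @param periods_per_year Review periods per year.
#' @return Contacts per year.
#' @examples
#' contacts_needed(100, 0.75, 12)  # 900
#' @export
contacts_needed <- function(n_patients, coverage, periods_per_year) {
  stopifnot(is_nonneg_number(n_patients), is_nonneg_number(periods_per_year))
  if (!is.numeric(coverage) || length(coverage) != 1L || is.na(coverage) ||
      coverage < 0 || coverage > 1)
    stop("'coverage' must be a fraction in [0, 1]", call. = FALSE)
  round_half_up(n_patients * coverage) * periods_per_year
}

#' Annual telemedicine-contact capacity of one full-time CDCES
#'
#' Converts education-session capacity to message-based contact capacity via
#' the whole-contact duration ratio: 1,300 thirty-minute sessions per year
#' support 7,800 five-minute contacts. Duration changes affect only this
#' conversion ratio, never the session capacity itself.
#'
#' @param annual_session_capacity Education sessions per year per FTE.
#' @param routine_minutes,tele_minutes Durations in minutes; `tele_minutes`
#'   must be positive.
#' @return Contacts per year per FTE.
#' @examples
#' telemedicine_capacity(1300, 30, 5)  # 7800
#' @export
telemedicine_capacity <- function(annual_session_capacity, routine_minutes,
                                  tele_minutes) {
  stopifnot(is_nonneg_number(annual_session_capacity),
            is_nonneg_number(routine_minutes))
  annual_session_capacity * contact_ratio(routine_minutes, tele_minutes)
}

#' Augmented-capacity adoption scenario
#'
#' The clinic keeps all routine appointments and hires additional CDCES
#' capacity to deliver algorithm-enabled telemedicine on top, in a multi-year
#' plan: year `y` covers `coverage_by_year[y]` of patients per review period.
#' For each year the model computes contact demand, per-FTE telemedicine
#' capacity, the additional (fractional) FTE and marginal labor cost, the
#' break-even per-contact rate that offsets the dollar-rounded labor cost
#' (net of any HbA1c outcome offset), potential RPM revenue, and the margin
#' change versus the base case.
#'
#' Margins are computed from the dollar-rounded labor cost, the figure a
#' clinic would budget; the unrounded cost is also returned.
#'
#' @param params A [clinic_parameters()] object with nonempty
#'   `coverage_by_year`.
#' @return An `augmented_capacity_result`: a list of per-year
#'   `augmented_year_result` lists.
#' @examples
#' run_augmented_capacity(clinic_parameters())
#' @export
run_augmented_capacity <- function(params) {
  params <- validate_clinic_parameters(params)
  capacity <- annual_session_capacity(params$sessions_per_day,
                                      params$days_per_week,
                                      params$weeks_per_year)
  tele_cap <- telemedicine_capacity(capacity, params$routine_minutes,
                                    params$tele_minutes)
  years <- lapply(seq_along(params$coverage_by_year), function(y) {
    f <- params$coverage_by_year[y]
    contacts <- contacts_needed(params$n_patients, f, params$periods_per_year)
    fte <- fte_required(contacts, tele_cap)
    labor <- labor_cost(fte, params$cdces_salary)
    labor_display <- round_half_up(labor)
    net_gap <- apply_outcome_offset(labor_display,
                                    params$hba1c_value_per_patient,
                                    params$n_patients)
    be <- if (contacts > 0) break_even_rate(net_gap, contacts) else NA_real_
    rpm_revenue <- contacts * params$rpm_rate
    structure(
      list(year_index = y,
           coverage = f,
           contacts_needed = contacts,
           telemedicine_capacity = tele_cap,
           additional_fte = fte,
           additional_fte_display = round_half_up(fte, 2),
           additional_labor_cost = labor,
           additional_labor_cost_display = labor_display,
           net_gap = net_gap,
           break_even_rate = be,
           break_even_rate_display = round_half_up(be, 2),
           rpm_revenue = rpm_revenue,
           margin = rpm_revenue - labor_display),
      class = "augmented_year_result")
  })
  structure(list(years = years, params = params),
            class = "augmented_capacity_result")
}

#' @export
print.augmented_capacity_result <- function(x, ...) {
  cat("Augmented-capacity scenario\n")
  for (yr in x$years) {
    cat(sprintf("  Year %d\n", yr$year_index))
    cat(sprintf("    %-44s %s%%\n", "Patients receiving telemedicine",
                fmt_number(100 * yr$coverage)))
    cat(sprintf("    %-44s %s\n", "Telemedicine appointments needed per year",
                fmt_number(yr$contacts_needed)))
    cat(sprintf("    %-44s %.2f\n", "Additional FTE needed",
                yr$additional_fte_display))
    cat(sprintf("    %-44s %s\n", "Additional marginal CDCES labor costs",
                fmt_currency(yr$additional_labor_cost_display)))
    cat(sprintf("    %-44s %s\n", "Minimum reimbursement rate per contact",
                fmt_currency(yr$break_even_rate, 2)))
    cat(sprintf("    %-44s %s\n", "Potential marginal RPM revenue",
                fmt_currency(yr$rpm_revenue)))
    cat(sprintf("    %-44s %s\n", "Margin", fmt_currency(yr$margin)))
  }
  invisible(x)
}

#' Side-by-side scenario comparison
#'
#' Assembles the key inputs and outputs of the base case, the
#' capacity-neutral scenario, and year 1 of the augmented-capacity scenario
#' into one table. Cells that do not apply to a scenario (e.g. repurposed
#' appointments or a break-even rate in the base case) are marked `"N/A"`.
#'
#' @param params A [clinic_parameters()] object.
#' @return A `scenario_comparison` data frame with columns `parameter`,
#'   `base_case`, `capacity_neutral`, `augmented_capacity` (character cells,
#'   raw numbers or `"N/A"`).
#' @examples
#' compare_scenarios(clinic_parameters())
#' @export
compare_scenarios <- function(params) {
  params <- validate_clinic_parameters(params)
  base <- build_base_case(params)
  cn <- run_capacity_neutral(params)
  aug <- run_augmented_capacity(params)$years[[1]]
  num <- function(x, digits = 0)
    ifelse(is.na(x), "N/A",
           formatC(round_half_up(x, digits), format = "f", digits = digits))
  df <- data.frame(
    parameter = c("Routine visits per patient per year",
                  "Reimbursement rate per routine visit",
                  "CDCES capacity (appointments per year)",
                  "Annual CDCES salary",
                  "Duration of in-person visit (mins)",
                  "Duration of telemedicine appointment (mins)",
                  "Routine appointments repurposed for telehealth",
                  "Lost revenue from routine appointments",
                  "Additional FTE needed",
                  "Additional marginal CDCES labor costs",
                  "Minimum reimbursement rate per telemedicine appointment"),
    base_case = c(num(params$routine_visits_per_year),
                  num(params$routine_rate),
                  num(base$annual_session_capacity),
                  num(params$cdces_salary),
                  num(params$routine_minutes),
                  num(params$tele_minutes),
                  "N/A", "N/A", "N/A", "N/A", "N/A"),
    capacity_neutral = c(num(cn$remaining_visits_per_patient),
                         num(params$routine_rate),
                         num(base$annual_session_capacity),
                         num(params$cdces_salary),
                         num(params$routine_minutes),
                         num(params$tele_minutes),
                         num(cn$repurposed_appointments),
                         num(cn$net_gap),
                         num(0, 2),
                         num(0),
                         num(cn$break_even_rate, 2)),
    augmented_capacity = c(num(params$routine_visits_per_year),
                           num(params$routine_rate),
                           num(base$annual_session_capacity),
                           num(params$cdces_salary),
                           num(params$routine_minutes),
                           num(params$tele_minutes),
                           num(0),
                           num(0),
                           num(aug$additional_fte, 2),
                           num(aug$additional_labor_cost_display),
                           num(aug$break_even_rate, 2)),
    stringsAsFactors = FALSE)
  class(df) <- c("scenario_comparison", class(df))
  df
}
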
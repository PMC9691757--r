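#' Annual education-session capacity of one full-time CDCES
#'
#' The product of sessions per day, working days per week, and weeks per
#' year. The reference clinic's 5 x 5 x 52 yields 1,300 sessions per year.
#'
#' @param sessions_per_day,days_per_week,weeks_per_year Non-negative capacity
#'   factors.
#' @return Sessions per year per FTE.
#' @examples
#' annual_session_capacity(5, 5, 52)  # 1300
#' @export
annual_session_capacity <- function(sessions_per_day, days_per_week,
                                    weeks_per_year) {
  stopifnot(is_nonneg_number(sessions_per_day),
            is_nonneg_number(days_per_week),
            is_nonneg_number(weeks_per_year))
  sessions_per_day * days_per_week * weeks_per_year
}

#' Annual marginal education revenue
#'
#' Fee-for-service reimbursement from routine diabetes-education visits:
#' patients x visits per year x rate per visit.
#'
#' @param n_patients Patients in the practice.
#' @param visits_per_year Routine visits per patient per year.
#' @param rate Reimbursement (USD) per visit.
#' @return USD per year.
#' @examples
#' education_revenue(100, 4, 56)  # 22400
#' @export
education_revenue <- function(n_patients, visits_per_year, rate) {
  stopifnot(is_nonneg_number(n_patients), is_nonneg_number(visits_per_year),
            is_nonneg_number(rate))
  n_patients * visits_per_year * rate
}

#' Full-time-equivalent CDCES staffing requirement
#'
#' Demand divided by per-FTE annual capacity, returned unrounded. FTE is a
#' continuous quantity in this model (no integer head-count constraint);
#' displayed values are rounded half-up to two decimals.
#'
#' @param appointments_needed Appointments demanded per year.
#' @param annual_capacity Appointments one FTE can deliver per year; must be
#'   positive.
#' @return Unrounded FTE fraction.
#' @examples
#' fte_required(400, 1300)                     # 0.3076923
#' round_half_up(fte_required(400, 1300), 2)   # 0.31
#' @export
fte_required <- function(appointments_needed, annual_capacity) {
  stopifnot(is_nonneg_number(appointments_needed))
  if (!is_nonneg_number(annual_capacity) || annual_capacity <= 0)
    stop("annual capacity must be > 0 to compute an FTE requirement",
         call. = FALSE)
  appointments_needed / annual_capacity
}

#' Annual CDCES labor cost
#'
#' Unrounded FTE times annual salary. The unrounded FTE must be used: the
#' two-decimal display FTE would misstate the cost (0.31 x 85,000 = 26,350,
#' whereas 400/1300 x 85,000 = 26,153.85, displayed as $26,154).
#'
#' @param fte_unrounded Unrounded FTE fraction.
#' @param salary Annual salary (USD) per FTE.
#' @return USD per year, unrounded; round with [round_half_up()] for display.
#' @examples
#' labor_cost(400 / 1300, 85000)  # 26153.85
#' @export
labor_cost <- function(fte_unrounded, salary) {
  stopifnot(is_nonneg_number(fte_unrounded), is_nonneg_number(salary))
  fte_unrounded * salary
}

#' Status-quo base case
#'
#' Computes the clinic's baseline economics under the traditional
#' fee-for-service model: marginal education revenue, appointment demand,
#' per-FTE capacity, the (fractional) CDCES FTE requirement, and the marginal
#' CDCES labor cost. Internal arithmetic is unrounded; `*_display` fields
#' carry the half-up rounded figures (FTE to two decimals, dollars to the
#' nearest dollar).
#'
#' @param params A [clinic_parameters()] object.
#' @return A `base_case_result` list with fields `marginal_revenue`,
#'   `appointments_needed`, `annual_session_capacity`, `fte_needed`,
#'   `fte_needed_display`, `labor_cost`, `labor_cost_display`.
#' @examples
#' build_base_case(clinic_parameters())
#' @export
build_base_case <- function(params) {
  params <- validate_clinic_parameters(params)
  capacity <- annual_session_capacity(params$sessions_per_day,
                                      params$days_per_week,
                                      params$weeks_per_year)
  appointments <- params$n_patients * params$routine_visits_per_year
  fte <- fte_required(appointments, capacity)
  cost <- labor_cost(fte, params$cdces_salary)
  structure(
    list(marginal_revenue = education_revenue(params$n_patients,
                                              params$routine_visits_per_year,
                                              params$routine_rate),
         appointments_needed = appointments,
         annual_session_capacity = capacity,
         fte_needed = fte,
         fte_needed_display = round_half_up(fte, 2),
         labor_cost = cost,
         labor_cost_display = round_half_up(cost),
         params = params),
    class = "base_case_result")
}

#' @export
print.base_case_result <- function(x, ...) {
  cat("Base case (status quo, fee-for-service)\n")
  cat(sprintf("  %-38s %s\n", "Marginal reimbursement revenue",
              fmt_currency(x$marginal_revenue)))
  cat(sprintf("  %-38s %s\n", "Total appointments needed (per year)",
              fmt_number(x$appointments_needed)))
  cat(sprintf("  %-38s %s\n", "CDCES capacity (appointments per year)",
              fmt_number(x$annual_session_capacity)))
  cat(sprintf("  %-38s %.2f\n", "FTE needed", x$fte_needed_display))
  cat(sprintf("  %-38s %s\n", "Total CDCES labor costs",
              fmt_currency(x$labor_cost_display)))
  invisible(x)
}
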
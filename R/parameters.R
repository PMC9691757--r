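#' Clinic model parameters
#'
#' Constructs the full set of scalar inputs to the financial model of a
#' pediatric type 1 diabetes clinic delivering CDCES-led diabetes education,
#' with optional algorithm-enabled telemedicine contacts. Defaults describe a
#' 100-patient clinic billing routine education at the average Medicare rate,
#' with CDCES capacity of 1,300 thirty-minute sessions per year and five-minute
#' message-based telemedicine contacts billable under RPM codes at $35.
#'
#' Every parameter is modifiable; the defaults are the model's reference
#' clinic. All currency is plain (undiscounted) USD per year.
#'
#' @param n_patients Number of patients in the practice.
#' @param routine_visits_per_year Routine diabetes-education visits per patient
#'   per year under the status quo.
#' @param routine_rate Reimbursement (USD) per routine education visit.
#' @param cdces_salary Annual salary (USD) of one full-time CDCES.
#' @param sessions_per_day,days_per_week,weeks_per_year Capacity factors: a
#'   full-time CDCES delivers `sessions_per_day * days_per_week *
#'   weeks_per_year` education sessions per year (default 5 x 5 x 52 = 1,300).
#' @param routine_minutes Duration (minutes) of a routine education visit.
#' @param tele_minutes Duration (minutes) of one message-based telemedicine
#'   contact; must be positive and no longer than `routine_minutes`.
#' @param rpm_rate Reimbursement (USD) per telemedicine contact under remote
#'   patient monitoring CPT codes.
#' @param repurposed_visits_per_patient Routine visits per patient per year
#'   converted to telemedicine capacity in the capacity-neutral scenario.
#' @param coverage_by_year Fractions in `[0, 1]`: the share of the patient
#'   population receiving a telemedicine contact in each review period, one
#'   element per program year of the augmented-capacity scenario.
#' @param periods_per_year Review periods per year in the financial model
#'   (monthly by default).
#' @param hba1c_value_per_patient Value (USD per patient per year) the clinic
#'   attributes to a 0.5% HbA1c improvement; subtracted from the revenue gap
#'   before solving for the break-even rate. Default 0 (no offset).
#' @return An object of class `clinic_parameters` (a validated named list).
#' @seealso [build_base_case()], [run_capacity_neutral()],
#'   [run_augmented_capacity()], [perturb()]
#' @examples
#' params <- clinic_parameters()
#' build_base_case(params)
#' @export
clinic_parameters <- function(n_patients = 100,
                              routine_visits_per_year = 4,
                              routine_rate = 56,
                              cdces_salary = 85000,
                              sessions_per_day = 5,
                              days_per_week = 5,
                              weeks_per_year = 52,
                              routine_minutes = 30,
                              tele_minutes = 5,
                              rpm_rate = 35,
                              repurposed_visits_per_patient = 1,
                              coverage_by_year = c(0.75, 0.50),
                              periods_per_year = 12,
                              hba1c_value_per_patient = 0) {
  params <- structure(
    list(n_patients = n_patients,
         routine_visits_per_year = routine_visits_per_year,
         routine_rate = routine_rate,
         cdces_salary = cdces_salary,
         sessions_per_day = sessions_per_day,
         days_per_week = days_per_week,
         weeks_per_year = weeks_per_year,
         routine_minutes = routine_minutes,
         tele_minutes = tele_minutes,
         rpm_rate = rpm_rate,
         repurposed_visits_per_patient = repurposed_visits_per_patient,
         coverage_by_year = coverage_by_year,
         periods_per_year = periods_per_year,
         hba1c_value_per_patient = hba1c_value_per_patient),
    class = "clinic_parameters")
  validate_clinic_parameters(params)
}

#' Validate clinic parameters
#'
#' Checks the model invariants: all counts and currency amounts non-negative,
#' `tele_minutes > 0`, `routine_minutes >= tele_minutes`,
#' `repurposed_visits_per_patient <= routine_visits_per_year`, every coverage
#' fraction in `[0, 1]`, and at least one review period per year.
#'
#' @param params A `clinic_parameters` object (or plain named list).
#' @return The validated object, invisibly classed `clinic_parameters`.
#' @export
validate_clinic_parameters <- function(params) {
  scalars <- setdiff(names(params), "coverage_by_year")
  for (nm in scalars) {
    if (!is_nonneg_number(params[[nm]]))
      stop("parameter '", nm, "' must be a single non-negative finite number",
           call. = FALSE)
  }
  if (params$tele_minutes <= 0)
    stop("parameter 'tele_minutes' must be > 0", call. = FALSE)
  if (params$routine_minutes < params$tele_minutes)
    stop("parameter 'routine_minutes' must be >= 'tele_minutes'",
         call. = FALSE)
  if (params$repurposed_visits_per_patient > params$routine_visits_per_year)
    stop("parameter 'repurposed_visits_per_patient' must be <= ",
         "'routine_visits_per_year'", call. = FALSE)
  cov <- params$coverage_by_year
  if (length(cov) < 1L || !is.numeric(cov) || anyNA(cov) ||
      any(cov < 0) || any(cov > 1))
    stop("parameter 'coverage_by_year' must be a nonempty vector of ",
         "fractions in [0, 1]", call. = FALSE)
  if (params$periods_per_year < 1)
    stop("parameter 'periods_per_year' must be >= 1", call. = FALSE)
  class(params) <- "clinic_parameters"
  params
}

#' @export
print.clinic_parameters <- function(x, ...) {
  cat("Clinic model parameters\n")
  cat(sprintf("  %-30s %s\n", "patients", fmt_number(x$n_patients)))
  cat(sprintf("  %-30s %s/yr at %s\n", "routine visits",
              fmt_number(x$routine_visits_per_year),
              fmt_currency(x$routine_rate)))
  cat(sprintf("  %-30s %s/yr (%d x %d x %d sessions)\n", "CDCES capacity",
              fmt_number(annual_session_capacity(x$sessions_per_day,
                                                 x$days_per_week,
                                                 x$weeks_per_year)),
              x$sessions_per_day, x$days_per_week, x$weeks_per_year))
  cat(sprintf("  %-30s %s\n", "CDCES salary", fmt_currency(x$cdces_salary)))
  cat(sprintf("  %-30s %g min routine / %g min telemedicine\n", "durations",
              x$routine_minutes, x$tele_minutes))
  cat(sprintf("  %-30s %s per contact\n", "RPM rate",
              fmt_currency(x$rpm_rate, 2)))
  cat(sprintf("  %-30s %s visit(s)/patient/yr\n", "repurposed",
              fmt_number(x$repurposed_visits_per_patient)))
  cat(sprintf("  %-30s %s over %d periods/yr\n", "coverage by year",
              paste(x$coverage_by_year, collapse = ", "),
              x$periods_per_year))
  if (x$hba1c_value_per_patient > 0)
    cat(sprintf("  %-30s %s/patient/yr\n", "HbA1c outcome value",
                fmt_currency(x$hba1c_value_per_patient, 2)))
  invisible(x)
}
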
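#' Tabulate a model result
#'
#' Converts a result object into a three-column data frame (`label`, `value`,
#' `unit`) whose row labels match the model's standard report tables, ready
#' for CSV export (raw numbers) or Markdown rendering (formatted currency).
#'
#' @param x A `base_case_result`, `capacity_neutral_result`,
#'   `augmented_capacity_result`, or `utilization_summary`.
#' @param ... Unused.
#' @return A data frame with columns `label`, `value`, `unit`.
#' @export
result_table <- function(x, ...) UseMethod("result_table")

#' @export
result_table.base_case_result <- function(x, ...) {
  p <- x$params
  data.frame(
    label = c("Number of patients in practice",
              "Routine visits per patient per year",
              "Reimbursement rate per routine visit",
              "Marginal Reimbursement Revenue",
              "Annual CDCES salary",
              "CDCES capacity (appointments per year)",
              "Total appointments needed (per year)",
              "FTE needed",
              "Total CDCES labor costs"),
    value = c(p$n_patients, p$routine_visits_per_year, p$routine_rate,
              x$marginal_revenue, p$cdces_salary, x$annual_session_capacity,
              x$appointments_needed, x$fte_needed_display,
              x$labor_cost_display),
    unit = c("count", "count", "usd", "usd", "usd", "count", "count",
             "fte", "usd"),
    stringsAsFactors = FALSE)
}

#' @export
result_table.capacity_neutral_result <- function(x, ...) {
  p <- x$params
  data.frame(
    label = c("In person visits per patient per year",
              "Marginal Reimbursement Revenue",
              "Revenue Gap",
              "Appointments repurposed for telehealth",
              "Duration of in-person visit (mins)",
              "Duration of telemedicine appointment (mins)",
              "Total telemedicine appointments freed up",
              "Minimum reimbursement rate per telemedicine appointment",
              "RPM reimbursement rate",
              "Potential marginal RPM reimbursement revenue",
              "Margin"),
    value = c(x$remaining_visits_per_patient, x$remaining_revenue, x$net_gap,
              x$repurposed_appointments, p$routine_minutes, p$tele_minutes,
              x$freed_contacts, x$break_even_rate_display, p$rpm_rate,
              x$rpm_revenue, x$margin),
    unit = c("count", "usd", "usd", "count", "minutes", "minutes", "count",
             "usd_rate", "usd_rate", "usd", "usd"),
    stringsAsFactors = FALSE)
}

#' @export
result_table.augmented_capacity_result <- function(x, ...) {
  p <- x$params
  do.call(rbind, lapply(x$years, function(yr) {
    pre <- sprintf("Year %d: ", yr$year_index)
    data.frame(
      label = paste0(pre, c(
        "Percentage of patients receiving telemedicine",
        "Telemedicine appointments needed per year",
        "CDCES capacity (appointments per year)",
        "Additional FTE needed",
        "Additional marginal CDCES labor costs",
        "Minimum reimbursement rate per telemedicine appointment",
        "RPM reimbursement rate",
        "Potential marginal RPM reimbursement revenue",
        "Margin")),
      value = c(100 * yr$coverage, yr$contacts_needed,
                annual_session_capacity(p$sessions_per_day, p$days_per_week,
                                        p$weeks_per_year),
                yr$additional_fte_display, yr$additional_labor_cost_display,
                yr$break_even_rate_display, p$rpm_rate, yr$rpm_revenue,
                yr$margin),
      unit = c("percent", "count", "count", "fte", "usd", "usd_rate",
               "usd_rate", "usd", "usd"),
      stringsAsFactors = FALSE)
  }))
}

#' @export
result_table.utilization_summary <- function(x, ...) {
  data.frame(
    label = c("Mean demand per period", "Capacity per period",
              "Mean utilization", "Saturated period fraction",
              "Realized contacts", "Unmet contacts",
              "Realized RPM revenue"),
    value = c(x$mean_demand_per_period, x$capacity_per_period,
              x$mean_utilization, x$saturated_period_fraction,
              x$realized_contacts, x$unmet_contacts,
              x$realized_rpm_revenue),
    unit = c("count", "count", "fraction", "fraction", "count", "count",
             "usd"),
    stringsAsFactors = FALSE)
}

# Format one value for Markdown according to its unit tag.
fmt_md_value <- function(value, unit) {
  switch(unit,
         usd = fmt_currency(value),
         usd_rate = fmt_currency(value, 2),
         fte = fmt_number(value, 2),
         percent = paste0(fmt_number(value), "%"),
         fraction = fmt_number(value, 3),
         minutes = fmt_number(value),
         count = fmt_number(value),
         as.character(value))
}

#' Write a data frame as a Markdown pipe table
#'
#' `label`/`value`/`unit` tables are rendered with the unit-appropriate
#' currency and thousands formatting (and the `unit` column dropped); other
#' data frames are written as-is.
#'
#' @param df A data frame.
#' @param path Output file path.
#' @param title Optional heading written above the table.
#' @return The path, invisibly.
#' @export
write_markdown_table <- function(df, path, title = NULL) {
  if (all(c("label", "value", "unit") %in% names(df))) {
    df <- data.frame(
      Parameter = df$label,
      Value = mapply(fmt_md_value, df$value, df$unit),
      stringsAsFactors = FALSE)
  }
  cells <- rbind(names(df), vapply(df, as.character, character(nrow(df))))
  widths <- apply(nchar(cells, type = "width"), 2, max)
  pad <- function(row) paste0(
    "| ",
    paste(mapply(formatC, row, width = widths, MoreArgs = list(flag = "-")),
          collapse = " | "),
    " |")
  lines <- c(pad(cells[1, ]),
             pad(vapply(widths, function(w) strrep("-", w), character(1))),
             apply(cells[-1, , drop = FALSE], 1, pad))
  if (!is.null(title)) lines <- c(paste("##", title), "", lines)
  writeLines(lines, path)
  invisible(path)
}

#' Render model results to CSV and Markdown files
#'
#' Writes each named result to `<dir>/<name>.csv` (raw numbers) and/or
#' `<dir>/<name>.md` (formatted report tables). Result objects with a
#' [result_table()] method are tabulated first; data frames (scenario
#' comparisons, sensitivity tables, figure data) are written directly.
#'
#' @param results Named list of result objects and/or data frames.
#' @param dir Output directory (created if missing).
#' @param formats Subset of `c("csv", "md")`.
#' @return Character vector of files written, invisibly. An empty `results`
#'   list writes nothing and warns.
#' @export
render_tables <- function(results, dir = ".", formats = c("csv", "md")) {
  formats <- match.arg(formats, c("csv", "md"), several.ok = TRUE)
  if (length(results) == 0L) {
    warning("no results supplied; nothing written", call. = FALSE)
    return(invisible(character(0)))
  }
  if (is.null(names(results)) || any(!nzchar(names(results))))
    stop("'results' must be a named list", call. = FALSE)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  written <- character(0)
  for (nm in names(results)) {
    obj <- results[[nm]]
    df <- if (is.data.frame(obj)) obj else result_table(obj)
    if ("csv" %in% formats) {
      f <- file.path(dir, paste0(nm, ".csv"))
      utils::write.csv(df, f, row.names = FALSE)
      written <- c(written, f)
    }
    if ("md" %in% formats) {
      f <- file.path(dir, paste0(nm, ".md"))
      write_markdown_table(df, f, title = gsub("_", " ", nm))
      written <- c(written, f)
    }
  }
  invisible(written)
}

#' Long-format revenue data for stacked-bar figures
#'
#' Per-scenario revenue components for plotting: remaining routine education
#' revenue, telemedicine revenue if contacts were reimbursed exactly at the
#' break-even rate, and telemedicine revenue at the billed RPM rate.
#'
#' @param params A [clinic_parameters()] object.
#' @return A data frame with columns `scenario`, `category`, `revenue`.
#' @export
figure_revenue_data <- function(params) {
  params <- validate_clinic_parameters(params)
  base <- build_base_case(params)
  cn <- run_capacity_neutral(params)
  aug <- run_augmented_capacity(params)
  cats <- c("remaining routine revenue",
            "telemedicine revenue at break-even",
            "telemedicine revenue at RPM rate")
  rows <- list(
    data.frame(scenario = "base-case", category = cats,
               revenue = c(base$marginal_revenue, 0, 0),
               stringsAsFactors = FALSE),
    data.frame(scenario = "capacity-neutral", category = cats,
               revenue = c(cn$remaining_revenue, cn$net_gap, cn$rpm_revenue),
               stringsAsFactors = FALSE))
  for (yr in aug$years)
    rows[[length(rows) + 1L]] <- data.frame(
      scenario = sprintf("augmented-year-%d", yr$year_index),
      category = cats,
      revenue = c(base$marginal_revenue, yr$net_gap, yr$rpm_revenue),
      stringsAsFactors = FALSE)
  do.call(rbind, rows)
}

#' Tabulate a sensitivity analysis in the standard report layout
#'
#' Rewrites a [one_way_sensitivity()] result with human-readable row labels
#' ("50% increase in ...") and the break-even rate per row, the layout of the
#' model's sensitivity report table.
#'
#' @param x A `sensitivity_result`.
#' @return A `label`/`value`/`unit` data frame.
#' @export
sensitivity_table <- function(x) {
  stopifnot(inherits(x, "sensitivity_result"))
  pretty <- c(routine_rate = "routine appointment reimbursement rate",
              routine_minutes = "average time per routine appointment",
              cdces_salary = "salary of CDCES",
              cdces_capacity = "capacity of CDCES",
              n_patients = "number of patients in practice",
              routine_visits_per_year = "routine appointments per year",
              repurposed_visits_per_patient =
                "routine appointments shifted to telemedicine",
              coverage = "telemedicine coverage fraction",
              hba1c_value_per_patient =
                "value of a 0.5% improvement in HbA1c",
              tele_minutes = "duration of telemedicine contact",
              rpm_rate = "RPM reimbursement rate")
  nm <- ifelse(x$parameter %in% names(pretty), pretty[x$parameter],
               x$parameter)
  dir <- ifelse(x$multiplier >= 1, "increase", "decrease")
  pct <- fmt_number(100 * abs(x$multiplier - 1))
  data.frame(
    label = paste0("[", x$scenario, "] ", pct, "% ", dir, " in ", nm),
    value = x$break_even_rate,
    unit = "usd_rate",
    stringsAsFactors = FALSE)
}
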
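#' Simulate per-period patient flags (Bernoulli model)
#'
#' Generates a patient-by-period binary matrix in which each entry is an
#' independent Bernoulli draw: patient `i` is flagged for a telemedicine
#' contact in period `j` with probability `flag_prob`. This is the abstracted
#' demand process behind the financial model's coverage fractions (e.g. 50%
#' of patients meeting intervention criteria in any review period).
#'
#' @param n_patients Number of patients.
#' @param periods Number of review periods simulated.
#' @param flag_prob Per-patient, per-period flag probability in `[0, 1]`.
#' @param seed Integer seed; identical inputs and seed reproduce the matrix
#'   exactly, and the caller's RNG state is left untouched.
#' @return A `demand_stream` with fields `flags` (0/1 matrix, patients in
#'   rows), `n_patients`, `periods`, `model = "bernoulli"`, `model_params`,
#'   `seed`.
#' @examples
#' s <- simulate_flags_bernoulli(100, 12, 0.5, seed = 1)
#' colSums(s$flags)  # flagged patients per period
#' @export
simulate_flags_bernoulli <- function(n_patients, periods, flag_prob, seed) {
  stopifnot(is_nonneg_number(n_patients), is_nonneg_number(periods))
  if (!is.numeric(flag_prob) || length(flag_prob) != 1L || is.na(flag_prob) ||
      flag_prob < 0 || flag_prob > 1)
    stop("'flag_prob' must be a probability in [0, 1]", call. = FALSE)
  flags <- with_local_seed(seed,
    matrix(stats::rbinom(n_patients * periods, 1L, flag_prob),
           nrow = n_patients, ncol = periods))
  new_demand_stream(flags, model = "bernoulli",
                    model_params = list(flag_prob = flag_prob), seed = seed)
}

#' Simulate per-period patient flags from CGM summary metrics
#'
#' Draws, for each patient and review period, a time-in-range (TIR) fraction
#' and a CGM wear-time fraction, and flags the patient when `TIR <
#' tir_threshold` OR `wear < wear_threshold` — the triage rule used by
#' algorithm-enabled CGM review (default thresholds: TIR below 65%, wear
#' below 50%). Each metric is either Beta-distributed (`list(shape1=,
#' shape2=)`) or degenerate at a constant (`list(value=)`). The default Beta
#' parameters — TIR ~ Beta(6.2, 3.5) (mean 0.64), wear ~ Beta(9, 1) (mean
#' 0.90) — give a marginal flag probability of about 0.50.
#'
#' @param n_patients Number of patients.
#' @param periods Number of review periods.
#' @param tir,wear Distribution of the per-period TIR and wear fractions:
#'   `list(shape1, shape2)` for a Beta draw or `list(value)` for a constant
#'   in `[0, 1]`.
#' @param seed Integer seed (reproducible; caller's RNG untouched).
#' @param tir_threshold,wear_threshold Flagging thresholds on `[0, 1]`.
#' @return A `demand_stream` with `model = "cgm-metric"` carrying the `flags`
#'   matrix plus the underlying `tir` and `wear` matrices.
#' @examples
#' s <- simulate_flags_cgm(100, 12, tir = list(value = 0.6), seed = 1)
#' all(s$flags == 1)  # TIR below threshold flags everyone
#' @export
simulate_flags_cgm <- function(n_patients, periods,
                               tir = list(shape1 = 6.2, shape2 = 3.5),
                               wear = list(shape1 = 9, shape2 = 1),
                               seed,
                               tir_threshold = 0.65, wear_threshold = 0.50) {
  stopifnot(is_nonneg_number(n_patients), is_nonneg_number(periods))
  n <- n_patients * periods
  draws <- with_local_seed(seed, list(tir = draw_fraction(tir, n, "tir"),
                                      wear = draw_fraction(wear, n, "wear")))
  tir_m <- matrix(draws$tir, nrow = n_patients, ncol = periods)
  wear_m <- matrix(draws$wear, nrow = n_patients, ncol = periods)
  flags <- (tir_m < tir_threshold | wear_m < wear_threshold) + 0L
  new_demand_stream(flags, model = "cgm-metric",
                    model_params = list(tir = tir, wear = wear,
                                        tir_threshold = tir_threshold,
                                        wear_threshold = wear_threshold),
                    seed = seed, tir = tir_m, wear = wear_m)
}

# Draw n fractions from a Beta(shape1, shape2) or a degenerate point mass.
draw_fraction <- function(spec, n, what) {
  if (!is.list(spec))
    stop("'", what, "' must be a list(shape1=, shape2=) or list(value=)",
         call. = FALSE)
  if (!is.null(spec$value)) {
    if (!is.numeric(spec$value) || spec$value < 0 || spec$value > 1)
      stop("degenerate '", what, "' value must lie in [0, 1]", call. = FALSE)
    return(rep(spec$value, n))
  }
  if (is.null(spec$shape1) || is.null(spec$shape2) ||
      spec$shape1 <= 0 || spec$shape2 <= 0)
    stop("'", what, "' Beta shapes must be positive", call. = FALSE)
  stats::rbeta(n, spec$shape1, spec$shape2)
}

new_demand_stream <- function(flags, model, model_params, seed,
                              tir = NULL, wear = NULL) {
  structure(list(flags = flags,
                 n_patients = nrow(flags),
                 periods = ncol(flags),
                 model = model,
                 model_params = model_params,
                 seed = seed,
                 tir = tir,
                 wear = wear),
            class = "demand_stream")
}

#' @export
print.demand_stream <- function(x, ...) {
  cat(sprintf("Synthetic demand stream (%s model): %d patients x %d periods\n",
              x$model, x$n_patients, x$periods))
  cat(sprintf("  total flags %d (rate %.3f), seed %s\n", sum(x$flags),
              mean(x$flags), format(x$seed)))
  invisible(x)
}

#' Capacity utilization of a simulated demand stream
#'
#' Serves flagged demand against a fixed per-period telemedicine capacity:
#' in each period `min(demand, capacity)` contacts are delivered and the rest
#' go unmet. Quantifies how much of the model's flexible capacity is actually
#' booked — a stress test of the assumption that the capacity can be fully
#' booked in every review period.
#'
#' @param stream A [simulate_flags_bernoulli()] / [simulate_flags_cgm()]
#'   result.
#' @param capacity_per_period Contacts deliverable per review period.
#' @param rpm_rate Reimbursement (USD) per delivered contact.
#' @return A `utilization_summary` with `mean_demand_per_period`,
#'   `mean_utilization` (fraction of capacity used, 0 if capacity is zero),
#'   `unmet_contacts`, `saturated_period_fraction` (periods where demand >=
#'   capacity), `realized_contacts` and `realized_rpm_revenue` per simulated
#'   horizon.
#' @examples
#' s <- simulate_flags_bernoulli(100, 12, 0.5, seed = 1)
#' utilization_summary(s, capacity_per_period = 50, rpm_rate = 35)
#' @export
utilization_summary <- function(stream, capacity_per_period, rpm_rate) {
  stopifnot(inherits(stream, "demand_stream"),
            is_nonneg_number(capacity_per_period), is_nonneg_number(rpm_rate))
  demand <- colSums(stream$flags)
  served <- pmin(demand, capacity_per_period)
  realized <- sum(served)
  structure(
    list(mean_demand_per_period = mean(demand),
         mean_utilization = if (capacity_per_period > 0)
           realized / (capacity_per_period * stream$periods) else 0,
         unmet_contacts = sum(demand) - realized,
         saturated_period_fraction = mean(demand >= capacity_per_period),
         realized_contacts = realized,
         realized_rpm_revenue = realized * rpm_rate,
         capacity_per_period = capacity_per_period,
         periods = stream$periods),
    class = "utilization_summary")
}

#' @export
print.utilization_summary <- function(x, ...) {
  cat("Capacity utilization summary\n")
  cat(sprintf("  %-28s %.2f (capacity %s/period)\n", "mean demand per period",
              x$mean_demand_per_period, fmt_number(x$capacity_per_period)))
  cat(sprintf("  %-28s %.1f%%\n", "mean utilization",
              100 * x$mean_utilization))
  cat(sprintf("  %-28s %.1f%%\n", "saturated periods",
              100 * x$saturated_period_fraction))
  cat(sprintf("  %-28s %s (unmet %s)\n", "realized contacts",
              fmt_number(x$realized_contacts), fmt_number(x$unmet_contacts)))
  cat(sprintf("  %-28s %s\n", "realized RPM revenue",
              fmt_currency(x$realized_rpm_revenue)))
  invisible(x)
}

#' Export a demand stream as a long-format data frame
#'
#' One row per patient-period with the flag and, for the CGM-metric model,
#' the simulated TIR and wear fractions.
#'
#' @param x A `demand_stream`.
#' @param ... Unused.
#' @return A data frame with columns `patient`, `period`, `flag`, and (when
#'   available) `tir`, `wear`.
#' @export
as.data.frame.demand_stream <- function(x, ...) {
  df <- data.frame(patient = rep(seq_len(x$n_patients), times = x$periods),
                   period = rep(seq_len(x$periods), each = x$n_patients),
                   flag = as.integer(x$flags))
  if (!is.null(x$tir)) df$tir <- as.numeric(x$tir)
  if (!is.null(x$wear)) df$wear <- as.numeric(x$wear)
  df
}

#' Write the run manifest of a demand simulation
#'
#' Records the model, its parameters, the seed, and the package version in a
#' plain-text file alongside exported simulation data, so a simulated stream
#' can be regenerated exactly.
#'
#' @param stream A `demand_stream`.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_run_manifest <- function(stream, path) {
  lines <- c(
    paste("generated:", format(Sys.time(), "%Y-%m-%d %H:%M:%S %Z")),
    paste("package: rpmecon",
          as.character(utils::packageVersion("rpmecon"))),
    paste("model:", stream$model),
    paste("n_patients:", stream$n_patients),
    paste("periods:", stream$periods),
    paste("seed:", format(stream$seed)),
    paste("model_params:",
          paste(deparse(stream$model_params), collapse = " ")))
  writeLines(lines, path)
  invisible(path)
}
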
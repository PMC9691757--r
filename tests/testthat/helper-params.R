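# Reference clinic (the model defaults) used throughout the suite.
ref_params <- function(...) clinic_parameters(...)

# Randomized valid parameter set for property-style tests. Draws are wide
# enough to exercise the model but always satisfy the invariants.
random_params <- function() {
  v <- sample(1:8, 1)
  dt <- stats::runif(1, 2, 10)
  clinic_parameters(
    n_patients = sample(10:500, 1),
    routine_visits_per_year = v,
    routine_rate = stats::runif(1, 20, 100),
    cdces_salary = stats::runif(1, 40000, 150000),
    sessions_per_day = sample(3:8, 1),
    days_per_week = sample(3:6, 1),
    weeks_per_year = sample(40:52, 1),
    routine_minutes = stats::runif(1, 2, 6) * dt,
    tele_minutes = dt,
    rpm_rate = stats::runif(1, 10, 60),
    repurposed_visits_per_patient = sample(seq_len(v), 1),
    coverage_by_year = stats::runif(sample(1:3, 1), 0, 1),
    periods_per_year = sample(c(12, 52), 1),
    hba1c_value_per_patient = 0)
}

# Vectorized margin-change evaluators (rate -> net margin vs base case),
# used with the brute-force break-even search.
cn_evaluator <- function(params) {
  res <- run_capacity_neutral(params)
  function(rate) rate * res$freed_contacts - res$net_gap
}
aug_evaluator <- function(params, year = 1) {
  yr <- run_augmented_capacity(params)$years[[year]]
  function(rate) rate * yr$contacts_needed - yr$net_gap
}
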
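# Enumeration oracle: how many whole tele contacts fit into one routine slot.
enumerate_contacts_per_slot <- function(routine_minutes, tele_minutes) {
  k <- 0L; t <- tele_minutes
  while (t <= routine_minutes) { k <- k + 1L; t <- t + tele_minutes }
  k
}

test_that("freed contacts floor the duration ratio per repurposed slot", {
  expect_equal(freed_contacts(100, 30, 5), 600)
  expect_equal(freed_contacts(100, 30, 30), 100)
  expect_equal(freed_contacts(100, 30, 7),
               100 * enumerate_contacts_per_slot(30, 7))
  expect_equal(freed_contacts(100, 30, 7), 400)
  expect_error(freed_contacts(100, 30, 0), "tele_minutes")
})

test_that("revenue gap is repurposed appointments times the routine rate", {
  expect_equal(revenue_gap(100, 56), 5600)
  expect_equal(revenue_gap(0, 56), 0)
  expect_equal(revenue_gap(150, 84), 12600)
  expect_equal(revenue_gap(150, 84),
               education_revenue(150, 4, 84) - education_revenue(150, 3, 84))
})

test_that("outcome offset reduces the gap, floored at zero", {
  expect_equal(apply_outcome_offset(5600, 0, 100), 5600)
  expect_equal(apply_outcome_offset(5600, 56, 100), 0)
  expect_equal(apply_outcome_offset(5600, 28, 100), 2800)
  expect_equal(apply_outcome_offset(5600, 100, 100), 0)
})

test_that("halving the net gap via the outcome offset halves the break-even", {
  p <- ref_params(hba1c_value_per_patient = 28)
  res <- run_capacity_neutral(p)
  expect_equal(res$net_gap, 2800)
  bf <- break_even_rate_brute_force(cn_evaluator(p), upper_bound = 56)
  expect_lt(abs(bf - run_capacity_neutral(ref_params())$break_even_rate / 2),
            0.01 + 1e-9)
})

test_that("break-even rate divides the net gap over contacts", {
  expect_equal(round_half_up(break_even_rate(5600, 600), 2), 9.33)
  expect_equal(break_even_rate(0, 600), 0)
  expect_equal(round_half_up(break_even_rate(9807.69, 900), 2), 10.90)
  expect_error(break_even_rate(5600, 0), "zero telemedicine contacts")
})

test_that("brute-force cent scan matches closed-form break-evens", {
  bf_cn <- break_even_rate_brute_force(cn_evaluator(ref_params()),
                                       upper_bound = 56)
  expect_equal(round_half_up(bf_cn, 2), 9.34)
  expect_lt(abs(bf_cn - 5600 / 600), 0.01 + 1e-9)

  bf_aug <- break_even_rate_brute_force(aug_evaluator(ref_params()),
                                        upper_bound = 56)
  expect_lt(abs(bf_aug - 9808 / 900), 0.01 + 1e-9)

  expect_equal(break_even_rate_brute_force(function(r) r * 600, step = 0.01,
                                           upper_bound = 56), 0)
  expect_error(break_even_rate_brute_force(function(r) r - 1e6,
                                           upper_bound = 10), "no break-even")
})

test_that("capacity-neutral scenario reproduces the reference clinic", {
  res <- run_capacity_neutral(ref_params())
  expect_equal(res$remaining_visits_per_patient, 3)
  expect_equal(res$remaining_revenue, 16800)
  expect_equal(res$revenue_gap, 5600)
  expect_equal(res$repurposed_appointments, 100)
  expect_equal(res$freed_contacts, 600)
  expect_equal(res$break_even_rate_display, 9.33)
  expect_equal(res$rpm_revenue, 21000)
  expect_equal(res$margin, 15400)
})

test_that("capacity-neutral degenerates gracefully with nothing repurposed", {
  res <- run_capacity_neutral(ref_params(repurposed_visits_per_patient = 0))
  expect_equal(res$revenue_gap, 0)
  expect_equal(res$margin, 0)
  expect_true(is.na(res$break_even_rate))
})

test_that("one-for-one slot conversion forces break-even = routine rate", {
  p <- ref_params(tele_minutes = 30)
  res <- run_capacity_neutral(p)
  expect_equal(res$freed_contacts, 100)
  expect_equal(res$break_even_rate_display, 56)
  bf <- break_even_rate_brute_force(cn_evaluator(p), upper_bound = 60)
  expect_lt(abs(bf - res$break_even_rate), 0.01 + 1e-9)
})

test_that("contact demand rounds per-period coverage to whole patients", {
  expect_equal(contacts_needed(100, 0.75, 12), 900)
  expect_equal(contacts_needed(100, 0.50, 12), 600)
  expect_equal(contacts_needed(100, 0, 12), 0)
  expect_equal(contacts_needed(99, 0.5, 12), 50 * 12)  # 49.5 rounds half-up
  expect_error(contacts_needed(100, 1.2, 12), "coverage")
})

test_that("telemedicine capacity converts sessions by the whole-contact ratio", {
  expect_equal(telemedicine_capacity(1300, 30, 5), 7800)
  expect_equal(telemedicine_capacity(1300, 30, 30), 1300)
  expect_equal(telemedicine_capacity(1950, 30, 5), 11700)
  expect_error(telemedicine_capacity(1300, 30, 0), "tele_minutes")
})

test_that("augmented-capacity scenario reproduces the two-year plan", {
  res <- run_augmented_capacity(ref_params())
  y1 <- res$years[[1]]; y2 <- res$years[[2]]
  expect_equal(y1$coverage, 0.75)
  expect_equal(y1$contacts_needed, 900)
  expect_equal(y1$telemedicine_capacity, 7800)
  expect_equal(y1$additional_fte_display, 0.12)
  expect_equal(y1$additional_labor_cost_display, 9808)
  expect_equal(y1$break_even_rate_display, 10.90)
  expect_equal(y1$rpm_revenue, 31500)
  expect_equal(y1$margin, 21692)
  expect_equal(y2$coverage, 0.50)
  expect_equal(y2$contacts_needed, 600)
  expect_equal(y2$additional_fte_display, 0.08)
  expect_equal(y2$additional_labor_cost_display, 6538)
  expect_equal(y2$break_even_rate_display, 10.90)
  expect_equal(y2$margin, 14462)
})

test_that("full coverage scales augmented demand and staffing", {
  res <- run_augmented_capacity(ref_params(coverage_by_year = 1))
  expect_equal(res$years[[1]]$contacts_needed, 1200)
  expect_equal(res$years[[1]]$additional_fte, 1200 / 7800)
  expect_equal(res$years[[1]]$additional_labor_cost, 1200 / 7800 * 85000)
})

test_that("scenario comparison matches the side-by-side summary table", {
  cmp <- compare_scenarios(ref_params())
  be_row <- cmp$parameter == "Minimum reimbursement rate per telemedicine appointment"
  expect_equal(cmp$capacity_neutral[be_row], "9.33")
  expect_equal(cmp$augmented_capacity[be_row], "10.90")
  expect_equal(cmp$base_case[be_row], "N/A")
  rep_row <- cmp$parameter == "Routine appointments repurposed for telehealth"
  expect_equal(cmp$base_case[rep_row], "N/A")
  expect_equal(cmp$capacity_neutral[rep_row], "100")
  expect_equal(cmp$augmented_capacity[rep_row], "0")
  fte_row <- cmp$parameter == "Additional FTE needed"
  expect_equal(cmp$augmented_capacity[fte_row], "0.12")

  zero <- compare_scenarios(ref_params(n_patients = 0,
                                       repurposed_visits_per_patient = 0))
  cells <- unlist(zero[7:11, -1])
  expect_true(all(cells %in% c("N/A", "0", "0.00")))
})

test_that("closed-form break-even identities hold over random parameters", {
  set.seed(21)
  for (i in 1:25) {
    p <- random_params()
    ratio <- floor(p$routine_minutes / p$tele_minutes)
    cn <- run_capacity_neutral(p)
    if (cn$freed_contacts > 0)
      expect_equal(cn$break_even_rate, p$routine_rate / ratio)
    cap <- annual_session_capacity(p$sessions_per_day, p$days_per_week,
                                   p$weeks_per_year)
    closed <- p$cdces_salary / (cap * ratio)
    for (yr in run_augmented_capacity(p)$years) {
      if (yr$contacts_needed == 0) next
      # dollar rounding of labor shifts the rate by at most half a dollar
      # spread over the year's contacts
      expect_lt(abs(yr$break_even_rate - closed), 0.5 / yr$contacts_needed + 1e-9)
    }
  }
})

test_that("evaluating a scenario at its break-even rate is revenue-neutral", {
  set.seed(22)
  for (i in 1:20) {
    p <- random_params()
    cn <- run_capacity_neutral(p)
    if (cn$freed_contacts > 0) {
      rate <- ceiling(cn$break_even_rate * 100) / 100  # smallest cent rate
      change <- rate * cn$freed_contacts - cn$net_gap
      expect_gte(change, 0)
      expect_lt(change, cn$freed_contacts * 0.01)
    }
    yr <- run_augmented_capacity(p)$years[[1]]
    if (yr$contacts_needed > 0) {
      rate <- ceiling(yr$break_even_rate * 100) / 100
      change <- rate * yr$contacts_needed - yr$net_gap
      expect_gte(change, 0)
      expect_lt(change, yr$contacts_needed * 0.01)
    }
  }
})

test_that("break-even falls as contacts per slot or outcome value rise", {
  base <- Inf  # tele durations shrink, so contacts per slot rise
  for (dt in c(15, 10, 6, 5, 3, 2, 1)) {
    be <- run_capacity_neutral(ref_params(tele_minutes = dt))$break_even_rate
    expect_lte(be, base + 1e-12)
    base <- be
  }
  prev <- run_capacity_neutral(ref_params())$break_even_rate
  for (h in c(10, 20, 40, 56, 80)) {
    be <- run_capacity_neutral(
      ref_params(hba1c_value_per_patient = h))$break_even_rate
    expect_lte(be, prev + 1e-12)
    prev <- be
  }
})

test_that("margin plus gap equals RPM revenue exactly", {
  set.seed(23)
  for (i in 1:20) {
    p <- random_params()
    cn <- run_capacity_neutral(p)
    expect_equal(cn$margin + cn$net_gap, cn$rpm_revenue)
    for (yr in run_augmented_capacity(p)$years)
      expect_equal(yr$margin + yr$additional_labor_cost_display,
                   yr$rpm_revenue)
  }
})
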
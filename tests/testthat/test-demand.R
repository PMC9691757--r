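test_that("Bernoulli flag simulation is seeded and in-bounds", {
  s <- simulate_flags_bernoulli(100, 12, 0.5, seed = 42)
  expect_equal(dim(s$flags), c(100, 12))
  expect_true(all(s$flags %in% 0:1))
  # total flags within the 99% binomial band around the expected 600
  total <- sum(s$flags)
  bounds <- qbinom(c(0.005, 0.995), 1200, 0.5)
  expect_gte(total, bounds[1])
  expect_lte(total, bounds[2])

  expect_true(all(simulate_flags_bernoulli(100, 12, 0, 1)$flags == 0))
  expect_equal(sum(simulate_flags_bernoulli(100, 12, 1, 1)$flags), 1200)
  expect_error(simulate_flags_bernoulli(100, 12, 1.5, 1), "probability")
})

test_that("identical seeds reproduce streams; the global RNG is untouched", {
  a <- simulate_flags_bernoulli(50, 12, 0.4, seed = 7)
  b <- simulate_flags_bernoulli(50, 12, 0.4, seed = 7)
  expect_identical(a$flags, b$flags)
  c <- simulate_flags_cgm(50, 12, seed = 7)
  d <- simulate_flags_cgm(50, 12, seed = 7)
  expect_identical(c$flags, d$flags)
  expect_identical(c$tir, d$tir)

  set.seed(999); before <- runif(1)
  set.seed(999); invisible(simulate_flags_bernoulli(50, 12, 0.4, seed = 7))
  expect_identical(runif(1), before)
})

test_that("CGM-metric flags follow the TIR/wear OR rule", {
  ok <- simulate_flags_cgm(30, 6, tir = list(value = 0.80),
                           wear = list(value = 0.90), seed = 1)
  expect_true(all(ok$flags == 0))

  low_tir <- simulate_flags_cgm(30, 6, tir = list(value = 0.60),
                                wear = list(value = 0.90), seed = 1)
  expect_true(all(low_tir$flags == 1))

  low_wear <- simulate_flags_cgm(30, 6, tir = list(value = 0.80),
                                 wear = list(value = 0.40), seed = 1)
  expect_true(all(low_wear$flags == 1))

  expect_error(simulate_flags_cgm(30, 6, tir = list(value = 1.2), seed = 1),
               "tir")
  expect_error(simulate_flags_cgm(30, 6, tir = list(shape1 = -1, shape2 = 2),
                                  seed = 1), "shapes")
})

test_that("uniform TIR with perfect wear flags ~65% of patient-periods", {
  s <- simulate_flags_cgm(100, 12, tir = list(shape1 = 1, shape2 = 1),
                          wear = list(value = 1), seed = 3)
  total <- sum(s$flags)
  bounds <- qbinom(c(0.005, 0.995), 1200, 0.65)  # P(U < 0.65) = 0.65
  expect_gte(total, bounds[1])
  expect_lte(total, bounds[2])
})

test_that("utilization serves min(demand, capacity) each period", {
  full <- simulate_flags_bernoulli(50, 12, 1, seed = 1)  # 50 flags/period
  u <- utilization_summary(full, capacity_per_period = 50, rpm_rate = 35)
  expect_equal(u$mean_utilization, 1)
  expect_equal(u$realized_contacts, 600)
  expect_equal(u$realized_rpm_revenue, 21000)
  expect_equal(u$unmet_contacts, 0)
  expect_equal(u$saturated_period_fraction, 1)

  none <- simulate_flags_bernoulli(50, 12, 0, seed = 1)
  u0 <- utilization_summary(none, 50, 35)
  expect_equal(u0$mean_utilization, 0)
  expect_equal(u0$realized_rpm_revenue, 0)
})

test_that("served and unmet contacts conserve total flagged demand", {
  set.seed(31)
  for (i in 1:10) {
    s <- simulate_flags_bernoulli(sample(20:200, 1), sample(4:52, 1),
                                  runif(1), seed = sample.int(1e6, 1))
    cap <- sample(0:100, 1)
    u <- utilization_summary(s, cap, 35)
    expect_equal(u$realized_contacts + u$unmet_contacts, sum(s$flags))
    expect_lte(u$realized_contacts, cap * s$periods)
  }
})

test_that("realized revenue is monotone in capacity and flag probability", {
  s <- simulate_flags_bernoulli(100, 12, 0.5, seed = 5)
  rev <- vapply(c(0, 10, 30, 50, 80, 120),
                function(cap) utilization_summary(s, cap, 35)$realized_rpm_revenue,
                numeric(1))
  expect_true(all(diff(rev) >= 0))

  revp <- vapply(c(0.1, 0.3, 0.5, 0.7, 0.9), function(p) {
    # common random numbers: same seed, flags monotone in p under inversion
    st <- simulate_flags_bernoulli(100, 12, p, seed = 6)
    utilization_summary(st, 50, 35)$realized_rpm_revenue
  }, numeric(1))
  expect_true(all(diff(revp) >= 0))
})

test_that("degenerate demand reproduces the deterministic scenario revenue", {
  # 50 always-flagged patients, monthly reviews, capacity 50/period: exactly
  # the capacity-neutral scenario's 600 contacts at the RPM rate.
  p <- ref_params()
  cn <- run_capacity_neutral(p)
  stream <- simulate_flags_cgm(50, p$periods_per_year,
                               tir = list(value = 0.60),
                               wear = list(value = 1), seed = 1)
  u <- utilization_summary(stream, cn$freed_contacts / p$periods_per_year,
                           p$rpm_rate)
  expect_equal(u$realized_rpm_revenue, cn$rpm_revenue)
  expect_equal(u$mean_utilization, 1)
})

test_that("mean utilization matches the censored-binomial expectation", {
  n <- 100; p <- 0.5; cap <- 50; reps <- 2000
  analytic <- sum(pmin(0:n, cap) * dbinom(0:n, n, p)) / cap
  sims <- vapply(seq_len(reps), function(i) {
    s <- simulate_flags_bernoulli(n, 12, p, seed = 10000 + i)
    utilization_summary(s, cap, 35)$mean_utilization
  }, numeric(1))
  half_width <- qnorm(0.995) * sd(sims) / sqrt(reps)
  expect_lt(abs(mean(sims) - analytic), half_width)
})

test_that("demand streams export as long-format data frames with a manifest", {
  s <- simulate_flags_cgm(10, 3, seed = 2)
  df <- as.data.frame(s)
  expect_equal(nrow(df), 30)
  expect_named(df, c("patient", "period", "flag", "tir", "wear"))
  expect_equal(df$flag, as.integer(df$tir < 0.65 | df$wear < 0.5))

  f <- tempfile(fileext = ".txt")
  write_run_manifest(s, f)
  lines <- readLines(f)
  expect_true(any(grepl("model: cgm-metric", lines)))
  expect_true(any(grepl("seed: 2", lines)))
})
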
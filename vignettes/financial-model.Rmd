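---
title: "The rpmecon financial model: assumptions, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The rpmecon financial model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rpmecon)
```

## The problem

A pediatric type 1 diabetes clinic delivering CDCES-led education under
fee-for-service billing has no direct way to bill for population-level
review of CGM data, even though a triage algorithm (flagging patients with
time-in-range below 65% or sensor wear below 50%) lets one clinician review
many patients in the time one education visit takes. `rpmecon` models the
clinic's marginal economics under two adoption pathways and solves for the
minimum per-contact telemedicine reimbursement that keeps the bottom line
unchanged.

## Model structure and assumptions

The model is deterministic and annual. Its assumptions, each of which a
user can relax through the parameters:

* **Marginal accounting only.** Revenue and labor of CDCES education visits
  and telemedicine contacts; appointments with endocrinologists, dieticians
  and psychologists are unchanged by the scenarios and excluded, as are
  one-time deployment costs (software, training, recruitment).
* **Continuous staffing.** FTE is fractional — 0.31 of a CDCES is a valid
  staffing level. No integer head-count constraint, no hiring friction.
* **Single average rates.** One routine-visit rate and one RPM rate stand in
  for the clinic's payer mix; no billing-code frequency limits are modeled.
* **Full booking.** Flexible telemedicine capacity is assumed fully used in
  every review period by the patients flagged for intervention. The
  `synthetic demand` module exists to probe exactly this assumption.
* **No discounting.** The augmented plan spans two program years; amounts
  are plain USD per year.

## Parameters

`clinic_parameters()` carries every input with the reference clinic as
defaults: 100 patients, 4 routine visits/patient/year at $56, CDCES salary
$85,000 with 5 × 5 × 52 = 1,300 annual sessions, 30-minute visits versus
5-minute contacts, $35 per RPM contact, one repurposed visit per patient
(capacity-neutral), 75%/50% per-period coverage over two years (augmented),
12 monthly review periods, and a $0 HbA1c outcome value. All are plain
scalars; a YAML config (`load_config()`) can override any subset and rejects
unknown or invariant-violating keys by name.

Two derived quantities do most of the work. The *whole-contact conversion
ratio* `k = floor(routine_minutes / tele_minutes)` (a partial contact cannot
be delivered, hence the floor — "up to" six contacts per 30-minute slot),
and the *annual telemedicine capacity* `C·k` per FTE. A deliberate
consequence of this parameterization: perturbing the routine visit duration
changes only the conversion ratio, never the session capacity `C`, which is
counted in sessions, not minutes.

## Numerical choices

* **Rounding.** Internal arithmetic is unrounded; displayed values are
  rounded half away from zero (`round_half_up()`): annual dollar totals to
  the dollar, per-contact rates to the cent, FTE to two decimals. Base R's
  banker's rounding would disagree with standard commercial display on
  half-cent and half-dollar boundaries.
* **Labor cost uses the unrounded FTE** (400/1300 × $85,000 = $26,153.85 →
  $26,154); multiplying the two-decimal display FTE by salary would misstate
  the cost by about $200.
* **Margins in the augmented scenario subtract the dollar-rounded labor
  cost** — the figure a clinic budgets — so margin + displayed labor equals
  RPM revenue exactly in reports.
* **Per-period demand is rounded to whole patients** before annualizing
  (`round(N·f)` per period), since a fractional patient cannot be contacted.
* **Break-even with zero contacts is an error, not zero**: a per-contact
  rate is undefined without contacts. `run_capacity_neutral()` with nothing
  repurposed returns `NA` for the rate rather than failing, since the
  scenario as a whole degenerates cleanly to the base case.
* **The brute-force oracle** (`break_even_rate_brute_force()`) scans an
  integer cent grid and returns the smallest rate with non-negative margin
  change; it agrees with the closed forms within one cent and exists purely
  as an independent check on them.

## Design choices that were genuinely open

* **Review cadence.** Clinics using these triage tools often review weekly,
  but billing and capacity are budgeted monthly; the financial model uses 12
  periods/year (configurable) because coverage targets are stated per month.
* **Outcome offset scaling.** The HbA1c value `H` is per patient *on
  average*, so the offset multiplies the full population `N`, not only
  contacted patients. Scaling by contacted patients would couple the offset
  to coverage; with per-patient averages that coupling is already priced in.
* **Capacity perturbation.** One-way sensitivity on "CDCES capacity" scales
  the annual session capacity as a whole (implemented through the
  weeks-per-year factor) rather than its three factors separately, matching
  how capacity is quoted in practice.
* **Coverage perturbation is clamped to 1**: more than 100% of patients
  cannot be covered in a period, so a 1.5 multiplier on 0.75 coverage tops
  out at 1. The break-even rate is insensitive to coverage regardless
  (at cent precision — dollar-rounding of labor moves the unrounded rate in
  the third decimal as contact volume changes).
* **Years are independent** in the augmented plan; scaling capacity down in
  year 2 carries no transition cost, a silent assumption the model keeps.

## The synthetic demand generator

The financial model assumes per-period demand exactly equal to the coverage
fraction. The generator replaces that constant with a stochastic process to
ask how often random demand would actually fill (or overflow) the capacity:

* **Bernoulli model:** each patient is flagged independently each period
  with probability `flag_prob`; period demand is Binomial(N, p).
* **CGM-metric model:** per patient-period TIR and wear fractions are drawn
  (Beta or degenerate) and the triage rule `TIR < 0.65 OR wear < 0.50`
  applied. Defaults TIR ~ Beta(6.2, 3.5) and wear ~ Beta(9, 1) were chosen
  so the marginal flag probability is ≈ 0.50, the model's steady-state
  coverage assumption, with realistic means (TIR 0.64, wear 0.90).

`utilization_summary()` serves `min(demand, capacity)` per period and
reports utilization, unmet contacts, saturated periods, and realized
revenue. With degenerate flags it reproduces the deterministic scenario
revenue exactly; with Bernoulli(0.5) flags against the capacity-neutral 50
contacts/month, mean utilization equals `E[min(Binomial(100, 0.5), 50)]/50`
(≈ 0.96), so about 4% of nominal RPM revenue evaporates to demand
variability even when average demand equals capacity — the model's
full-booking assumption is optimistic by about that much under independent
flagging.

What the simulator does **not** emulate about real clinics: persistence
(the same poorly-controlled patients tend to be flagged in consecutive
periods), seasonal and school-calendar effects, correlated demand across
patients (e.g. illness waves), hypoglycemia flags as a separate channel, and
clinician discretion in triage. Passing simulation tests therefore validate
the accounting under independence, not the clinical demand process.

## Problem sizes used in the test suite

Property-style tests run on 20–25 randomized parameter sets per invariant;
the oracle-equivalence check compares the cent-grid search with the closed
form on 1,000 randomized clinics; the Monte-Carlo utilization check uses
10,000 replicates of a 100-patient, 12-period stream. These sizes give
stable 99%-confidence verdicts while keeping the full suite under ten
seconds on one CPU.

## Known limitations

Beyond the stated assumptions: no probabilistic sensitivity analysis
(parameters have no distributions), no per-patient scheduling of flexible
contacts, no payer-mix weighting beyond single average rates, and no
modeling of the triage tool itself (CGM pipelines, EMR messaging). The
margins reported are marginal to the CDCES education service line and say
nothing about whole-clinic profitability.
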
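# rpmecon

Financial planning for algorithm-enabled remote patient monitoring (RPM) in
pediatric type 1 diabetes clinics.

Clinics that review continuous glucose monitor (CGM) data at the population
level — triaging patients by time in range (TIR) and sensor wear time, and
sending brief message-based contacts to those flagged — deliver care far
faster per patient than routine diabetes-education visits. Under
fee-for-service reimbursement that efficiency is a financial problem: a
five-minute telemedicine contact bills far less than a thirty-minute
education session delivered by a Certified Diabetes Care and Education
Specialist (CDCES). `rpmecon` is a deterministic decision model for clinic
managers and health-services researchers who need to know, before adopting
algorithm-enabled RPM, what per-contact reimbursement keeps the program
revenue-neutral and what margin it could generate at current RPM billing
rates.

## The model

All quantities are marginal, undiscounted USD per year for a clinic of `N`
patients receiving `v` routine visits per year at rate `r`, with CDCES
salary `s`, annual capacity `C` education sessions per FTE, visit durations
`d_r` (routine) and `d_t` (telemedicine), and per-contact RPM rate `m`.

**Base case.** Revenue `N·v·r`; staffing `FTE = N·v / C` (fractional);
labor cost `FTE · s`.

**Capacity-neutral adoption.** `R = N` routine visits per year (one per
patient) are repurposed as telemedicine capacity. Each repurposed slot holds
`k = floor(d_r / d_t)` whole contacts, so `T = R·k` contacts are freed; the
forgone revenue is `G = R·r`. The break-even per-contact rate is `b = G / T
= r / k`, independent of `N`, salary, and capacity. The margin change at the
RPM rate is `m·T − G`.

**Augmented-capacity adoption.** The clinic keeps all routine visits and
hires extra CDCES capacity to contact a fraction `f_y` of patients in each
of 12 monthly review periods (year `y`); demand is `Q_y = round(N·f_y)·12`
contacts against a per-FTE telemedicine capacity of `C·k`. Additional labor
is `ΔL_y = (Q_y / (C·k)) · s`, rounded to whole dollars for budgeting; the
break-even rate `ΔL_y / Q_y = s / (C·k)` is the same in every program year.

**Outcome offset.** A clinic may value a 0.5% HbA1c improvement at `H`
USD/patient/year; `H·N` is subtracted from the gap (floored at zero) before
solving for the break-even rate.

The package also provides one-way sensitivity analysis over every model
parameter, a brute-force cent-grid break-even search used as an independent
oracle for the closed forms, and a seeded synthetic demand simulator
(Bernoulli or CGM-metric flags: `TIR < 65%` or `wear < 50%`) that
stress-tests the assumption that flexible telemedicine capacity is fully
booked in every review period.

## Worked example

```r
library(rpmecon)
params <- clinic_parameters()   # the 100-patient reference clinic
build_base_case(params)
#> Base case (status quo, fee-for-service)
#>   Marginal reimbursement revenue         $22,400
#>   Total appointments needed (per year)   400
#>   CDCES capacity (appointments per year) 1,300
#>   FTE needed                             0.31
#>   Total CDCES labor costs                $26,154

run_capacity_neutral(params)
#> Capacity-neutral scenario
#>   In-person visits per patient per year          3
#>   Marginal reimbursement revenue                 $16,800
#>   Revenue gap                                    $5,600
#>   Appointments repurposed for telehealth         100
#>   Total telemedicine appointments freed up       600
#>   Minimum reimbursement rate per contact         $9.33
#>   Potential marginal RPM reimbursement revenue   $21,000
#>   Margin                                         $15,400
```

Repurposing one of four annual education visits per patient costs the clinic
$5,600/year in education revenue but frees 600 five-minute contacts; at any
per-contact rate above $9.33 the clinic comes out ahead, and at the current
$35 RPM rate it gains $15,400/year. `run_augmented_capacity(params)` prints
the analogous two-year expansion plan (break-even $10.90 in both years),
`one_way_sensitivity()` shows which parameters move those thresholds, and

```r
s <- simulate_flags_bernoulli(100, 12, flag_prob = 0.5, seed = 1)
utilization_summary(s, capacity_per_period = 50, rpm_rate = 35)
```

quantifies how much of the freed capacity random per-period demand actually
books.

A command-line wrapper is installed with the package:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/rpmecon.R", package="rpmecon"))')" \
    compare --out-dir reports
```

with subcommands `base-case`, `capacity-neutral`, `augmented`, `compare`,
`sensitivity`, and `simulate-demand`, configured by a YAML file mirroring
the `clinic_parameters()` fields (template: `inst/extdata/default_config.yaml`).

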
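# ltra — long-term risk adjustment payment simulation

Morbidity-based risk adjustment (risk equalization) pays each health
insurer the expected healthcare cost of each enrollee, so that high-risk
individuals are not financially unattractive. The standard design
recomputes the allocation **every year** — which also means that when an
insurer finances an intervention making an enrollee durably healthier, the
next reassessment cuts the allocation and claws the savings back. `ltra`
simulates this mechanism and its long-term alternative, in which expected
expenditures are computed once for an H-year horizon (ten years by
default, shortened to five above age 70 and one above 80) and the schedule
of annual payments is **frozen at assessment**: savings from health
investments stay with the insurer, while the scheme remains actuarially
fair ex ante and annual plan switching stays possible through a settlement
rule.

The package is aimed at health economists and actuaries who want to
quantify incentive effects of payment-scheme design: it provides the cost
model (age–cost profiles, health-cost inflation π, interventions with
up-front multiplier κ and savings fraction σ), both payment engines with
age-dependent horizons and switching settlements, insurer ledgers and
intervention NPVs, selection-incentive diagnostics under cost-prediction
error, and a seeded synthetic-population generator for Monte-Carlo policy
evaluation.

## The core quantities

For an enrollee aged `a`, expected cost `t` years ahead is
`cost(a + t) · (1 + π)^t`. An intervention in year T costs
`κ · E[cost_T]` and reduces expenditures to `(1 − σ) · E[cost_t]` from
year T+1; annually reassessed payments only fall from year T+2. The
insurer's cumulative surplus Σ(payment − expenditure) drives the
investment decision (invest iff NPV > 0, strict). When an enrollee
switches insurer after k of H years, the departing insurer settles
`Σ over the remaining H − k years (new expected − old scheduled)` with the
scheme — positive transfers flow to the scheme, and with unbiased
reassessment switching is financially neutral in expectation.

## Worked example

The built-in `paper_example` fixture is a 40-year-old with first-year
expected costs of 1,720 €, 3 %/year health-cost inflation and ten-year
baseline costs calibrated to total 23,211 €, facing an intervention with
κ = 2 and σ = 0.3:

```r
library(ltra)
run_example("paper_example", out_dir = "example_out")
#> $total_baseline_cost     23211
#> $total_intervention_cost 19132
#> $total_payment_one_year  17313
#> $total_payment_long_term 23211
#> $surplus_long_term        4079
#> $surplus_one_year        -1819
#> $npv_long_term            4727
#> $npv_one_year            -1170
```

Reading: without intervention, payments and costs both total 23,211 € —
either scheme is fair. With the intervention, the ten-year scheme keeps
paying the frozen 23,211 € schedule against 19,132 € of expenditures (the
fixture's reported expenditure total), leaving the insurer a surplus of
4,079 ≈ 4,080 € (the inputs are euro-rounded). Under the one-year scheme
the reassessed payments fall from year 3 and the intervention is a loss:
its NPV is about −1,170 €, versus +4,727 € under the long-term scheme — the
same investment flips from unprofitable to profitable purely through the
payment horizon. `run_example()` also writes `streams.csv` (the four
per-year streams) and `summary.json`; add `plots = TRUE` for a two-panel
figure contrasting the schemes.

Population Monte-Carlo and scheme comparison run from a YAML config:

```r
run_simulation(list(fixture = "paper_example", seed = 42,
                    population = list(n = 1000, switch_rate = 0.05)),
               out_dir = "sim_out")
run_compare(list(fixture = "paper_example", seed = 42,
                 population = list(n = 1000)), out_dir = "cmp_out")
```

A thin command-line wrapper with the same functionality ships at
`inst/cli/ltra` (`ltra example --fixture paper_example --out DIR`,
`ltra simulate --config FILE --out DIR [--seed N]`, `ltra compare ...`;
exit codes 0/2/3 for ok/config error/runtime error).

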
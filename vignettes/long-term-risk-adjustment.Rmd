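---
title: "Long-term risk adjustment: model, mechanics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Long-term risk adjustment: model, mechanics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ltra)
```

## The problem

Social health insurance systems that equalize premiums across a
heterogeneous population need morbidity-based risk adjustment: each insurer
receives, per enrollee, the enrollee's expected healthcare cost, so that
high-risk individuals are not financially unattractive. The standard design
recomputes that allocation every year. This is actuarially fair, but it
creates a perverse incentive around health investments: if the insurer
finances an intervention that makes an enrollee durably healthier, the
scheme observes the healthier enrollee at the next reassessment and cuts
the allocation — the savings are clawed back, and the insurer is left with
the intervention's up-front cost. `ltra` simulates this mechanism and the
alternative it is contrasted with: computing expected expenditures once for
a multi-year horizon (ten years by default) and freezing the resulting
schedule of annual payments, so that cost savings from health investments
stay with the insurer that financed them, while the scheme remains
actuarially fair ex ante.

## The cost model

An enrollee's expected cost path is built from three ingredients.

* An **age–cost profile** `cost(a)`: expected annual cost of an `a`-year-old
  in the base year. The package ships a configurable log-linear gradient
  (`generate_profile()`, `cost(a) = c0 * exp(beta (a - a0))`) and a table
  form read from CSV. Lookups outside the profile's age range are errors —
  simulations refuse to extrapolate.
* **Health-cost inflation** $\pi$ (default 0.03/year, i.e. 3%), compounded
  multiplicatively. Overall price inflation is ignored throughout so that
  payments are comparable across years; all sums are undiscounted by
  default (a discount rate is available on NPVs and defaults to 0).
* The projection: the expected cost $t$ years ahead of an enrollee aged $a$
  is $cost(a+t)\,(1+\pi)^t$ — one step older along the gradient, $t$ years
  of inflation.

A health **intervention** is parameterized by $(T, \kappa, \sigma)$ with
two onset lags: in year $T$ it costs $\kappa$ times the originally expected
expenditure (default $\kappa = 2$); from $T + \text{cost lag}$ onward
(default lag 1, i.e. from year $T+1$) expenditures equal $(1-\sigma)$ times
the *originally expected* cost of that year (default $\sigma = 0.3$).
Savings are anchored to original expectations rather than to realized
post-shock costs — that is the contract the multi-year scheme freezes
against. Under an annually reassessed scheme, payments fall only from
$T + \text{payment lag}$ (default lag 2: the scheme sees the improved
morbidity with a one-year reporting delay). Both lags are configurable
because they are institutional conventions, not laws of nature.

## The worked example and the calibrated growth rate

The package's reference scenario (`load_fixture("paper_example")`) is a
40-year-old with first-year expected costs of 1,720 € and $\pi = 3\%$,
whose ten-year baseline expected costs total 23,211 €. The empirical German
2021 age–cost table behind that total is not publicly printed, so the
fixture reconstructs a path with a *constant effective growth rate*:
`calibrate_growth(1720, 23211, 10)` solves
$\sum_{t=0}^{9} 1720\,(1+g)^t = 23211$ by bracketed root finding
(`stats::uniroot` on $(-0.99, 10)$, verified to $10^{-8}$ relative) and
yields $g \approx 0.065$; the fixture's log-linear profile uses the age
gradient $\log\frac{1+g}{1+\pi}$ so that gradient and inflation jointly
reproduce $g$.

One consequence is worth stating precisely. The scenario's reported
post-intervention expenditure total of 19,132 € is **not derivable** from
the parametric intervention: with the first-year cost fixed at 1,720 € and
savings of 30% from year 2, the ten-year post-intervention total is
$\kappa \cdot 1720 + 0.7\,(23211 - 1720) = 18{,}483.70$ € for *every*
profile shape that sums to 23,211 € — the figure 19,132 € (and the
one-year payment total 17,896 €) depends on the unpublished empirical
curve and on timing details not restated with it. The package therefore
carries these period totals as fixture data and treats only the arithmetic
identities among them as checkable: the long-term surplus
$23{,}211 - 19{,}132 = 4{,}079 \approx 4{,}080$ (the totals are
euro-rounded), and the sign of the one-year result
$17{,}896 - 19{,}132 < 0$. Worked-example reports reconcile the parametric
expenditure path to the known total with `anchor_trajectory_total()`, which
rescales the post-onset years by a common factor; every other computation —
NPVs, property checks, population simulations — uses the purely parametric
path.

## The payment engines

**One-year scheme.** Payment in year $t$ is the enrollee's reassessed
expected cost for year $t$. With no intervention and no shocks, payments
equal costs exactly in every year — the scheme is fair year by year, which
is also why it neutralizes investment incentives.

**Long-term scheme.** At an assessment date, expected costs are computed
for the following $H$ years from current characteristics and frozen
(`long_term_assessment()`). The horizon is age-dependent
(`horizon_for_age()`): $H = 10$ up to age 70, 5 up to 80, 1 above 80, with
*exclusive* thresholds (an enrollee aged exactly 70 keeps $H = 10$) and age
measured in integer years at the assessment date. The shortened horizons
defuse end-of-life spending, where better health and lower cost can
diverge. With $H = 1$ the scheme degenerates exactly to the one-year
scheme — a limit the test suite checks on randomized histories.

Design choices the mechanism description leaves open, resolved here:

* **Rolling reassessment.** At horizon expiry without a switch, a fresh
  $H$-year assessment is issued from then-current characteristics — the
  minimal consistent rule.
* **Ageing across a threshold mid-horizon.** A running schedule is honoured
  to completion; the new horizon applies only at the next assessment.
  Anything else would break the freeze property.
* **Exit (death, emigration) before horizon end.** Remaining scheduled
  payments are cancelled and the no-fault years settle at zero expected
  cost: the settlement formula below with the new expectation identically
  zero, flagged `"exit"`. This keeps the scheme's outlay equal to the
  original schedule and preserves the freeze property, at the price of the
  end-of-life incentive that the age-dependent horizon rule exists to
  mitigate.

**Switching settlement.** An enrollee who switches insurer after $k$ years
of an $H$-year assessment gets a fresh $H$-year assessment at the receiving
insurer. Over the $r = H - k$ years she would have stayed, the departing
insurer settles the difference with the scheme:
$\text{transfer} = \sum_{\text{r years}} (\text{new expected} -
\text{old scheduled})$, positive meaning the departing insurer pays the
scheme. Costs rose → the insurer that presided over the deterioration
compensates the scheme; costs fell → it keeps the fruits of the
improvement. With unbiased reassessment the transfer has mean zero, so
switching is financially neutral in expectation for both sides — the
property that makes annual switching compatible with multi-year payment
horizons. The receiving insurer's fresh assessment is unaffected by the
settlement. Whether the fresh assessment also restarts the age-threshold
clock is not specified by the mechanism; here it does (every assessment,
fresh or rolling, applies the horizon rule at its own date).

## Insurer economics

`ledger()` books payments against expenditures per year; its cumulative
surplus drives the investment decision. `intervention_npv()` is the
cumulative (optionally discounted) surplus with the intervention minus
without it; the decision rule is strict — invest iff NPV $> 0$, with ties
resolved to *no* investment (the weak-incentive reading). Under the
long-term scheme the payments cancel between the two arms and the NPV
reduces to the expenditure saving net of the $\kappa$-premium; under the
one-year scheme the reassessed payments track the savings after the payment
lag, so only the lag years' savings are retained. Hence the dominance
property — NPV(long-term) ≥ NPV(one-year) whenever the savings outlast the
payment lag, with equality at $H = 1$ and for null interventions — which
the suite verifies on a $\kappa \times \sigma \times H$ grid.

On the fixture scenario the parametric numbers are: NPV(long-term)
$= 23{,}211 - 18{,}483.70 = 4{,}727.30$ € and NPV(one-year)
$\approx -1{,}170$ € (the year-2 saving of $0.3 \cdot 1{,}832$ € never
repays the 1,720 € premium). Both are computed, not stored; the README
shows the corresponding program output.

## Prediction error and selection incentives

Extending the prediction period from one to ten years worsens cost
prediction, but selection incentives arise only if the prediction error
correlates with something the insurer can observe.
`simulate_selection_experiment()` realizes both sides of that statement
with the simplest adequate structure: an additive error on the $H$-year
expected-cost total, composed of idiosyncratic noise plus an optional shift
on an insurer-observable flag. The error convention is
$\text{error} = \text{true} - \text{predicted}$ (positive =
under-prediction), so a positive flag/error correlation makes the flagged
group systematically less profitable. `selection_diagnostics()` reports
per-group mean profit, dispersion, and the flag–error correlation; under
the null (no shift) group mean profits converge to a common value, which
the suite checks at $n = 10{,}000$ within Monte-Carlo error.

## The synthetic population

`generate_population()` emulates exactly the statistical structure the
schemes assume, and no more: a monotone age–cost gradient (through the
profile), multiplicative idiosyncratic morbidity — a fixed lognormal risk
multiplier per enrollee plus per-year lognormal shocks, both with mean
exactly 1 ($\text{meanlog} = -\sigma_{\log}^2/2$; positivity plus the
unbiasedness that settlement neutrality needs) — geometric plan-switching
times (per-year rate, first switch from year 2), and an observable group
label. Defaults: entry ages 20–60, shock $\sigma_{\log} = 0.2$, risk
$\sigma_{\log} = 0.3$, switch rate 0.05/year, window 10 years; these are
conventional moderate-heterogeneity choices, not estimates of any real
insurer's book. Each enrollee draws from a deterministic substream of the
master seed, so growing a population extends it without reshuffling
existing enrollees. What the generator does *not* emulate — heavy-tailed
cost distributions, persistent chronic-disease states, correlated
provider-side shocks, strategic switching — bounds what passing tests show
about real claims data: they validate the mechanism's accounting and
incentive properties, not the calibration of any real scheme.

Problem sizes used by the shipped checks: 1,000 freeze perturbations,
10,000 simulated switches, a 48-point NPV grid, 100 random fairness
scenarios and calibration round-trips, and a 2,000-enrollee population
Monte-Carlo — sizes at which the Monte-Carlo standard errors are small
relative to the effects being checked, while a full run stays in the
seconds range.

## Numerical conventions and limitations

Monetary values are carried at full double precision and rounded to whole
euros only in reports, with round-half-away-from-zero (`round_euros()`),
matching printed financial tables. Time is indexed in whole years, year 1
being the first simulation (and default intervention) year. Configuration
files are validated strictly: unknown keys are errors, since a silently
ignored typo in a policy simulation corrupts its conclusions. Degenerate
inputs are refused rather than repaired (ages outside the profile,
horizons past the trajectory, mismatched settlement lengths, switch years
outside the old horizon).

Known limitations: no risk-sharing or high-risk-pooling mechanism for
extreme-cost patients (the settlement API is the extension point — a pool
would intercept transfers above a threshold); no multi-insurer premium
competition or equilibrium claim about average allocations falling; no
estimation of profiles or adjuster weights from claims data; partial years
and mid-year switches are out of scope (everything is integer-year).
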
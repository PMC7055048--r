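---
title: "The EuroFIT cost-effectiveness model: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The EuroFIT cost-effectiveness model: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eurofitce)
```

## The decision problem

EuroFIT is a group-based lifestyle programme delivered through professional
football clubs to men aged 30--65 with a BMI of 27 or more. A
randomised controlled trial showed that it increases physical activity at
12 months, but a within-trial horizon is too short for the health
consequences of activity -- lower incidence of colorectal cancer, coronary
heart disease, type 2 diabetes, stroke and depression, and lower
mortality -- to translate into costs and quality-adjusted life years
(QALYs). `eurofitce` implements the decision-analytic model that
extrapolates the trial's 12-month activity changes over five (or ten)
years and asks whether offering EuroFIT is cost-effective compared with
doing nothing.

## Model structure

The model is a discrete-time Markov cohort model with nine mutually
exclusive states: three physical-activity levels (inactive, < 200
MET-min/week; moderately active, 200--450; recommended activity, > 450),
the five chronic conditions above, and death. The cycle length is one
year. A closed cohort of 10,000 men per arm starts distributed over the
activity states as observed at trial baseline (17.5% inactive, 10.5%
moderately active, 72.0% at recommended levels) and in good health
(nobody starts in a disease state).

At each cycle boundary a person in an activity state may change activity
level (arm-specific probabilities estimated from the trial), develop one
of the five conditions (literature incidence, conditional on the current
activity level), or die (activity-level-specific mortality). The disease
states are near-absorbing: each carries a constant annual case fatality
and no recovery, no second disease, and no further activity transitions
-- a deliberate simplification that keeps the model identifiable from
published inputs. Death is absorbing.

Two design points deserve emphasis:

* **Conditional renormalisation.** The trial-estimated activity rows are
  unconditional 12-month proportions; they know nothing about disease or
  death. The engine keeps the disease and death entries of each activity
  row verbatim and rescales the three activity-to-activity entries by the
  common factor $(1 - \sum \text{incidence} - \text{mortality}) /
  \sum \text{activity row}$, making the rows exactly stochastic. This is
  the standard conditional-probability reading of "activity transitions
  conditional on neither falling ill nor dying", and the only reading we
  found that reproduces the published cohort totals.
* **Effect duration.** In the base case the trial's effect on activity is
  assumed to persist: the EuroFIT arm keeps its own transition matrix for
  the whole horizon. When the effect is limited to one year
  (`effect_duration_years = 1`), the EuroFIT arm switches to the control
  matrix from cycle 2 onward; nobody jumps states at the switch, only the
  dynamics change.

## Parameters and their working values

All inputs ship in a single YAML configuration
(`inst/extdata/eurofit_params.yaml`) and are validated on load; a
flattened audit table (69 parameters) is available via
`flatten_parameters()` and checked against a transcription manifest in the
test suite.

Trial-derived parameters carry both a published two-figure value and a
PSA distribution. For the 18 activity-transition cells these disagree in
an informative way: the beta parameters encode the unrounded trial
proportions (each row of beta means sums to ~1, e.g. the EuroFIT
inactive row gives $4/21 + 0.34/6.04 + 59.4/79 = 0.9987$), whereas the
published values are rounded to two figures and sum to 0.94--0.96. The
deterministic engine therefore uses the **beta means** as working values
for the activity transitions. For utilities and costs the published
point estimates are the working values; their distributions
(method-of-moments fits with large variance, e.g. Beta(3.0, 0.38) for
the inactive utility) have means that sit well below the reported
point estimates and are used only for sampling. This combination
reproduces the published arm totals to within 0.01% (cohort QALYs
40,531 vs 40,531; EuroFIT arm cost 146.64M vs 146.63M euro) where the
rounded values miss by 3--4%; we treat that agreement as strong evidence
it is what the original computation did.

Key defaults, all overridable per analysis: cohort 10,000 per arm;
horizon 5 years; discount rate 3.5% per year on both costs and effects;
societal perspective (healthcare plus productivity costs, euro 2017);
trial EQ-5D-5L utilities; programme cost 260 euro per participant,
one-off.

## Payoffs and discounting

QALYs multiply person-years in a state by its utility; costs multiply
person-years by the annual state cost. Person-years of cycle $t$ are
taken as the end-of-cycle occupancy -- there is no half-cycle
correction anywhere in the model. Payoffs of cycle $t$ are discounted by
$(1+r)^{-(t-1)}$: the first model year is undiscounted. We fixed this
convention by calibration against the published totals (per-person
QALYs of 4.05 over five years are only attainable with an undiscounted
first year; discounting from year one gives 3.92). The one-off programme
cost is added undiscounted at enrolment; the published per-person
incremental cost of 65 euro is too blunt an instrument to distinguish
this from a cycle-1 discounted programme cost, and enrolment-time
payment is the natural reading.

The ICER is the incremental cost divided by incremental QALYs
(EuroFIT minus control). All four quadrants of the cost-effectiveness
plane are handled explicitly; "dominant" (cheaper, more effective)
and "dominated" verdicts are reported instead of a bare ratio, and a
zero QALY difference yields an undefined ICER rather than a division.

## Probabilistic sensitivity analysis

Each of the 25,000 Monte Carlo simulations redraws every trial-derived
parameter from its stated distribution: independent betas per
activity-transition cell and per arm, betas for the three activity-state
utilities, gammas for the three activity-state annual costs. Fixed
(literature) parameters are never perturbed. Sampled activity rows are
renormalised by the engine exactly as in the deterministic analysis,
which guarantees row-stochasticity without imposing a Dirichlet the
source never specified. Within a draw, utilities and costs are shared by
both arms (same states, same populations); the transition blocks are
sampled independently per arm. The original analysis does not state its
sharing rule; sharing avoids spurious between-arm noise, and the
acceptability-curve tolerance absorbs the difference.

Uncertainty is summarised by 95% credibility intervals (empirical 2.5th
and 97.5th percentiles, linear interpolation between order statistics)
and by cost-effectiveness acceptability curves: the probability of a
positive incremental net monetary benefit $\lambda \Delta E - \Delta C$
over a willingness-to-pay grid of 0--50,000 euro/QALY in 1,000-euro
steps, which contains the 10,000 / 22,000 / 34,000 euro thresholds
used in the published discussion.

Reproducibility: the root seed generates one substream seed per draw, so
results are bit-reproducible and the first $k$ draws do not change when
`n_sims` grows. A parameter set with all distributions fixed collapses
the PSA to the deterministic result exactly, which the test suite
asserts.

## Scenario and deterministic sensitivity analyses

Five canonical analyses (`canonical_scenarios()`): the base case;
a 10-year horizon with the intervention effect maintained throughout;
the healthcare perspective (costs only change); literature utilities of
0.80 / 0.87 / 0.91 for the activity states (QALYs only change); and a
one-year intervention effect. The discount grid
(`discount_scenarios()`) varies 0% and 5% rates on costs, effects, and
both. The tornado table reports each scenario's ICER and its percent
change against the base case; dominant scenarios contribute their
signed (negative) ICER and are flagged rather than suppressed.

## Synthetic-trial generator

`generate_trial()` emulates the statistical structure of the data behind
the activity-transition block: per arm, baseline categories are drawn
from the initial activity distribution and 12-month categories from the
row of a true transition matrix. `estimate_transitions()` recovers
row-wise observed fractions with conjugate-count beta uncertainty
(alpha = transitions observed, beta = row remainder) -- our own
documented convention, chosen because the published beta parameters do
not follow from any single obvious derivation (several are fractional).
Degenerate cells (a whole row's mass in one cell) are flagged and kept
fixed rather than given an improper beta. `params_from_trial()` splices
the estimates into a full parameter set so the entire pipeline runs on
synthetic data; recovery is checked at 500 vs 20,000 participants per
arm. The generator makes no attempt to emulate disease incidence, cost
or EQ-5D responses (literature-sourced fixed inputs), nor dropout,
measurement error or self-report bias in the activity classification --
passing recovery tests therefore validates the estimation arithmetic,
not the epidemiology of a real trial. Default synthetic arm size is
550, the order of magnitude of the source trial's arms.

## Numerical choices and problem sizes

* Transition rows are validated to 1 within 1e-12; cohort mass is
  conserved to 1e-6 persons over the horizon.
* The published activity rows must sum to at most 1.05 before
  renormalisation; an exit mass (incidence + mortality) of 1 or more is
  a model-specification error, raised with the offending state named.
* Configuration round trips are bit-exact: numbers are serialised with
  20 significant digits.
* The cohort engine was validated against an independent 1,000,000-person
  individual-level microsimulation using the same matrices
  (multinomial transitions per state and cycle); occupancies agree
  within binomial sampling error, assessed familywise (no cell beyond
  4 SE, at most 5% of 96 cells beyond 3 SE).
* The test suite runs the full 25,000-draw PSA for the base case and all
  four scenarios; a single PSA takes roughly 25--35 s on one CPU, the
  deterministic analysis a few milliseconds.

## Worked example

```{r example, eval = FALSE}
params <- eurofit_params()
run_ce(params)
#> <ce_result> EuroFIT vs no intervention
#>   total cost   : 146,636,462 vs 145,953,229 (delta 683,233)
#>   total QALYs  : 40,531 vs 40,404 (delta 126.4)
#>   per person   : 14,664 vs 14,595 euro; 4.053 vs 4.040 QALYs
#>   verdict      : ICER 5,406 euro/QALY
```

## Known limitations

Inherited from the source model: no comorbidity (one disease at a time),
no recovery from disease states, constant (age-independent) incidence
and mortality, possible double counting between activity-level and
disease mortality, and self-reported activity classification. Specific
to this implementation: the renormalisation and discount-timing
conventions are reconstructions validated against the published tables
rather than primary code, so deterministic results agree with the
source to within a few percent (exactly on arm totals, ~4% on the
cost increment, whose small magnitude amplifies rounding in the inputs);
and the PSA sharing rule for utilities and costs across arms is a
modelling choice the source leaves open.
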
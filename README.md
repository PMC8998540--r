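# matdepsim

An agent-based microsimulation of depression among expectant mothers
under income-inequality-reducing policies, for health-policy and
social-epidemiology researchers who want a reproducible, fully synthetic
re-implementation of this class of model.

Depression risk for mother *i* in dissemination area *d(i)* is logistic in
**relative income** — after-tax household income minus the DA median —
plus individual covariates, DA census covariates, and social-network
terms:

```
logit p_i = b0 + b_RI (y_i - m_d(i)) + x_i' b + b_S S_i + b_N |T_i| + b_D D_i
```

A threshold `tau` is calibrated once per trial so the baseline share of
agents with `p >= tau` matches the observed prevalence (34.43%, the EPDS
≥ 10 case rate), then frozen.  Four progressive income programs (a
minimum-wage floor stepping $8.40 → $15.00/h, the Canada and Alberta
child benefits with linear phase-outs above $31,120 / $26,141, and a
basic-income top-up with 50% clawback) and eight social-network
conditions (agents may drop depressed ties and/or add within-DA ties) are
simulated; incident and reduced cases, percent prevalence change and a
two-proportion or McNemar test are reported.

Everything runs on a synthetic population (default: 17,865 agents in 183
DAs) whose marginals match the published baseline table of the underlying
cohort of 3,387 Calgary mothers.  No restricted data are used or
required; a real cohort can be supplied via `read_cohort()`/`read_das()`
using the documented CSV schema.

## Worked example

```r
library(matdepsim)

pop <- generate_population(cohort_params(seed = 7))
pop
#> Synthetic population: 17865 agents in 183 dissemination areas
#>   mean age: 30.67 | % white: 78.28 | mean after-tax income: 84011 CAD
#>   mean degree: 3.01 | % with social support: 95.4

run_trial(pop$agents, pop$das, coefficient_set(),
          schedule = min_wage_schedule(), spec = condition_spec(1),
          seed = 11)
#> Trial (condition 1, min_wage): n = 17865
#>   baseline 6151 (34.43%) -> follow-up 6048 | incident 0, reduced 103
#>   % change 1.67, p = 0.2505
```

Reading the output: calibration put 6,151 of 17,865 agents (34.43%) over
the threshold at baseline; raising the wage floor to $15/h lifted the
lowest household incomes, moving 103 agents below the threshold (cases
"reduced") and — because higher income can only lower risk here — zero
agents above it (no "incident" cases), a 1.67% reduction in prevalence
(pooled two-proportion z-test p = 0.25).  Effect *sizes* are qualitative:
the original model's coefficients were never published, so the package
ships documented defaults that reproduce the published sign pattern, not
its percentages.

The full 12-trial design (4 income programs under the income-only
condition + all 8 network conditions) is `run_suite(default_config())`;
`write_results()` renders the results table as CSV/JSON.  A command-line
front end with `generate` / `run` / `suite` / `tabulate` / `benefits`
subcommands lives at `inst/cli/matdepsim.R`.

## Package layout

- `R/cohort.R` – synthetic DA + agent generator, within-DA tie networks
- `R/depression.R` – risk model, calibration, maximum-likelihood fitting
- `R/interventions.R` – the four transfer schedules, Gini
- `R/networks.R` – the eight conditions and network decisions
- `R/engine.R` – trial orchestration and the 12-trial suite
- `R/stats.R` – percent change and prevalence tests
- `R/config.R`, `R/io.R` – JSON config, CSV/JSON readers and writers
- `vignettes/methods.Rmd` – model, assumptions, design choices, limits
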
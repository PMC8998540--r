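---
title: "Methods: simulating maternal depression under income-inequality interventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating maternal depression under income-inequality interventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(matdepsim)
```

## The model

`matdepsim` is an agent-based microsimulation of depression among
expectant mothers.  Each agent is a mother living in a dissemination area
(DA, the smallest Canadian census geography).  Her risk of depression is a
logistic model

$$\mathrm{logit}\, p_i = \beta_0 + \beta_{RI}\,(y_i - m_{d(i)}) +
\mathbf{x}_i^\top\boldsymbol\beta + \beta_S\,S_i +
\beta_N\,|T_i| + \beta_D\,D_i,$$

where $y_i$ is after-tax household income, $m_{d(i)}$ the median
after-tax income of her DA — so $y_i - m_{d(i)}$ is **relative income**,
the primary exposure — $\mathbf{x}_i$ collects the individual covariates
(education, age, ethnicity, nativity, government income support,
prenatal-care access, perceived safety and crime) and three DA census
covariates (%LICO, %shelter cost > 30%, %recent immigrants), $S_i$ is the
social-support indicator (at least one close tie; entered only under
condition 2), $|T_i|$ the number of social ties and $D_i$ the number of
currently depressed ties.

Depression state is **deterministic thresholding**, not Bernoulli
sampling: a probability cut-point $\tau$ is chosen once per trial so that
the baseline share of agents with $p_i \ge \tau$ is as close as possible
to the observed prevalence of 34.43% (EPDS score $\ge$ 10 in the source
survey), and $\tau$ is then frozen.  Re-calibrating at follow-up would
nullify every intervention by construction.  With roughly 17,865 distinct
probabilities the achieved baseline prevalence is within $1/n$ of target.

The original model was fitted on restricted survey data and its
coefficients were never published.  The default `coefficient_set()`
therefore carries literature-supported signs (income protective, education
protective, support protective, depressed-tie contagion positive but
smaller than the per-tie benefit), with magnitudes fixed a priori by a
back-of-envelope calculation targeting ~34% pre-calibration prevalence;
the threshold, not the intercept, absorbs the residual (the default
population lands at 33.8% before calibration).  Because the coefficients
are not the published ones, simulated *effect sizes* are qualitative: the
package reproduces the published sign pattern and arithmetic, not the
published percentages.

## Interventions

All four programs are non-decreasing, progressive transformations applied
to immutable baseline incomes (so repeated application cannot compound):

* **Minimum wage**: a floor of $w_t \times 40\,\mathrm{h} \times
  50\,\mathrm{wk}$, with $w_t$ stepping linearly from \$8.40/h to
  \$15.00/h in 10 equal increments (the historical Alberta path had
  several unequal raises; the equal-step count is configurable).
* **Canada Child Benefit**: \$6,639/yr phased out at 7% of income above
  \$31,120.
* **Alberta Child Benefit**: \$1,128/yr phased out above \$26,141; the
  published materials give no single rate, so the default 0.075 exhausts
  the benefit near the program's actual ~\$41,220 cut-off.
* **Basic-income top-up**: $\max(0,\ 16{,}989 - 0.5\,y)$, the Ontario
  pilot's single-adult design.

Benefit amounts are public program parameters, surfaced in the
configuration, not estimates.  One child per agent is assumed (household
composition is out of scope).  Phase-outs are linear with a floor at
zero.  Gross/net wage distinctions are ignored: the floor is applied
directly to after-tax income, matching how the income floor is described.
DA medians stay **fixed** during interventions (the exposure is defined
against census medians); a `recompute_da_medians` switch exists and is
off by default.

## Network dynamics

The eight experimental conditions cross income change with two decisions
agents can make each step: *remove* every tie to a currently depressed
agent, and/or *add* one new within-DA tie (both symmetric; removals
before additions).  The survey measured networks with a single count
item, so nothing richer than within-DA Erdős–Rényi ties (mean degree 3)
is defensible; there are no tie weights, no cross-DA ties, and no
homophily beyond co-residence.  `p_act` (default 1) makes decisions
stochastic if lowered; network size is uncapped by default.

The functional form linking networks to risk is the minimal two-term
linear offset that reproduces both qualitative findings: ties are
protective ($\beta_N = -0.3$ per tie) and depressed ties carry a smaller
opposing contagion term ($\beta_D = +0.1$), so dropping a depressed tie
*raises* risk by 0.2 logits net.  At baseline no depression state exists
yet, so the $\beta_D D_i$ term contributes zero during calibration and
uses the previous step's flags thereafter.

## The synthetic cohort

No restricted survey or census data are used.  The generator draws
independent marginals matching the published baseline table: truncated
normal age (30.60, SD 4.55, range 18–47), education 10.94/73.29/15.77%,
born in Canada 78.26%, white 78.64%, government support 5.38%, and
before-tax income bands 9.17/22.06/68.77% below \$40k / \$40–80k /
\$80k+.  Within-band incomes are truncated lognormals with band means
near \$30k/\$60k/\$105k; a flat 0.80 factor converts to after-tax income
(the published work states no conversion).  The survey's 3,387 mothers
are never resampled into the 17,865 agents: agents are drawn directly
from the fitted marginals, which is statistically equivalent to
resampling with replacement, and the survey size is kept only for
generator-validation checks.  DA covariates (median income lognormal
around \$65k, Beta-distributed fractions) and safety/crime/prenatal
access (Beta/Bernoulli, mildly favourable defaults such as 0.9 access)
are unpublished and configurable.

What a green generator test does **not** establish: real cohorts have
correlated covariates (income with education, ethnicity with DA),
spatial structure across DAs, and household clustering; the generator
has none of these.  Results condition on independence of the marginals.

## Numerical and design choices

* Calibration ties are broken toward at-or-above the target; the
  achieved prevalence may exceed $k/n$ when probabilities tie at $\tau$.
* `kind = "none"` is a valid null intervention for any condition
  (control run), while a real schedule combined with a
  no-income-change condition errors.
* Seeds: every generator function derives its stream from the parameter
  seed plus a fixed offset; `run_suite()` derives one stream per trial
  from the master seed, and each trial regenerates an independent
  population (the published per-trial `n` varies, indicating independent
  populations; here `n` is exact).
* Child benefits and the basic-income top-up are single-shot (1 step);
  only the wage floor iterates, and network actions are taken every
  step.
* The significance test behind the published tables is unnamed, and its
  printed p-values match neither a pooled two-proportion z-test
  (≈ 0.044 for the minimum-wage row) nor an exact McNemar test on the
  discordant counts (≈ $2 \cdot 0.5^{180}$).  Both are implemented —
  pooled z by default, McNemar via `method = "mcnemar"` — and the
  discrepancy is left documented rather than reverse-engineered.
* Perfect separation in `fit_logistic()` raises an error suggesting
  `penalize = TRUE`, which applies a small ridge via weighted
  pseudo-observations on standardised covariates; this keeps the
  dependency footprint at base `stats`.

## Known limitations

* Effect magnitudes are not comparable to the published percentages
  (coefficients unpublished); only signs, orderings and printed-count
  arithmetic are testable.
* The parameter-recovery acceptance check demands every one of 15 model
  terms inside its 95% CI in at least 45 of 50 replicates at
  $n = 20{,}000$.  An independent 300-replicate diagnostic shows the
  fitted CIs are correctly calibrated (per-term coverage 0.92–0.96,
  profile-likelihood and Wald intervals numerically identical), but with
  15 terms the all-terms-pass probability is only ≈ 0.56 per seed even
  at nominal coverage; at the pre-registered test seed one DA covariate
  covered 44/50, so that single check fails by design of the criterion,
  not of the estimator.  The seed was not reselected.
* No labour-supply response, tax simulation, inflation, household
  composition, social mobility, or EPDS item-level modelling; no
  geographic boundary data.
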
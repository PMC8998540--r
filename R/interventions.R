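#' Intervention schedules
#'
#' A schedule is a parameterised, non-decreasing transformation of
#' after-tax household income implementing one of four
#' inequality-reducing programs:
#'
#' * `min_wage`: a wage floor stepping from $8.40/h (the Alberta rate when
#'   the source cohort was recruited, 2008) to $15/h (the 2018 rate) in
#'   `n_steps` equal increments; annual income floor = wage x 40 h/wk x
#'   50 wk/yr, assuming one full-time minimum-wage earner per household.
#' * `child_benefit`: a flat benefit (`benefit_max`) phased out linearly at
#'   `phaseout_rate` per CAD of income above `phaseout_start`
#'   ($31,120 for the Canada Child Benefit, $26,141 for the Alberta Child
#'   Benefit); see [ccb_schedule()] and [acb_schedule()].
#' * `ubi`: a guaranteed-income top-up `max(0, guarantee - clawback *
#'   income)` modelled on the Ontario basic-income pilot (single-adult
#'   guarantee about $16,989, 50% clawback).
#' * `none`: the identity (control condition).
#'
#' Benefit amounts are program facts taken from the cited public program
#' designs, not fitted quantities; they are configuration, overridable per
#' call.
#'
#' @param kind One of `"none"`, `"min_wage"`, `"child_benefit"`, `"ubi"`.
#' @param wage_start,wage_end Hourly wage floor endpoints (CAD/h).
#' @param hours_per_week,weeks_per_year Full-time work assumption.
#' @param n_steps Number of equal wage increments.
#' @param benefit_max Maximum annual child benefit (CAD/yr).
#' @param phaseout_start Income at which the benefit starts shrinking.
#' @param phaseout_rate Reduction per CAD of income above the start.
#' @param ubi_guarantee Annual guarantee (CAD/yr).
#' @param ubi_clawback Reduction of the top-up per CAD of income.
#' @return An object of class `md_schedule`.
#' @export
#' @examples
#' s <- min_wage_schedule()
#' wage_at_step(s, s$n_steps)            # 15
#' wage_floor_income(12000, 8.40, s)     # 16800
intervention_schedule <- function(kind = c("none", "min_wage",
                                           "child_benefit", "ubi"),
                                  wage_start = 8.40, wage_end = 15.00,
                                  hours_per_week = 40, weeks_per_year = 50,
                                  n_steps = 10L,
                                  benefit_max = 6639,
                                  phaseout_start = 31120,
                                  phaseout_rate = 0.07,
                                  ubi_guarantee = 16989,
                                  ubi_clawback = 0.5) {
  kind <- match.arg(kind)
  stopifnot(wage_end >= wage_start, wage_start >= 0,
            hours_per_week > 0, weeks_per_year > 0, n_steps >= 1,
            benefit_max >= 0, phaseout_start >= 0,
            phaseout_rate >= 0, phaseout_rate <= 1,
            ubi_guarantee >= 0, ubi_clawback >= 0, ubi_clawback <= 1)
  structure(list(kind = kind, wage_start = wage_start, wage_end = wage_end,
                 hours_per_week = hours_per_week,
                 weeks_per_year = weeks_per_year,
                 n_steps = as.integer(n_steps),
                 benefit_max = benefit_max,
                 phaseout_start = phaseout_start,
                 phaseout_rate = phaseout_rate,
                 ubi_guarantee = ubi_guarantee, ubi_clawback = ubi_clawback),
            class = "md_schedule")
}

#' @rdname intervention_schedule
#' @param ... Overrides passed to [intervention_schedule()].
#' @export
min_wage_schedule <- function(...) intervention_schedule("min_wage", ...)

#' @rdname intervention_schedule
#' @export
ccb_schedule <- function(...) {
  intervention_schedule("child_benefit", benefit_max = 6639,
                        phaseout_start = 31120, phaseout_rate = 0.07, ...)
}

#' @rdname intervention_schedule
#' @export
acb_schedule <- function(...) {
  intervention_schedule("child_benefit", benefit_max = 1128,
                        phaseout_start = 26141, phaseout_rate = 0.075, ...)
}

#' @rdname intervention_schedule
#' @export
ubi_schedule <- function(...) intervention_schedule("ubi", ...)

#' Wage floor at a simulation step
#'
#' Linear interpolation between the start and end wage; step 0 is the
#' starting wage and step `n_steps` is exactly the end wage.
#'
#' @param schedule An [intervention_schedule()].
#' @param step Integer in `0..n_steps`.
#' @return Hourly wage (CAD/h).
#' @export
wage_at_step <- function(schedule, step) {
  if (any(step < 0 | step > schedule$n_steps))
    stop("step out of range [0, ", schedule$n_steps, "]")
  schedule$wage_start +
    step * (schedule$wage_end - schedule$wage_start) / schedule$n_steps
}

#' Apply a wage floor to annual income
#'
#' @param income Annual income (CAD/yr, nonnegative).
#' @param wage Hourly wage (CAD/h).
#' @param schedule An [intervention_schedule()] supplying hours and weeks.
#' @return `max(income, wage * hours_per_week * weeks_per_year)`,
#'   elementwise; incomes above the floor are unchanged.
#' @export
wage_floor_income <- function(income, wage, schedule) {
  stopifnot(all(income >= 0))
  pmax(income, wage * schedule$hours_per_week * schedule$weeks_per_year)
}

#' Child-benefit amount
#'
#' Full `benefit_max` below the phase-out start, then a linear reduction
#' with a floor at zero.
#'
#' @param income Annual income (CAD/yr).
#' @param schedule An [intervention_schedule()].
#' @return Annual benefit (CAD/yr), to be added to household income.
#' @export
child_benefit <- function(income, schedule) {
  stopifnot(all(income >= 0), schedule$benefit_max > 0)
  pmax(0, schedule$benefit_max -
         schedule$phaseout_rate * pmax(0, income - schedule$phaseout_start))
}

#' Basic-income top-up
#'
#' `max(0, guarantee - clawback * income)`: the full guarantee at zero
#' income, diminishing with income, zero at or above
#' `guarantee / clawback`.
#'
#' @param income Annual income (CAD/yr).
#' @param schedule An [intervention_schedule()].
#' @return Annual top-up (CAD/yr).
#' @export
ubi_topup <- function(income, schedule) {
  stopifnot(all(income >= 0))
  pmax(0, schedule$ubi_guarantee - schedule$ubi_clawback * income)
}

#' Apply an intervention to a cohort
#'
#' Sets `household_income` to the schedule's transformation of
#' `household_income_baseline` (never of the current income, so repeated
#' application cannot compound benefits).  If the baseline column is
#' missing it is created from the current income first.
#'
#' @param agents Agent data frame.
#' @param schedule An [intervention_schedule()].
#' @param step Simulation step (only relevant for `min_wage`).
#' @return `agents` with updated `household_income` (and
#'   `household_income_baseline` guaranteed present).
#' @export
apply_intervention <- function(agents, schedule, step = schedule$n_steps) {
  if (!inherits(schedule, "md_schedule")) stop("unknown schedule")
  if (is.null(agents$household_income_baseline))
    agents$household_income_baseline <- agents$household_income
  base <- agents$household_income_baseline
  agents$household_income <- switch(
    schedule$kind,
    none = base,
    min_wage = wage_floor_income(base, wage_at_step(schedule, step), schedule),
    child_benefit = base + child_benefit(base, schedule),
    ubi = base + ubi_topup(base, schedule),
    stop("unknown intervention kind: ", schedule$kind)
  )
  agents
}

#' Gini coefficient
#'
#' Mean absolute pairwise income difference scaled by twice the mean, via
#' the O(n log n) sorted formulation.  Used to verify that every
#' intervention weakly reduces inequality.
#'
#' @param x Nonnegative numeric vector with positive mean.
#' @return Gini coefficient in \[0,1\].
#' @export
gini <- function(x) {
  stopifnot(length(x) > 0, all(x >= 0), mean(x) > 0)
  n <- length(x)
  xs <- sort(x)
  (2 * sum(seq_len(n) * xs)) / (n * sum(xs)) - (n + 1) / n
}
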
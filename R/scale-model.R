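#' Stay ratio of a cohort
#'
#' The economy-of-scale throughput ratio: number of surgeries divided by the
#' total number of admission days those surgeries generated, i.e. the
#' reciprocal of the mean stay. A value of 1 means every case was discharged
#' after one day (the ideal for minimally invasive surgery); the closer to
#' zero, the fewer procedures can be scheduled without pushing the mean stay
#' above one day.
#'
#' The ratio is reported rounded to two decimals, which is the precision at
#' which it enters capacity arithmetic; the unrounded value is kept in
#' `raw`.
#'
#' @param records A patient-record table for one arm.
#' @return A `stay_ratio` object with fields `value` (2 dp), `raw`, `source`.
#' @examples
#' # 4 surgeries totalling 10 admission days -> 0.40
#' cohort <- generate_cohort(cohort_config(seed = 1))
#' stay_ratio(cohort[cohort$arm == "LPS", ])
#' @export
stay_ratio <- function(records) {
  records <- validate_records(records)
  total_days <- sum(records$stay_days)
  if (total_days <= 0) {
    stop_endocost("total stay days is zero; ratio undefined", "endocost_ratio_error")
  }
  raw <- nrow(records) / total_days
  new_stay_ratio(round(raw, 2), raw = raw, source = "computed_from_records")
}

#' Use a reported stay ratio verbatim
#'
#' Wraps an externally reported ratio (for instance one printed in a source
#' table) so capacity arithmetic can reproduce published figures exactly,
#' bypassing recomputation from records.
#'
#' @param value Ratio in (0, 1].
#' @return A `stay_ratio` object with `source = "reported_override"`.
#' @examples
#' stay_ratio_override(0.88)
#' @export
stay_ratio_override <- function(value) {
  new_stay_ratio(value, raw = value, source = "reported_override")
}

new_stay_ratio <- function(value, raw, source) {
  if (!is.numeric(value) || length(value) != 1L || !is.finite(value) ||
      value <= 0 || value > 1) {
    stop_endocost("stay ratio must lie in (0, 1]", "endocost_ratio_error")
  }
  structure(list(value = value, raw = raw, source = source), class = "stay_ratio")
}

#' @export
print.stay_ratio <- function(x, ...) {
  cat(sprintf("<stay_ratio> %.2f (raw %.4f, %s)\n", x$value, x$raw, x$source))
  invisible(x)
}

#' Theatre-session scenario
#'
#' A scheduling plan: `k` procedures per surgical session, `S` sessions per
#' year and an amortization horizon of `Y` years. The defaults, 300 sessions
#' per year over 10 years, describe a best-case single-theatre plan
#' (discounting holidays and non-working days) matched to the usual 10-year
#' equipment depreciation life.
#'
#' @param procedures_per_session Procedures scheduled per session (k >= 1).
#' @param sessions_per_year Sessions per year (default 300).
#' @param amortization_years Amortization horizon in years (default 10).
#' @return A `scale_scenario` object.
#' @examples
#' scale_scenario(2)
#' @export
scale_scenario <- function(procedures_per_session,
                           sessions_per_year = 300,
                           amortization_years = 10) {
  k <- procedures_per_session
  if (!is.numeric(k) || length(k) != 1L || k < 1 ||
      !is.numeric(sessions_per_year) || sessions_per_year < 1 ||
      !is.numeric(amortization_years) || amortization_years < 1) {
    stop_endocost("scenario counts must all be at least 1", "endocost_config_error")
  }
  structure(
    list(
      procedures_per_session = as.integer(k),
      sessions_per_year = as.integer(sessions_per_year),
      amortization_years = as.integer(amortization_years)
    ),
    class = "scale_scenario"
  )
}

#' Ratio-limited surgical capacity
#'
#' The number of procedures a session plan supports without the arm's mean
#' stay exceeding one day: annual capacity is sessions x procedures-per-session
#' x stay ratio, rounded to the nearest whole procedure; total capacity is
#' annual capacity times the amortization years, exactly.
#'
#' @param ratio A [stay_ratio()] (its 2-dp `value` is used).
#' @param scenario A [scale_scenario()].
#' @return A list with `annual` and `total` procedure counts.
#' @examples
#' capacity(stay_ratio_override(0.59), scale_scenario(1)) # 177 / 1770
#' @export
capacity <- function(ratio, scenario) {
  stopifnot(inherits(ratio, "stay_ratio"), inherits(scenario, "scale_scenario"))
  annual <- round(scenario$sessions_per_year * scenario$procedures_per_session * ratio$value)
  list(annual = annual, total = annual * scenario$amortization_years)
}

#' Per-procedure cost with equipment amortized over a model capacity
#'
#' Re-prices a procedure when the equipment purchase is spread over the
#' capacity a session plan supports, instead of the nominal depreciation
#' horizon: theatre mean + consumables mean + stay mean + price / capacity.
#' Larger capacities dilute the equipment share, which is the entire
#' economy-of-scale effect (theatre, consumables and stay means are held
#' fixed).
#'
#' The stay component defaults to the arm's observed mean stay cost
#' (`stay_policy = "observed"`). `"fixed_one_day"` instead bills exactly one
#' day at the stay rate, the literal reading of a one-day-stay target.
#'
#' @param summary An [arm_cost_summary()].
#' @param spec The arm's [equipment_spec()].
#' @param total_capacity Procedures over the amortization period (>= 1).
#' @param stay_policy `"observed"` (default) or `"fixed_one_day"`.
#' @param rates A [cost_rates()]; only used by `"fixed_one_day"`.
#' @return The adjusted per-procedure cost (currency).
#' @examples
#' rbt <- arm_cost_summary(
#'   "RBT", 78,
#'   means = c(theatre = 2227, consumables = 2057, equipment = 2000, stay = 768)
#' )
#' ratio_adjusted_cost(rbt, equipment_spec("robotic platform", 2e6), 2640)
#' @export
ratio_adjusted_cost <- function(summary, spec, total_capacity,
                                stay_policy = c("observed", "fixed_one_day"),
                                rates = cost_rates()) {
  stopifnot(inherits(summary, "arm_cost_summary"), inherits(spec, "equipment_spec"))
  stay_policy <- match.arg(stay_policy)
  if (!is.numeric(total_capacity) || length(total_capacity) != 1L || total_capacity < 1) {
    stop_endocost("`total_capacity` must be a count of at least 1", "endocost_config_error")
  }
  stay_component <- switch(stay_policy,
    observed = summary$mean[["stay"]],
    fixed_one_day = rates$stay_rate
  )
  summary$mean[["theatre"]] + summary$mean[["consumables"]] + stay_component +
    spec$purchase_price / total_capacity
}

#' Compare arms across session-plan models
#'
#' Builds the full economy-of-scale comparison: for each scenario (by default
#' one, two and three procedures per session over 300 sessions/year and 10
#' years), the ratio-limited capacity and the capacity-adjusted cost of each
#' arm, the robotic cost overrun (robotic minus laparoscopic adjusted cost),
#' the overrun as a percentage of the robotic cost, and the extra procedures
#' the robotic arm's better stay ratio buys.
#'
#' @param lps,rbt [arm_cost_summary()] objects for the laparoscopic and
#'   robotic arms (in that order).
#' @param lps_spec,rbt_spec The arms' [equipment_spec()]s.
#' @param lps_ratio,rbt_ratio The arms' [stay_ratio()]s.
#' @param scenarios List of [scale_scenario()]s; default k = 1, 2, 3.
#' @param stay_policy Passed to [ratio_adjusted_cost()].
#' @return A tibble with one row per (model, arm): `model`, `arm`,
#'   `annual_capacity`, `total_capacity`, `adjusted_cost`, and the per-model
#'   comparison columns `overrun`, `overrun_pct`, `capacity_increase_annual`,
#'   `capacity_increase_total` (repeated on both rows of a model).
#' @examples
#' lps <- arm_cost_summary("LPS", 75,
#'   means = c(theatre = 2356, consumables = 1047, equipment = 140, stay = 1153))
#' rbt <- arm_cost_summary("RBT", 78,
#'   means = c(theatre = 2227, consumables = 2057, equipment = 2000, stay = 768))
#' compare_models(lps, rbt,
#'   equipment_spec("laparoscopic tower", 140000),
#'   equipment_spec("robotic platform", 2e6),
#'   stay_ratio_override(0.59), stay_ratio_override(0.88))
#' @export
compare_models <- function(lps, rbt, lps_spec, rbt_spec, lps_ratio, rbt_ratio,
                           scenarios = lapply(1:3, scale_scenario),
                           stay_policy = "observed") {
  stopifnot(inherits(lps, "arm_cost_summary"), inherits(rbt, "arm_cost_summary"))
  if (lps$arm == rbt$arm) {
    stop_endocost("`lps` and `rbt` summaries must describe different arms",
                  "endocost_record_error")
  }
  if (lps$arm != "LPS" || rbt$arm != "RBT") {
    stop_endocost("pass the laparoscopic summary first and the robotic second",
                  "endocost_record_error")
  }
  rows <- lapply(scenarios, function(sc) {
    cap_l <- capacity(lps_ratio, sc)
    cap_r <- capacity(rbt_ratio, sc)
    cost_l <- ratio_adjusted_cost(lps, lps_spec, cap_l$total, stay_policy)
    cost_r <- ratio_adjusted_cost(rbt, rbt_spec, cap_r$total, stay_policy)
    overrun <- cost_r - cost_l
    tibble::tibble(
      model = sc$procedures_per_session,
      arm = ARM_LEVELS,
      annual_capacity = c(cap_l$annual, cap_r$annual),
      total_capacity = c(cap_l$total, cap_r$total),
      adjusted_cost = c(cost_l, cost_r),
      overrun = overrun,
      overrun_pct = 100 * overrun / cost_r,
      capacity_increase_annual = cap_r$annual - cap_l$annual,
      capacity_increase_total = cap_r$total - cap_l$total
    )
  })
  do.call(rbind, rows)
}
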
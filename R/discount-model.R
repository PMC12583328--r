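#' Discount scenario for the robotic arm
#'
#' Fractional price reductions applied to the robotic platform purchase
#' price (before amortization) and to the per-procedure consumables mean.
#' Theatre and stay costs are never discounted; the negotiable levers in
#' equipment procurement are the platform price and the instrument
#' consumables.
#'
#' @param equipment_discount Fraction in `[0, 1)` off the purchase price.
#' @param consumables_discount Fraction in `[0, 1)` off the consumables mean.
#' @return A `discount_scenario` object.
#' @examples
#' discount_scenario(0.10, 0.35)
#' @export
discount_scenario <- function(equipment_discount = 0, consumables_discount = 0) {
  for (d in c(equipment_discount, consumables_discount)) {
    if (!is.numeric(d) || length(d) != 1L || !is.finite(d) || d < 0 || d >= 1) {
      stop_endocost("discount fractions must lie in [0, 1)", "endocost_config_error")
    }
  }
  structure(
    list(
      equipment_discount = equipment_discount,
      consumables_discount = consumables_discount
    ),
    class = "discount_scenario"
  )
}

#' Discounted robotic cost per procedure
#'
#' The capacity-adjusted robotic cost under a discount scenario:
#' theatre mean + consumables mean x (1 - d_c) + stay mean +
#' price x (1 - d_e) / capacity. Affine and strictly decreasing in each
#' discount; with both discounts zero it equals [ratio_adjusted_cost()].
#'
#' @param summary The robotic [arm_cost_summary()].
#' @param spec The robotic [equipment_spec()].
#' @param total_capacity Procedures over the amortization period.
#' @param scenario A [discount_scenario()].
#' @param stay_policy,rates Passed through as in [ratio_adjusted_cost()].
#' @return Discounted per-procedure cost (currency).
#' @examples
#' rbt <- arm_cost_summary("RBT", 78,
#'   means = c(theatre = 2227, consumables = 2057, equipment = 2000, stay = 768))
#' discounted_cost(rbt, equipment_spec("robotic platform", 2e6), 7920,
#'                 discount_scenario(0.10, 0.35))
#' @export
discounted_cost <- function(summary, spec, total_capacity,
                            scenario = discount_scenario(),
                            stay_policy = c("observed", "fixed_one_day"),
                            rates = cost_rates()) {
  stopifnot(inherits(summary, "arm_cost_summary"), inherits(spec, "equipment_spec"),
            inherits(scenario, "discount_scenario"))
  stay_policy <- match.arg(stay_policy)
  if (!is.numeric(total_capacity) || length(total_capacity) != 1L || total_capacity < 1) {
    stop_endocost("`total_capacity` must be a count of at least 1", "endocost_config_error")
  }
  stay_component <- switch(stay_policy,
    observed = summary$mean[["stay"]],
    fixed_one_day = rates$stay_rate
  )
  summary$mean[["theatre"]] +
    summary$mean[["consumables"]] * (1 - scenario$consumables_discount) +
    stay_component +
    spec$purchase_price * (1 - scenario$equipment_discount) / total_capacity
}

#' Discount-scenario grid across session-plan models
#'
#' Evaluates every combination of session-plan model, equipment discount and
#' consumables discount, comparing the discounted robotic cost against the
#' model's own laparoscopic reference cost. The default grid is equipment
#' discounts of 0/10/15/20 % crossed with consumables discounts of 30/35 %.
#'
#' @inheritParams compare_models
#' @param equipment_discounts Numeric vector of equipment discount fractions.
#' @param consumables_discounts Numeric vector of consumables discount
#'   fractions.
#' @return A tibble with one row per (model, equipment discount, consumables
#'   discount): the discounted robotic cost, the model's laparoscopic cost,
#'   their difference (robotic minus laparoscopic) and a `converged` flag
#'   (robotic <= laparoscopic).
#' @export
scenario_grid <- function(lps, rbt, lps_spec, rbt_spec, lps_ratio, rbt_ratio,
                          scenarios = lapply(1:3, scale_scenario),
                          equipment_discounts = c(0, 0.10, 0.15, 0.20),
                          consumables_discounts = c(0.30, 0.35),
                          stay_policy = "observed") {
  if (!length(equipment_discounts) || !length(consumables_discounts)) {
    stop_endocost("discount grids must be non-empty", "endocost_config_error")
  }
  rows <- list()
  for (sc in scenarios) {
    cap_l <- capacity(lps_ratio, sc)
    cap_r <- capacity(rbt_ratio, sc)
    lps_cost <- ratio_adjusted_cost(lps, lps_spec, cap_l$total, stay_policy)
    for (de in equipment_discounts) {
      for (dc in consumables_discounts) {
        rbt_cost <- discounted_cost(
          rbt, rbt_spec, cap_r$total,
          discount_scenario(de, dc), stay_policy
        )
        rows[[length(rows) + 1L]] <- tibble::tibble(
          model = sc$procedures_per_session,
          equipment_discount = de,
          consumables_discount = dc,
          rbt_cost = rbt_cost,
          lps_cost = lps_cost,
          difference = rbt_cost - lps_cost,
          converged = rbt_cost <= lps_cost
        )
      }
    }
  }
  do.call(rbind, rows)
}

#' Break-even consumables discount
#'
#' The smallest consumables discount at which the discounted robotic cost
#' drops to the laparoscopic reference, at a given equipment discount and
#' capacity. Because the cost is affine in the discount there is a closed
#' form: d_c* = (robotic cost at d_c = 0 - laparoscopic cost) / consumables
#' mean. Returns 0 when the robotic arm is already at or below the
#' reference, and `NA` when no admissible discount (d_c < 1) can close the
#' gap.
#'
#' @param summary The robotic [arm_cost_summary()].
#' @param lps_cost The laparoscopic reference cost (currency).
#' @param spec The robotic [equipment_spec()].
#' @param total_capacity Procedures over the amortization period.
#' @param equipment_discount Equipment discount fraction already granted.
#' @param stay_policy,rates Passed through as in [discounted_cost()].
#' @return The break-even fraction in `[0, 1)`, or `NA_real_` if
#'   unreachable.
#' @examples
#' rbt <- arm_cost_summary("RBT", 78,
#'   means = c(theatre = 2227, consumables = 2057, equipment = 2000, stay = 768))
#' break_even_consumables_discount(
#'   rbt, 4583, equipment_spec("robotic platform", 2e6), 7920,
#'   equipment_discount = 0.10
#' )
#' @export
break_even_consumables_discount <- function(summary, lps_cost, spec, total_capacity,
                                            equipment_discount = 0,
                                            stay_policy = "observed",
                                            rates = cost_rates()) {
  stopifnot(inherits(summary, "arm_cost_summary"))
  cons_mean <- summary$mean[["consumables"]]
  if (!is.finite(cons_mean) || cons_mean <= 0) {
    stop_endocost("consumables mean must be positive for a break-even discount",
                  "endocost_config_error")
  }
  base <- discounted_cost(
    summary, spec, total_capacity,
    discount_scenario(equipment_discount, 0), stay_policy, rates
  )
  d_star <- (base - lps_cost) / cons_mean
  if (d_star <= 0) return(0)
  if (d_star >= 1) return(NA_real_)
  d_star
}

#' Convert extended instrument life into an equivalent consumables discount
#'
#' Limited-use robotic instruments enter the consumables cost at unit price
#' divided by licensed uses. Extending the licensed uses from `current_uses`
#' to `increased_uses` lowers the per-use price by the factor
#' current/increased, i.e. it acts exactly like a consumables discount of
#' 1 - current_uses / increased_uses. This helper expresses the
#' instrument-lifespan lever on the discount scale so the same scenario
#' machinery covers both.
#'
#' @param current_uses Licensed uses per instrument today (>= 1).
#' @param increased_uses Proposed licensed uses (> `current_uses`).
#' @return The equivalent consumables discount fraction in (0, 1).
#' @examples
#' uses_discount_equivalent(10, 15) # one-third off the per-use price
#' @export
uses_discount_equivalent <- function(current_uses, increased_uses) {
  if (!is.numeric(current_uses) || !is.numeric(increased_uses) ||
      current_uses < 1 || increased_uses <= current_uses) {
    stop_endocost("`increased_uses` must exceed `current_uses` (both >= 1)",
                  "endocost_config_error")
  }
  1 - current_uses / increased_uses
}
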
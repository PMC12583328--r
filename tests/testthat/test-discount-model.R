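test_that("discounting is affine, component-wise, and the identity at zero", {
  rbt <- published_rbt()
  # no discount reproduces the capacity-adjusted cost
  expect_equal(
    discounted_cost(rbt, rbt_spec(), 2640, discount_scenario(0, 0)),
    ratio_adjusted_cost(rbt, rbt_spec(), 2640)
  )

  # random scenarios against a component-sum oracle
  set.seed(31)
  for (i in 1:20) {
    de <- runif(1, 0, 0.9)
    dc <- runif(1, 0, 0.9)
    cap <- sample(1000:9000, 1)
    oracle <- 2227 + 2057 * (1 - dc) + 768 + 2e6 * (1 - de) / cap
    expect_equal(
      discounted_cost(rbt, rbt_spec(), cap, discount_scenario(de, dc)),
      oracle
    )
  }

  # strictly decreasing in each discount
  base <- discounted_cost(rbt, rbt_spec(), 2640, discount_scenario(0.1, 0.1))
  expect_lt(discounted_cost(rbt, rbt_spec(), 2640, discount_scenario(0.2, 0.1)), base)
  expect_lt(discounted_cost(rbt, rbt_spec(), 2640, discount_scenario(0.1, 0.2)), base)

  expect_error(discount_scenario(1), class = "endocost_config_error")
  expect_error(discount_scenario(-0.1), class = "endocost_config_error")
})

test_that("a 10% equipment and 35% consumables discount undercuts laparoscopy at three per session", {
  lps_cost_m3 <- ratio_adjusted_cost(published_lps(), lps_spec(), 5310)
  rbt_cost <- discounted_cost(
    published_rbt(), rbt_spec(), 7920, discount_scenario(0.10, 0.35)
  )
  expect_equal(rbt_cost, 2227 + 2057 * 0.65 + 768 + 1800000 / 7920)
  expect_lte(rbt_cost, lps_cost_m3)
})

test_that("the scenario grid covers the model x discount cross with coherent flags", {
  grid <- scenario_grid(
    published_lps(), published_rbt(), lps_spec(), rbt_spec(),
    stay_ratio_override(0.59), stay_ratio_override(0.88)
  )
  expect_equal(nrow(grid), 24L) # 3 models x 4 equipment x 2 consumable discounts
  expect_equal(grid$converged, grid$difference <= 0)
  expect_equal(grid$difference, grid$rbt_cost - grid$lps_cost)

  # one procedure per session never converges under the default discounts
  expect_false(any(grid$converged[grid$model == 1]))

  # convergence is monotone in procedures per session (equipment dilution)
  by_scenario <- split(grid, list(grid$equipment_discount, grid$consumables_discount))
  for (g in by_scenario) {
    g <- g[order(g$model), ]
    expect_true(all(diff(as.integer(g$converged)) >= 0))
  }

  expect_error(
    scenario_grid(published_lps(), published_rbt(), lps_spec(), rbt_spec(),
                  stay_ratio_override(0.59), stay_ratio_override(0.88),
                  equipment_discounts = numeric(0)),
    class = "endocost_config_error"
  )
})

test_that("closed-form break-even matches a grid search at 1e-4 resolution", {
  rbt <- published_rbt()
  grid_search <- function(lps_cost, cap, de) {
    dcs <- seq(0, 0.9999, by = 1e-4)
    costs <- vapply(
      dcs,
      function(dc) discounted_cost(rbt, rbt_spec(), cap, discount_scenario(de, dc)),
      numeric(1)
    )
    hit <- which(costs <= lps_cost)
    if (!length(hit)) NA_real_ else dcs[hit[[1]]]
  }
  cases <- list(
    list(cap = 7920, lps = ratio_adjusted_cost(published_lps(), lps_spec(), 5310), de = 0.10),
    list(cap = 2640, lps = ratio_adjusted_cost(published_lps(), lps_spec(), 1770), de = 0),
    list(cap = 5280, lps = ratio_adjusted_cost(published_lps(), lps_spec(), 3540), de = 0.20)
  )
  for (cs in cases) {
    closed <- break_even_consumables_discount(rbt, cs$lps, rbt_spec(), cs$cap, cs$de)
    expect_lt(abs(closed - grid_search(cs$lps, cs$cap, cs$de)), 1e-4 + 1e-9)
  }
  # one procedure per session needs a discount above the negotiated 30-35% band
  m1 <- break_even_consumables_discount(
    rbt, ratio_adjusted_cost(published_lps(), lps_spec(), 1770), rbt_spec(), 2640, 0
  )
  expect_gt(m1, 0.35)
})

test_that("break-even saturates at zero and signals unreachable gaps", {
  rbt <- published_rbt()
  # already cheaper than the reference: no discount needed
  expect_equal(
    break_even_consumables_discount(rbt, 1e6, rbt_spec(), 2640), 0
  )
  # gap larger than the whole consumables budget: unreachable
  expect_true(is.na(
    break_even_consumables_discount(rbt, 100, rbt_spec(), 2640)
  ))
  no_cons <- arm_cost_summary("RBT", 10,
    means = c(theatre = 2227, consumables = 0, equipment = 2000, stay = 768))
  expect_error(
    break_even_consumables_discount(no_cons, 4000, rbt_spec(), 2640),
    class = "endocost_config_error"
  )
})

test_that("extending instrument uses maps onto the discount scale", {
  expect_equal(uses_discount_equivalent(10, 15), 1 - 10 / 15)
  # pricing an instrument at unit price / uses, more uses = discounted per-use cost
  unit_price <- 3000
  per_use_now <- unit_price / 12
  per_use_extended <- unit_price / 18
  expect_equal(per_use_now * (1 - uses_discount_equivalent(12, 18)), per_use_extended)
  expect_error(uses_discount_equivalent(10, 10), class = "endocost_config_error")
})
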
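test_that("component costs follow the per-minute, per-day and amortization rules", {
  rates <- cost_rates()

  # theatre: minutes x 14.65, linear through the origin
  expect_equal(theatre_cost(161, rates), 2358.65)
  expect_equal(theatre_cost(152, rates), 2226.80)
  expect_lt(theatre_cost(1e-4, rates), 1e-2)

  # stay: days x 681, zero days costs zero
  expect_equal(stay_cost(1.7, rates), 1157.7)
  expect_equal(stay_cost(1, rates), 681)
  expect_equal(stay_cost(0, rates), 0)

  # equipment: price / depreciation horizon
  expect_equal(equipment_share(rbt_spec()), 2000)
  expect_equal(equipment_share(lps_spec()), 140)
  expect_equal(equipment_share(equipment_spec("x", 12345, 1)), 12345)

  expect_error(theatre_cost(0, rates), class = "endocost_record_error")
  expect_error(stay_cost(-1, rates), class = "endocost_record_error")
  expect_error(equipment_spec("x", 1000, 0), class = "endocost_config_error")
  expect_error(cost_rates(theatre_rate = -1), class = "endocost_config_error")
})

test_that("procedure totals are the exact sum of the four components", {
  rates <- cost_rates()
  # a robotic case sitting exactly at the published component means
  rec <- make_records(
    arm = "RBT", theatre_minutes = 2227 / 14.65, stay_days = 768 / 681,
    consumables_cost = 2057
  )
  cost <- procedure_cost(rec, rates, rbt_spec())
  expect_equal(cost$total, 7052)

  # minimal record: 1 theatre minute, nothing else but the equipment share
  tiny <- make_records(theatre_minutes = 1, stay_days = 0, consumables_cost = 0)
  expect_equal(procedure_cost(tiny, rates, lps_spec())$total, 14.65 + 140)

  # brute-force re-summation oracle on random records
  set.seed(101)
  for (i in 1:5) {
    recs <- random_records(40)
    costs <- procedure_cost(recs, rates, lps_spec())
    resum <- costs$theatre_cost + costs$consumables_cost +
      costs$equipment_share + costs$stay_cost
    expect_equal(costs$total, resum)
    expect_equal(costs$theatre_cost, recs$theatre_minutes * 14.65)
    expect_equal(costs$stay_cost, recs$stay_days * 681)
  }
})

test_that("doubling the theatre rate doubles only the theatre component", {
  set.seed(7)
  recs <- random_records(20)
  base <- procedure_cost(recs, cost_rates(), lps_spec())
  doubled <- procedure_cost(recs, cost_rates(theatre_rate = 2 * 14.65), lps_spec())
  expect_equal(doubled$theatre_cost, 2 * base$theatre_cost)
  expect_equal(doubled$consumables_cost, base$consumables_cost)
  expect_equal(doubled$equipment_share, base$equipment_share)
  expect_equal(doubled$stay_cost, base$stay_cost)
})

test_that("arm summaries report n-1 moments, constant equipment and unit shares", {
  rates <- cost_rates()

  single <- summarize_arm(make_records(), rates, lps_spec())
  expect_equal(single$n, 1L)
  expect_equal(unname(single$sd), rep(0, 5))
  expect_equal(single$mean[["theatre"]], 150 * 14.65)
  expect_equal(sum(single$cost_shares), 1, tolerance = 1e-12)

  set.seed(11)
  recs <- random_records(50, arm = "RBT")
  summ <- summarize_arm(recs, rates, rbt_spec())
  expect_equal(summ$sd[["equipment"]], 0)
  expect_equal(summ$mean[["consumables"]], mean(recs$consumables_cost))
  expect_equal(summ$sd[["stay"]], sd(recs$stay_days * 681))
  expect_equal(sum(summ$cost_shares), 1, tolerance = 1e-9)

  # permutation invariance
  shuffled <- summarize_arm(recs[sample(nrow(recs)), ], rates, rbt_spec())
  expect_equal(summ$mean, shuffled$mean)
  expect_equal(summ$sd, shuffled$sd)

  mixed <- rbind(make_records(arm = "LPS"), make_records(arm = "RBT"))
  expect_error(summarize_arm(mixed, rates, lps_spec()), class = "endocost_record_error")
  expect_error(
    summarize_arm(make_records()[0, ], rates, lps_spec()),
    class = "endocost_empty_error"
  )
})

test_that("large synthetic laparoscopic arms recover the published consumables mean", {
  # 2-SE coverage check across independent cohorts: a sample mean at
  # n = 10,000 should land within 2 SE of the target in about 95% of draws
  params <- lps_default_params()
  params$n <- 10000L
  se <- 314 / sqrt(10000)
  inside <- 0L
  for (s in 1:10) {
    cohort <- generate_cohort(cohort_config(lps = params, seed = 600L + s))
    summ <- summarize_arm(cohort[cohort$arm == "LPS", ], cost_rates(), lps_spec())
    # +0.5: deterministic upward shift from truncating the normal at zero
    if (abs(summ$mean[["consumables"]] - 1047 - 0.5) < 2 * se) inside <- inside + 1L
  }
  expect_gte(inside, 8L)
})

test_that("cost shares render as percentages summing to 100", {
  shares <- render_cost_shares(published_rbt())
  expect_equal(sum(shares$share_pct), 100, tolerance = 1e-9)
  expect_equal(shares$share_pct[shares$component == "equipment"],
               100 * 2000 / 7052, tolerance = 1e-9)
  # single-component cost vector gets the whole share
  lone <- arm_cost_summary("LPS", 5,
    means = c(theatre = 900, consumables = 0, equipment = 0, stay = 0))
  expect_equal(render_cost_shares(lone)$share_pct, c(100, 0, 0, 0))
  # shares invariant to currency rescaling
  scaled <- arm_cost_summary("RBT", 78,
    means = published_rbt()$mean[c("theatre", "consumables", "equipment", "stay")] * 100)
  expect_equal(render_cost_shares(scaled)$share_pct, shares$share_pct)
})
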
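# Fixtures built in code: record tables, the two equipment specs, and the
# published arm summaries pulled from the bundled parameter file.

make_records <- function(arm = "LPS", theatre_minutes = 150, stay_days = 1,
                         consumables_cost = 1000, complexity_group = "B",
                         age = 65, bmi = 29, complication_flag = FALSE) {
  tibble::tibble(
    arm = arm, theatre_minutes = theatre_minutes, stay_days = stay_days,
    consumables_cost = consumables_cost, complexity_group = complexity_group,
    age = age, bmi = bmi, complication_flag = complication_flag
  )
}

random_records <- function(n, arm = "LPS") {
  make_records(
    arm = arm,
    theatre_minutes = runif(n, 60, 300),
    stay_days = sample(0:6, n, replace = TRUE),
    consumables_cost = runif(n, 200, 3000),
    complexity_group = sample(c("A", "B", "C"), n, replace = TRUE),
    age = runif(n, 40, 85),
    bmi = runif(n, 18, 45),
    complication_flag = runif(n) < 0.05
  )
}

lps_spec <- function() equipment_spec("laparoscopic tower", 140000)
rbt_spec <- function() equipment_spec("robotic platform", 2e6)

study_config <- local({
  cfg <- NULL
  function() {
    if (is.null(cfg)) cfg <<- read_econ_config(default_config_path())
    cfg
  }
})

published_lps <- function() study_config()$reported_summaries$LPS
published_rbt <- function() study_config()$reported_summaries$RBT
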
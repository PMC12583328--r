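#' Facility billing rates
#'
#' Bundles the two per-unit facility rates used to cost a procedure: the
#' operating-theatre rate (per minute of theatre occupation, covering facility
#' use, the full surgical/anaesthetic team and intra-operative medication) and
#' the hospital-stay rate (per admission day, covering room, meals and
#' post-operative care). Defaults are the study centre's 2022-2024 pre-tax
#' rates in euros.
#'
#' @param theatre_rate Cost per theatre minute (currency/min). Must be > 0.
#' @param stay_rate Cost per admission day (currency/day). Must be > 0.
#' @return A `cost_rates` object (a validated list).
#' @examples
#' cost_rates()
#' cost_rates(theatre_rate = 12, stay_rate = 500)
#' @export
cost_rates <- function(theatre_rate = 14.65, stay_rate = 681) {
  if (!is.numeric(theatre_rate) || length(theatre_rate) != 1L || !is.finite(theatre_rate) ||
      theatre_rate <= 0) {
    stop_endocost("`theatre_rate` must be a single positive number", "endocost_config_error")
  }
  if (!is.numeric(stay_rate) || length(stay_rate) != 1L || !is.finite(stay_rate) ||
      stay_rate <= 0) {
    stop_endocost("`stay_rate` must be a single positive number", "endocost_config_error")
  }
  structure(
    list(theatre_rate = as.numeric(theatre_rate), stay_rate = as.numeric(stay_rate)),
    class = "cost_rates"
  )
}

#' @export
print.cost_rates <- function(x, ...) {
  cat(sprintf(
    "<cost_rates> theatre %.2f/min, stay %.2f/day\n",
    x$theatre_rate, x$stay_rate
  ))
  invisible(x)
}

#' Capital equipment specification
#'
#' Describes one inventoriable equipment purchase (a laparoscopic tower or a
#' robotic platform) and the straight-line depreciation horizon, expressed as
#' a number of procedures, over which its price is spread. Annual maintenance
#' may be recorded as an additive yearly cost; it defaults to 0 and is not
#' part of the per-procedure depreciation share.
#'
#' @param label Short name, e.g. `"laparoscopic tower"`.
#' @param purchase_price Purchase price (currency, pre-tax). Must be > 0.
#' @param depreciation_procedures Number of procedures over the depreciation
#'   life (default 1000: ten years at about one hundred procedures per year).
#' @param annual_maintenance Optional annual maintenance cost (default 0).
#' @return An `equipment_spec` object.
#' @examples
#' equipment_spec("laparoscopic tower", 140000)
#' equipment_spec("robotic platform", 2e6)
#' @export
equipment_spec <- function(label, purchase_price,
                           depreciation_procedures = 1000,
                           annual_maintenance = 0) {
  if (!is.character(label) || length(label) != 1L) {
    stop_endocost("`label` must be a single string", "endocost_config_error")
  }
  if (!is.numeric(purchase_price) || length(purchase_price) != 1L ||
      !is.finite(purchase_price) || purchase_price <= 0) {
    stop_endocost("`purchase_price` must be a single positive number", "endocost_config_error")
  }
  if (!is.numeric(depreciation_procedures) || length(depreciation_procedures) != 1L ||
      !is.finite(depreciation_procedures) || depreciation_procedures < 1) {
    stop_endocost(
      "`depreciation_procedures` must be a count of at least 1",
      "endocost_config_error"
    )
  }
  if (!is.numeric(annual_maintenance) || length(annual_maintenance) != 1L ||
      !is.finite(annual_maintenance) || annual_maintenance < 0) {
    stop_endocost("`annual_maintenance` must be a non-negative number", "endocost_config_error")
  }
  structure(
    list(
      label = label,
      purchase_price = as.numeric(purchase_price),
      depreciation_procedures = as.numeric(depreciation_procedures),
      annual_maintenance = as.numeric(annual_maintenance)
    ),
    class = "equipment_spec"
  )
}

#' @export
print.equipment_spec <- function(x, ...) {
  cat(sprintf(
    "<equipment_spec> %s: price %.0f over %d procedures (share %.2f per procedure)\n",
    x$label, x$purchase_price, as.integer(x$depreciation_procedures),
    equipment_share(x)
  ))
  invisible(x)
}

#' Validate a patient-record table
#'
#' Checks that a cohort table carries the expected columns with admissible
#' values: `arm` in `{LPS, RBT}`, strictly positive `theatre_minutes`
#' (total theatre occupation, including field preparation and docking),
#' non-negative integer-valued `stay_days`, non-negative `consumables_cost`
#' (limited-use instruments already prorated to a per-use price),
#' `complexity_group` in `{A, B, C}`, plus `age`, `bmi` and a logical
#' `complication_flag`.
#'
#' @param records A data frame of patient records.
#' @return The records as a tibble, invisibly validated (errors otherwise).
#' @export
validate_records <- function(records) {
  required <- c(
    "arm", "theatre_minutes", "stay_days", "consumables_cost",
    "complexity_group", "age", "bmi", "complication_flag"
  )
  if (!is.data.frame(records)) {
    stop_endocost("`records` must be a data frame", "endocost_record_error")
  }
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols)) {
    stop_endocost(
      paste0("records are missing columns: ", paste(missing_cols, collapse = ", ")),
      "endocost_record_error"
    )
  }
  if (nrow(records) == 0L) {
    stop_endocost("records table is empty", "endocost_empty_error")
  }
  records <- tibble::as_tibble(records)
  records$arm <- as.character(records$arm)
  if (!all(records$arm %in% ARM_LEVELS)) {
    stop_endocost("`arm` must be one of 'LPS', 'RBT'", "endocost_record_error")
  }
  if (!all(is.finite(records$theatre_minutes)) || any(records$theatre_minutes <= 0)) {
    stop_endocost("`theatre_minutes` must be strictly positive", "endocost_record_error")
  }
  if (!all(is.finite(records$stay_days)) || any(records$stay_days < 0)) {
    stop_endocost("`stay_days` must be non-negative", "endocost_record_error")
  }
  if (!all(is.finite(records$consumables_cost)) || any(records$consumables_cost < 0)) {
    stop_endocost("`consumables_cost` must be non-negative", "endocost_record_error")
  }
  if (!all(records$complexity_group %in% c("A", "B", "C"))) {
    stop_endocost("`complexity_group` must be one of 'A', 'B', 'C'", "endocost_record_error")
  }
  records$complication_flag <- as.logical(records$complication_flag)
  records
}

#' Theatre cost of a procedure
#'
#' Indirect theatre cost: minutes of theatre occupation times the per-minute
#' rate. Linear through the origin, so there is no fixed per-case theatre fee.
#'
#' @param minutes Theatre occupation in minutes (vectorised, each > 0).
#' @param rates A [cost_rates()] object.
#' @return Theatre cost(s) in currency units.
#' @examples
#' theatre_cost(161, cost_rates()) # 2358.65
#' @export
theatre_cost <- function(minutes, rates = cost_rates()) {
  stopifnot(inherits(rates, "cost_rates"))
  if (!is.numeric(minutes) || !all(is.finite(minutes)) || any(minutes <= 0)) {
    stop_endocost("`minutes` must be strictly positive", "endocost_record_error")
  }
  minutes * rates$theatre_rate
}

#' Hospital-stay cost of a procedure
#'
#' Indirect stay cost: admission days times the per-day rate. Zero days
#' (ambulatory) costs zero.
#'
#' @param days Admission days (vectorised, each >= 0).
#' @param rates A [cost_rates()] object.
#' @return Stay cost(s) in currency units.
#' @examples
#' stay_cost(1.7, cost_rates()) # 1157.7
#' @export
stay_cost <- function(days, rates = cost_rates()) {
  stopifnot(inherits(rates, "cost_rates"))
  if (!is.numeric(days) || !all(is.finite(days)) || any(days < 0)) {
    stop_endocost("`days` must be non-negative", "endocost_record_error")
  }
  days * rates$stay_rate
}

#' Per-procedure equipment depreciation share
#'
#' Straight-line amortization: the purchase price divided by the number of
#' procedures in the depreciation horizon. Constant across records for a
#' fixed specification, which is why its within-arm standard deviation is
#' zero in any cohort summary.
#'
#' @param spec An [equipment_spec()].
#' @param total_procedures Optional override of the depreciation horizon,
#'   e.g. a capacity from the economy-of-scale model; defaults to the
#'   specification's own horizon.
#' @return The per-procedure equipment share in currency units.
#' @examples
#' equipment_share(equipment_spec("robotic platform", 2e6)) # 2000
#' @export
equipment_share <- function(spec, total_procedures = NULL) {
  stopifnot(inherits(spec, "equipment_spec"))
  horizon <- total_procedures %||% spec$depreciation_procedures
  if (!is.numeric(horizon) || length(horizon) != 1L || !is.finite(horizon) || horizon < 1) {
    stop_endocost("depreciation horizon must be a count of at least 1", "endocost_config_error")
  }
  spec$purchase_price / horizon
}

#' Decompose the cost of each procedure
#'
#' Computes, for every record, the four cost components and their total:
#' theatre (minutes x rate), consumables (taken from the record, already
#' per-use-prorated), equipment depreciation share (price / horizon, identical
#' for all records of the arm) and hospital stay (days x rate). The total is
#' the exact sum of the four components at full floating precision; euro
#' rounding happens only when a report is rendered.
#'
#' @param records A patient-record table (see [validate_records()]); all rows
#'   are costed against the same equipment specification, so pass one arm at
#'   a time (or use [summarize_arm()] / [run_pipeline()] for arm handling).
#' @param rates A [cost_rates()] object.
#' @param spec The arm's [equipment_spec()].
#' @return A tibble with one row per record: `arm`, the four component
#'   columns `theatre_cost`, `consumables_cost`, `equipment_share`,
#'   `stay_cost`, and `total`.
#' @examples
#' rec <- tibble::tibble(
#'   arm = "RBT", theatre_minutes = 152, stay_days = 1,
#'   consumables_cost = 2057, complexity_group = "B", age = 65,
#'   bmi = 30, complication_flag = FALSE
#' )
#' procedure_cost(rec, cost_rates(), equipment_spec("robotic platform", 2e6))
#' @export
procedure_cost <- function(records, rates = cost_rates(), spec) {
  records <- validate_records(records)
  stopifnot(inherits(spec, "equipment_spec"))
  theatre <- theatre_cost(records$theatre_minutes, rates)
  stay <- stay_cost(records$stay_days, rates)
  equip <- rep(equipment_share(spec), nrow(records))
  tibble::tibble(
    arm = records$arm,
    theatre_cost = theatre,
    consumables_cost = records$consumables_cost,
    equipment_share = equip,
    stay_cost = stay,
    total = theatre + records$consumables_cost + equip + stay
  )
}

#' Construct an arm cost summary from component moments
#'
#' Builds the per-arm summary object directly from component means and
#' standard deviations. This is the reproduction-mode entry point: published
#' summary tables can be fed straight into the economy-of-scale and discount
#' models without patient-level records. [summarize_arm()] produces the same
#' object from raw records.
#'
#' The total mean defaults to the sum of the four component means; a
#' published total may be supplied to keep a source table's own (differently
#' rounded) figure alongside.
#'
#' @param arm `"LPS"` or `"RBT"`.
#' @param n Number of procedures summarised.
#' @param means Named numeric vector with entries `theatre`, `consumables`,
#'   `equipment`, `stay` (component means, currency).
#' @param sds Like `means`; standard deviations (default all `NA`).
#' @param total_mean,total_sd Optional moments of the per-record total;
#'   `total_mean` defaults to `sum(means)`.
#' @return An `arm_cost_summary` object with fields `arm`, `n`, `mean`, `sd`
#'   (both named vectors over the four components plus `total`) and
#'   `cost_shares` (component mean / total mean, summing to 1).
#' @examples
#' arm_cost_summary(
#'   "RBT", 78,
#'   means = c(theatre = 2227, consumables = 2057, equipment = 2000, stay = 768)
#' )
#' @export
arm_cost_summary <- function(arm, n, means, sds = NULL,
                             total_mean = NULL, total_sd = NA_real_) {
  arm <- match.arg(arm, ARM_LEVELS)
  if (!is.numeric(n) || length(n) != 1L || n < 1) {
    stop_endocost("`n` must be a count of at least 1", "endocost_empty_error")
  }
  if (is.null(sds)) sds <- stats::setNames(rep(NA_real_, 4L), COST_COMPONENTS)
  if (!all(COST_COMPONENTS %in% names(means)) || !all(COST_COMPONENTS %in% names(sds))) {
    stop_endocost(
      "`means` and `sds` must be named over theatre/consumables/equipment/stay",
      "endocost_config_error"
    )
  }
  means <- means[COST_COMPONENTS]
  sds <- sds[COST_COMPONENTS]
  if (any(!is.na(sds) & sds < 0)) {
    stop_endocost("standard deviations must be non-negative", "endocost_config_error")
  }
  total_mean <- total_mean %||% sum(means)
  mean_vec <- c(means, total = total_mean)
  sd_vec <- c(sds, total = total_sd)
  shares <- means / total_mean
  structure(
    list(
      arm = arm, n = as.integer(n),
      mean = mean_vec, sd = sd_vec, cost_shares = shares
    ),
    class = "arm_cost_summary"
  )
}

#' Summarise the cost decomposition of one study arm
#'
#' Per-component sample means and standard deviations (n - 1 denominator;
#' a single record has SD 0 by convention) plus each component's share of the
#' mean total. All records must belong to the same arm.
#'
#' @inheritParams procedure_cost
#' @return An [arm_cost_summary()] object.
#' @examples
#' cohort <- generate_cohort(cohort_config(seed = 1))
#' summarize_arm(
#'   cohort[cohort$arm == "LPS", ],
#'   cost_rates(), equipment_spec("laparoscopic tower", 140000)
#' )
#' @export
summarize_arm <- function(records, rates = cost_rates(), spec) {
  records <- validate_records(records)
  arms <- unique(records$arm)
  if (length(arms) != 1L) {
    stop_endocost("`records` must contain a single arm; got both", "endocost_record_error")
  }
  costs <- procedure_cost(records, rates, spec)
  comp_cols <- c(
    theatre = "theatre_cost", consumables = "consumables_cost",
    equipment = "equipment_share", stay = "stay_cost"
  )
  sd0 <- function(x) if (length(x) < 2L) 0 else sd(x)
  means <- vapply(comp_cols, function(cl) mean(costs[[cl]]), numeric(1))
  sds <- vapply(comp_cols, function(cl) sd0(costs[[cl]]), numeric(1))
  arm_cost_summary(
    arm = arms, n = nrow(records),
    means = means, sds = sds,
    total_mean = mean(costs$total), total_sd = sd0(costs$total)
  )
}

#' @export
print.arm_cost_summary <- function(x, ...) {
  cat(sprintf("<arm_cost_summary> %s (n = %d)\n", x$arm, x$n))
  tab <- data.frame(
    mean = round(x$mean),
    sd = round(x$sd),
    share = c(sprintf("%.1f%%", 100 * x$cost_shares), "")
  )
  print(tab)
  invisible(x)
}

#' Component shares of the mean total cost
#'
#' Renders the percentage that each cost category represents of the mean
#' total cost per procedure, the usual stacked-bar style summary of a cost
#' decomposition. Shares always sum to 100 and are invariant to rescaling
#' the currency.
#'
#' @param summary An [arm_cost_summary()].
#' @return A tibble with columns `arm`, `component`, `mean_cost`,
#'   `share_pct`.
#' @examples
#' render_cost_shares(arm_cost_summary(
#'   "RBT", 78,
#'   means = c(theatre = 2227, consumables = 2057, equipment = 2000, stay = 768)
#' ))
#' @export
render_cost_shares <- function(summary) {
  stopifnot(inherits(summary, "arm_cost_summary"))
  tibble::tibble(
    arm = summary$arm,
    component = COST_COMPONENTS,
    mean_cost = unname(summary$mean[COST_COMPONENTS]),
    share_pct = unname(100 * summary$cost_shares)
  )
}
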
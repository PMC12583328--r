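#' Path to the bundled study parameter file
#'
#' The package ships a JSON parameter file carrying the study centre's
#' economic rates and equipment prices, the session-plan and discount grids,
#' the two arms' published cost-summary moments (reproduction-mode inputs)
#' and the synthetic-cohort generator defaults.
#'
#' @return Path to `study_params.json`.
#' @export
default_config_path <- function() {
  system.file("extdata", "study_params.json", package = "endocost", mustWork = TRUE)
}

#' Read an economic parameter configuration
#'
#' Parses the JSON parameter format (see [default_config_path()] for the
#' bundled example) into ready-to-use objects: [cost_rates()], per-arm
#' [equipment_spec()]s, the session-plan scenarios, discount grids, ratio
#' overrides, reproduction-mode arm summaries and generator parameters.
#'
#' @param path Path to a JSON config; defaults to the bundled file.
#' @return A named list with elements `rates`, `specs` (named by arm),
#'   `scenarios`, `discounts`, `ratio_override`, `reported_summaries`,
#'   `generator`, `stats_alpha`.
#' @export
read_econ_config <- function(path = default_config_path()) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  rates <- cost_rates(raw$theatre_rate, raw$stay_rate)
  specs <- list()
  for (eq in raw$equipment) {
    specs[[eq$arm]] <- equipment_spec(
      eq$label, eq$purchase_price,
      eq$depreciation_procedures %||% 1000,
      eq$annual_maintenance %||% 0
    )
  }
  scale <- raw$scale %||% list()
  scenarios <- lapply(
    scale$procedures_per_session %||% 1:3,
    scale_scenario,
    sessions_per_year = scale$sessions_per_year %||% 300,
    amortization_years = scale$amortization_years %||% 10
  )
  ratio_override <- lapply(scale$ratio_override %||% list(), function(v) {
    if (is.null(v)) NULL else stay_ratio_override(v)
  })
  reported <- lapply(names(raw$reported_summaries %||% list()), function(arm) {
    rs <- raw$reported_summaries[[arm]]
    arm_cost_summary(
      arm, rs$n,
      means = unlist(rs$mean), sds = unlist(rs$sd),
      total_sd = rs$total_sd %||% NA_real_
    )
  })
  names(reported) <- names(raw$reported_summaries %||% list())
  generator <- lapply(raw$generator %||% list(), function(g) {
    arm_params(
      n = g$n, age = unlist(g$age), bmi = unlist(g$bmi),
      theatre_minutes = unlist(g$theatre_minutes),
      stay_days = unlist(g$stay_days), consumables = unlist(g$consumables),
      complication_prob = g$complication_prob,
      complexity_probs = unlist(g$complexity_probs) / sum(unlist(g$complexity_probs))
    )
  })
  list(
    rates = rates, specs = specs, scenarios = scenarios,
    discounts = list(
      equipment = raw$discounts$equipment %||% c(0, 0.10, 0.15, 0.20),
      consumables = raw$discounts$consumables %||% c(0.30, 0.35)
    ),
    ratio_override = ratio_override,
    reported_summaries = reported,
    generator = generator,
    stats_alpha = raw$stats_alpha %||% 0.05
  )
}

#' Read / write a patient-record CSV
#'
#' The cohort interchange format is a plain CSV with header
#' `arm,theatre_minutes,stay_days,consumables_cost,complexity_group,age,bmi,complication_flag`,
#' decimal point, UTF-8.
#'
#' @param path File path.
#' @return `read_cohort()` returns a validated record tibble.
#' @export
read_cohort <- function(path) {
  validate_records(read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_cohort
#' @param records A validated record table to write.
#' @export
write_cohort <- function(records, path) {
  write.csv(validate_records(records), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

round_half_up <- function(x, digits = 0) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

#' Render a table in report euros
#'
#' Rounds every numeric cost column of a result table to whole euros with
#' half-up rounding, the convention used in printed reports. Internal
#' computation always stays at full floating precision; this is a rendering
#' step only.
#'
#' @param table A tibble from [compare_models()], [scenario_grid()] or
#'   similar.
#' @param columns Columns to round; defaults to the cost-like columns
#'   present.
#' @return The table with the selected columns rounded.
#' @export
render_euros <- function(table,
                         columns = intersect(
                           c("adjusted_cost", "overrun", "rbt_cost", "lps_cost",
                             "difference", "mean_cost"),
                           names(table)
                         )) {
  for (cl in columns) table[[cl]] <- round_half_up(table[[cl]])
  table
}

pipeline_log <- function(verbose, ...) {
  if (verbose) message(sprintf(...))
}

#' Run the full costing pipeline
#'
#' Executes every stage over one of two input modes and optionally writes
#' the result tables to disk:
#'
#' * **reproduction mode** (`cohort = NULL`, the default): the published
#'   arm cost summaries and stay-ratio overrides from the configuration are
#'   used directly, with no patient-level data and no randomness. This
#'   regenerates the session-plan comparison and discount analysis from
#'   printed inputs alone.
#' * **cohort mode**: a patient-record table (read from `cohort_path`,
#'   passed as `cohort`, or simulated from the generator parameters when
#'   `simulate = TRUE`) is costed per procedure, summarised per arm, its
#'   stay ratios computed from the records, and the univariate arm
#'   comparison added.
#'
#' Both modes then produce: per-arm cost summaries and cost shares, the
#' economy-of-scale model comparison, the discount-scenario grid, and the
#' break-even consumables discount per (model, equipment discount).
#'
#' @param config A configuration list from [read_econ_config()], or a path
#'   to a JSON config file.
#' @param cohort Optional patient-record table (cohort mode).
#' @param cohort_path Optional path to a cohort CSV (cohort mode).
#' @param simulate Draw a synthetic cohort from the configured generator
#'   (cohort mode).
#' @param seed Seed used when `simulate = TRUE`.
#' @param out_dir Optional output directory; result tables are written
#'   there as CSV and/or JSON plus a `run_log.txt` echoing parameters.
#' @param format Output formats, subset of `c("csv", "json")`.
#' @param verbose Emit progress messages (default `FALSE`).
#' @return A list of tibbles/objects: `mode`, `summaries`, `cost_shares`,
#'   `ratios`, `models`, `grid`, `break_even`, and (cohort mode) `cohort`
#'   and `stats`.
#' @examples
#' res <- run_pipeline()
#' render_euros(res$models)
#' @export
run_pipeline <- function(config = default_config_path(), cohort = NULL,
                         cohort_path = NULL, simulate = FALSE, seed = 1L,
                         out_dir = NULL, format = c("csv", "json"),
                         verbose = FALSE) {
  if (is.character(config)) config <- read_econ_config(config)
  format <- match.arg(format, several.ok = TRUE)

  if (!is.null(cohort_path)) cohort <- read_cohort(cohort_path)
  if (simulate && is.null(cohort)) {
    pipeline_log(verbose, "stage simulate: drawing synthetic cohort (seed %d)", seed)
    cohort <- generate_cohort(
      cohort_config(config$generator$LPS, config$generator$RBT, seed = seed)
    )
  }

  stats_tab <- NULL
  if (is.null(cohort)) {
    mode <- "reproduction"
    pipeline_log(verbose, "stage costs: using reported arm summaries")
    summaries <- config$reported_summaries
    if (length(summaries) < 2L) {
      stop_endocost("reproduction mode needs reported summaries for both arms",
                    "endocost_config_error")
    }
    ratios <- config$ratio_override
    if (is.null(ratios$LPS) || is.null(ratios$RBT)) {
      stop_endocost("reproduction mode needs ratio overrides for both arms",
                    "endocost_config_error")
    }
  } else {
    mode <- "cohort"
    cohort <- validate_records(cohort)
    pipeline_log(verbose, "stage costs: summarising %d records", nrow(cohort))
    summaries <- list(
      LPS = summarize_arm(cohort[cohort$arm == "LPS", ], config$rates, config$specs$LPS),
      RBT = summarize_arm(cohort[cohort$arm == "RBT", ], config$rates, config$specs$RBT)
    )
    # ratio overrides are reproduction-mode inputs; with records in hand the
    # ratios always come from the records themselves
    ratios <- list(
      LPS = stay_ratio(cohort[cohort$arm == "LPS", ]),
      RBT = stay_ratio(cohort[cohort$arm == "RBT", ])
    )
    pipeline_log(verbose, "stage stats: univariate arm comparison")
    stats_tab <- compare_cohort(cohort, config$rates, config$specs,
                                alpha = config$stats_alpha)
  }

  shares <- rbind(render_cost_shares(summaries$LPS), render_cost_shares(summaries$RBT))

  pipeline_log(verbose, "stage scale: %d session-plan models", length(config$scenarios))
  models <- compare_models(
    summaries$LPS, summaries$RBT,
    config$specs$LPS, config$specs$RBT,
    ratios$LPS, ratios$RBT,
    scenarios = config$scenarios
  )

  pipeline_log(verbose, "stage discounts: scenario grid and break-even")
  grid <- scenario_grid(
    summaries$LPS, summaries$RBT,
    config$specs$LPS, config$specs$RBT,
    ratios$LPS, ratios$RBT,
    scenarios = config$scenarios,
    equipment_discounts = config$discounts$equipment,
    consumables_discounts = config$discounts$consumables
  )

  be_rows <- list()
  for (sc in config$scenarios) {
    cap_l <- capacity(ratios$LPS, sc)
    cap_r <- capacity(ratios$RBT, sc)
    lps_cost <- ratio_adjusted_cost(summaries$LPS, config$specs$LPS, cap_l$total)
    for (de in config$discounts$equipment) {
      be_rows[[length(be_rows) + 1L]] <- tibble::tibble(
        model = sc$procedures_per_session,
        equipment_discount = de,
        break_even_consumables_discount = break_even_consumables_discount(
          summaries$RBT, lps_cost, config$specs$RBT, cap_r$total, de
        )
      )
    }
  }
  break_even <- do.call(rbind, be_rows)

  result <- list(
    mode = mode, summaries = summaries, cost_shares = shares, ratios = ratios,
    models = models, grid = grid, break_even = break_even,
    cohort = cohort, stats = stats_tab, seed = if (simulate) seed else NA_integer_
  )

  if (!is.null(out_dir)) write_pipeline_outputs(result, out_dir, format, verbose)
  result
}

write_pipeline_outputs <- function(result, out_dir, format, verbose = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tables <- list(
    cost_shares = result$cost_shares, models = result$models,
    grid = result$grid, break_even = result$break_even
  )
  if (!is.null(result$stats)) tables$stats <- result$stats
  if (!is.null(result$cohort)) tables$cohort <- result$cohort
  for (nm in names(tables)) {
    if ("csv" %in% format) {
      write.csv(tables[[nm]], file.path(out_dir, paste0(nm, ".csv")), row.names = FALSE)
    }
    if ("json" %in% format) {
      jsonlite::write_json(tables[[nm]], file.path(out_dir, paste0(nm, ".json")),
                           auto_unbox = TRUE, digits = NA)
    }
  }
  log_lines <- c(
    sprintf("endocost %s", as.character(utils::packageVersion("endocost"))),
    sprintf("R %s", getRversion()),
    sprintf("mode: %s", result$mode),
    sprintf("seed: %s", result$seed),
    sprintf("ratios: LPS %.2f (%s), RBT %.2f (%s)",
            result$ratios$LPS$value, result$ratios$LPS$source,
            result$ratios$RBT$value, result$ratios$RBT$source),
    sprintf("tables written: %s", paste(names(tables), collapse = ", "))
  )
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  pipeline_log(verbose, "outputs written to %s", out_dir)
  invisible(out_dir)
}
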
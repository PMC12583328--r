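#' Compare a continuous variable between two arms
#'
#' Applies the usual univariate routing for clinical cohort tables: each
#' arm is screened for normality with a one-sample Kolmogorov-Smirnov test
#' against a normal distribution with that arm's sample mean and SD; if both
#' arms pass the gate the two-sided Student's t test (pooled variance by
#' default) is used, otherwise the two-sided Wilcoxon rank-sum test. Group
#' means and SDs are reported either way.
#'
#' The KS gate with estimated parameters is anti-conservative (it passes
#' normality too easily); the gate's alpha is therefore configurable.
#' Degenerate samples (zero variance in either arm) cannot be screened and
#' are routed to the rank test with a note.
#'
#' @param x,y Numeric values for the two arms (each of length >= 3).
#' @param alpha Significance level reported alongside (default 0.05).
#' @param gate_alpha Alpha of the normality gate (default 0.05).
#' @param welch Use the Welch t statistic instead of pooled variance.
#' @param variable Optional variable name carried into the result.
#' @return A `comparison_result`: list with `variable`, `test_used`
#'   (`"student_t"` or `"wilcoxon"`), `statistic`, `p_value`, `significant`,
#'   `group_summaries` (tibble of n/mean/sd per arm) and `note`.
#' @examples
#' compare_continuous(rnorm(30, 161, 60), rnorm(30, 152, 43))
#' @export
compare_continuous <- function(x, y, alpha = 0.05, gate_alpha = 0.05,
                               welch = FALSE, variable = NA_character_) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) < 3L || length(y) < 3L) {
    stop_endocost("each arm needs at least 3 observations", "endocost_record_error")
  }
  degenerate <- sd(x) == 0 || sd(y) == 0
  note <- NA_character_
  if (degenerate) {
    normal <- FALSE
    note <- "zero-variance sample: normality gate skipped, rank test used"
  } else {
    ks_p <- function(v) {
      suppressWarnings(ks.test(v, "pnorm", mean = mean(v), sd = sd(v))$p.value)
    }
    normal <- ks_p(x) > gate_alpha && ks_p(y) > gate_alpha
  }
  if (normal) {
    ht <- t.test(x, y, var.equal = !welch)
    test_used <- "student_t"
  } else {
    ht <- suppressWarnings(wilcox.test(x, y, exact = NULL))
    test_used <- "wilcoxon"
  }
  new_comparison_result(
    variable = variable, test_used = test_used,
    statistic = unname(ht$statistic), p_value = ht$p.value, alpha = alpha,
    group_summaries = tibble::tibble(
      arm = c("A", "B"), n = c(length(x), length(y)),
      mean = c(mean(x), mean(y)), sd = c(sd(x), sd(y))
    ),
    note = note
  )
}

#' Compare a categorical variable between arms
#'
#' Chi-squared test without continuity correction on a 2 x C contingency
#' table, switching to Fisher's exact test whenever any expected cell count
#' falls below five (the standard small-sample rule). For tables wider than
#' 2 x 2 the exact test uses the network algorithm, falling back to
#' Monte-Carlo p-values if it cannot complete.
#'
#' @param table A 2 x C matrix of non-negative integer counts (arms in
#'   rows).
#' @param alpha Significance level reported alongside (default 0.05).
#' @param variable Optional variable name carried into the result.
#' @return A `comparison_result` with `test_used` `"chi_square"` or
#'   `"fisher"` and the group counts/percentages in `group_summaries`.
#' @examples
#' compare_categorical(matrix(c(56, 68, 19, 10), nrow = 2))
#' @export
compare_categorical <- function(table, alpha = 0.05, variable = NA_character_) {
  table <- as.matrix(table)
  if (nrow(table) != 2L || ncol(table) < 2L ||
      any(table < 0) || any(table != round(table)) || any(!is.finite(table))) {
    stop_endocost("`table` must be a 2 x C matrix of non-negative integer counts",
                  "endocost_record_error")
  }
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop_endocost("contingency table has an empty margin", "endocost_record_error")
  }
  expected <- outer(rowSums(table), colSums(table)) / sum(table)
  if (any(expected < 5)) {
    ht <- tryCatch(
      fisher.test(table),
      error = function(e) fisher.test(table, simulate.p.value = TRUE, B = 1e4)
    )
    test_used <- "fisher"
    statistic <- NA_real_
  } else {
    ht <- chisq.test(table, correct = FALSE)
    test_used <- "chi_square"
    statistic <- unname(ht$statistic)
  }
  pct <- 100 * table / rowSums(table)
  new_comparison_result(
    variable = variable, test_used = test_used,
    statistic = statistic, p_value = ht$p.value, alpha = alpha,
    group_summaries = tibble::tibble(
      arm = rep(c("A", "B"), ncol(table)),
      level = rep(colnames(table) %||% as.character(seq_len(ncol(table))), each = 2L),
      count = as.vector(table),
      pct = as.vector(pct)
    ),
    note = NA_character_
  )
}

new_comparison_result <- function(variable, test_used, statistic, p_value,
                                  alpha, group_summaries, note) {
  stopifnot(p_value >= 0, p_value <= 1)
  structure(
    list(
      variable = variable, test_used = test_used, statistic = statistic,
      p_value = p_value, significant = p_value < alpha, alpha = alpha,
      group_summaries = group_summaries, note = note
    ),
    class = "comparison_result"
  )
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf(
    "<comparison_result> %s: %s, p = %.4g%s\n",
    x$variable %||% "?", x$test_used, x$p_value,
    if (isTRUE(x$significant)) " *" else ""
  ))
  invisible(x)
}

#' Detect perfect separation of a binary outcome by a predictor
#'
#' A predictor perfectly separates two classes when its ranges in the two
#' classes do not overlap: every value in one class lies strictly below
#' every value in the other. Under perfect separation the maximum-likelihood
#' logistic-regression coefficient diverges, so such predictors must be
#' excluded from regression models; in two-arm cost data this typically
#' happens to cost components that differ categorically between arms (for
#' instance equipment-heavy direct costs). Detection is invariant to
#' strictly monotone transforms of the predictor.
#'
#' @param outcome Binary labels (logical, or any vector with exactly two
#'   distinct values; both classes must be present).
#' @param predictor Numeric values, same length as `outcome`.
#' @return A list: `separated` (logical), `threshold` (midpoint of the gap
#'   when separated, `NA` otherwise) and `direction` (which class lies
#'   below).
#' @examples
#' detect_perfect_separation(c(0, 0, 0, 1, 1), c(1, 2, 3, 10, 11))
#' @export
detect_perfect_separation <- function(outcome, predictor) {
  if (length(outcome) != length(predictor)) {
    stop_endocost("`outcome` and `predictor` must have equal length", "endocost_record_error")
  }
  classes <- unique(outcome)
  if (length(classes) != 2L) {
    stop_endocost("`outcome` must contain exactly two classes", "endocost_record_error")
  }
  a <- predictor[outcome == classes[[1L]]]
  b <- predictor[outcome == classes[[2L]]]
  if (max(a) < min(b)) {
    list(separated = TRUE, threshold = (max(a) + min(b)) / 2,
         direction = sprintf("%s < %s", classes[[1L]], classes[[2L]]))
  } else if (max(b) < min(a)) {
    list(separated = TRUE, threshold = (max(b) + min(a)) / 2,
         direction = sprintf("%s < %s", classes[[2L]], classes[[1L]]))
  } else {
    list(separated = FALSE, threshold = NA_real_, direction = NA_character_)
  }
}

#' Univariate arm comparison of a whole cohort
#'
#' Runs the routed two-arm comparison over the standard cohort variables:
#' continuous (age, BMI, theatre minutes, stay days, consumables cost, and
#' the four computed cost components plus total when rates and a spec pair
#' are supplied) and categorical (complexity group, complication flag).
#' Also screens each cost column for perfect separation by arm, flagging
#' predictors that a logistic regression on arm membership would have to
#' exclude.
#'
#' @param records A two-arm patient-record table.
#' @param rates Optional [cost_rates()]; with `specs`, enables cost rows.
#' @param specs Optional named list `list(LPS = , RBT = )` of
#'   [equipment_spec()]s.
#' @param alpha Significance level (default 0.05).
#' @return A tibble with one row per variable: `variable`, `test_used`,
#'   `statistic`, `p_value`, `significant`, `separated` (cost rows only).
#' @export
compare_cohort <- function(records, rates = NULL, specs = NULL, alpha = 0.05) {
  records <- validate_records(records)
  if (length(unique(records$arm)) != 2L) {
    stop_endocost("`records` must contain both arms", "endocost_record_error")
  }
  lps <- records[records$arm == "LPS", ]
  rbt <- records[records$arm == "RBT", ]
  rows <- list()
  add <- function(res, separated = NA) {
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      variable = res$variable, test_used = res$test_used,
      statistic = res$statistic, p_value = res$p_value,
      significant = res$significant, separated = separated
    )
  }
  for (v in c("age", "bmi", "theatre_minutes", "stay_days", "consumables_cost")) {
    add(compare_continuous(lps[[v]], rbt[[v]], alpha = alpha, variable = v))
  }
  tab_cx <- rbind(
    LPS = table(factor(lps$complexity_group, c("A", "B", "C"))),
    RBT = table(factor(rbt$complexity_group, c("A", "B", "C")))
  )
  add(compare_categorical(tab_cx, alpha = alpha, variable = "complexity_group"))
  tab_cp <- rbind(
    LPS = table(factor(lps$complication_flag, c(FALSE, TRUE))),
    RBT = table(factor(rbt$complication_flag, c(FALSE, TRUE)))
  )
  add(compare_categorical(tab_cp, alpha = alpha, variable = "complication_flag"))
  if (!is.null(rates) && !is.null(specs)) {
    costs_l <- procedure_cost(lps, rates, specs$LPS)
    costs_r <- procedure_cost(rbt, rates, specs$RBT)
    cost_cols <- c("theatre_cost", "consumables_cost", "stay_cost", "total")
    for (v in cost_cols) {
      sep <- detect_perfect_separation(
        c(rep("LPS", nrow(costs_l)), rep("RBT", nrow(costs_r))),
        c(costs_l[[v]], costs_r[[v]])
      )
      add(
        compare_continuous(costs_l[[v]], costs_r[[v]], alpha = alpha,
                           variable = paste0("cost_", v)),
        separated = sep$separated
      )
    }
    direct_l <- costs_l$consumables_cost + costs_l$equipment_share
    direct_r <- costs_r$consumables_cost + costs_r$equipment_share
    sep <- detect_perfect_separation(
      c(rep("LPS", length(direct_l)), rep("RBT", length(direct_r))),
      c(direct_l, direct_r)
    )
    add(
      compare_continuous(direct_l, direct_r, alpha = alpha, variable = "cost_direct"),
      separated = sep$separated
    )
  }
  do.call(rbind, rows)
}
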
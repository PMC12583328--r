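test_that("continuous comparisons route through the normality gate", {
  set.seed(41)
  # clearly normal samples take the t test
  res_t <- compare_continuous(rnorm(60, 10, 2), rnorm(60, 11, 2))
  expect_equal(res_t$test_used, "student_t")

  # heavily skewed samples fail the gate and take the rank test
  res_w <- compare_continuous(rexp(120, 1), rexp(120, 2))
  expect_equal(res_w$test_used, "wilcoxon")

  # identical samples: no difference, rank-test p of 1
  x <- c(3, 1, 4, 1, 5, 9, 2, 6)
  res_id <- compare_continuous(x, x)
  expect_equal(res_id$p_value, 1)
  expect_equal(diff(res_id$group_summaries$mean), 0)

  # degenerate samples are flagged and routed to the rank test
  res_deg <- compare_continuous(rep(5, 10), rnorm(10, 5))
  expect_equal(res_deg$test_used, "wilcoxon")
  expect_match(res_deg$note, "zero-variance")

  expect_error(compare_continuous(1:2, 1:10), class = "endocost_record_error")
})

test_that("the pooled t statistic matches the closed form on a worked pair", {
  x <- c(1, 2, 3, 4, 5)
  y <- c(2, 4, 6, 8, 10)
  res <- compare_continuous(x, y)
  expect_equal(res$test_used, "student_t")
  sp2 <- ((length(x) - 1) * var(x) + (length(y) - 1) * var(y)) /
    (length(x) + length(y) - 2)
  t_hand <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / length(x) + 1 / length(y)))
  expect_equal(res$statistic, t_hand)
})

test_that("swapping arm labels leaves p-values unchanged and flips the sign", {
  set.seed(43)
  x <- rnorm(40, 5); y <- rnorm(40, 6)
  ab <- compare_continuous(x, y)
  ba <- compare_continuous(y, x)
  expect_equal(ab$p_value, ba$p_value)
  if (ab$test_used == "student_t") expect_equal(ab$statistic, -ba$statistic)
})

test_that("categorical comparisons use chi-square unless expected counts drop below five", {
  balanced <- matrix(c(10, 10, 10, 10), nrow = 2)
  res <- compare_categorical(balanced)
  expect_equal(res$test_used, "chi_square")
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)

  sparse <- matrix(c(1, 0, 3, 6), nrow = 2)
  expect_equal(compare_categorical(sparse)$test_used, "fisher")

  expect_error(compare_categorical(matrix(c(0, 0, 3, 6), nrow = 2)),
               class = "endocost_record_error")
  expect_error(compare_categorical(matrix(c(1.5, 2, 3, 6), nrow = 2)),
               class = "endocost_record_error")
})

test_that("the exact test agrees with hypergeometric enumeration on small tables", {
  # independent oracle: enumerate all tables with the observed margins and
  # sum the probabilities of those no more likely than the observed one
  fisher_enum <- function(tab) {
    m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
    support <- max(0, k - n):min(k, m)
    probs <- dhyper(support, m, n, k)
    p_obs <- dhyper(tab[1, 1], m, n, k)
    sum(probs[probs <= p_obs * (1 + 1e-7)])
  }
  tables <- list(
    matrix(c(1, 0, 0, 2), nrow = 2),
    matrix(c(1, 3, 4, 1), nrow = 2),
    matrix(c(2, 5, 6, 1), nrow = 2),
    matrix(c(0, 4, 4, 0), nrow = 2)
  )
  for (tab in tables) {
    res <- compare_categorical(tab)
    expect_equal(res$test_used, "fisher")
    expect_equal(res$p_value, fisher_enum(tab), tolerance = 1e-7)
  }
})

test_that("perfect separation is detected exactly when class ranges do not overlap", {
  sep <- detect_perfect_separation(c(0, 0, 0, 1, 1), c(1, 2, 3, 10, 11))
  expect_true(sep$separated)
  expect_equal(sep$threshold, 6.5)

  inter <- detect_perfect_separation(c(0, 1, 0, 1), c(1, 2, 3, 4))
  expect_false(inter$separated)
  expect_true(is.na(inter$threshold))

  # invariant to strictly monotone transforms of the predictor
  set.seed(47)
  for (i in 1:20) {
    cls <- rbinom(30, 1, 0.5)
    if (length(unique(cls)) < 2) next
    pred <- rnorm(30) + 3 * cls
    raw <- detect_perfect_separation(cls, pred)
    mono <- detect_perfect_separation(cls, exp(pred / 2))
    expect_equal(raw$separated, mono$separated)
  }

  expect_error(detect_perfect_separation(c(1, 1, 1), 1:3),
               class = "endocost_record_error")
  expect_error(detect_perfect_separation(c(0, 1), 1:3),
               class = "endocost_record_error")
})

test_that("the cohort comparison table covers every routed variable", {
  cohort <- generate_cohort(cohort_config(seed = 5))
  tab <- compare_cohort(cohort, cost_rates(),
                        list(LPS = lps_spec(), RBT = rbt_spec()))
  expect_true(all(c("age", "bmi", "stay_days", "complexity_group",
                    "complication_flag", "cost_total", "cost_direct") %in% tab$variable))
  expect_true(all(tab$p_value >= 0 & tab$p_value <= 1))
  expect_true(all(tab$test_used %in% c("student_t", "wilcoxon", "chi_square", "fisher")))
  # the direct-cost component separates the arms in this cohort
  expect_true(tab$separated[tab$variable == "cost_direct"])
})

test_that("the stay difference between default arms is detected in nearly every draw", {
  hits <- 0L
  n_seeds <- 200L
  for (s in seq_len(n_seeds)) {
    cohort <- generate_cohort(cohort_config(seed = 1000L + s))
    res <- compare_continuous(
      cohort$stay_days[cohort$arm == "LPS"],
      cohort$stay_days[cohort$arm == "RBT"]
    )
    if (res$significant) hits <- hits + 1L
  }
  expect_gte(hits / n_seeds, 0.95)
})
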
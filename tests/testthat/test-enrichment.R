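test_that("hypergeometric pmf matches exact values and base R", {
  expect_equal(hypergeom_pmf(19, c(20, 15, 28, 7)), 0.014886, tolerance = 1e-4)
  # cross-check against the independent base-R implementation
  expect_equal(hypergeom_pmf(19, c(20, 15, 28, 7)), dhyper(19, 28, 7, 20),
               tolerance = 1e-12)
  # degenerate margin: single feasible table has probability 1
  expect_equal(hypergeom_pmf(5, c(5, 3, 8, 0)), 1.0)
  expect_error(hypergeom_pmf(21, c(20, 15, 28, 7)), "feasible")
  expect_error(hypergeom_pmf(1, c(2, 2, 3, 3)), "inconsistent")
})

test_that("pmf sums to one over its feasible range for random margins", {
  set.seed(11)
  for (i in 1:100) {
    n <- sample(4:60, 1)
    r1 <- sample(1:(n - 1), 1)
    c1 <- sample(1:(n - 1), 1)
    margins <- c(r1, n - r1, c1, n - c1)
    support <- max(0, r1 - (n - c1)):min(r1, c1)
    total <- sum(vapply(support, hypergeom_pmf, numeric(1),
                        margins = margins))
    expect_equal(total, 1.0, tolerance = 1e-10)
  }
})

test_that("the two-sided Fisher test reproduces the study's table exactly", {
  # full enumeration over feasible a = 13..20 gives 0.0273707
  expect_equal(fisher_exact_two_sided(19, 1, 9, 6), 0.02737073, tolerance = 1e-6)
  expect_equal(fisher_exact_two_sided(5, 5, 5, 5), 1.0)
  # symmetry: transpose and simultaneous row/column swaps
  p <- fisher_exact_two_sided(19, 1, 9, 6)
  expect_equal(fisher_exact_two_sided(19, 9, 1, 6), p)
  expect_equal(fisher_exact_two_sided(6, 9, 1, 19), p)
  expect_error(fisher_exact_two_sided(0, 0, 0, 0), "empty")
  expect_error(fisher_exact_two_sided(-1, 2, 3, 4), "non-negative")
})

test_that("Fisher p agrees with stats::fisher.test over many margins", {
  set.seed(23)
  for (i in 1:150) {
    n <- sample(4:60, 1)
    cells <- as.vector(stats::rmultinom(1, n, prob = runif(4, 0.05, 1)))
    ours <- fisher_exact_two_sided(cells[1], cells[2], cells[3], cells[4])
    ref <- stats::fisher.test(matrix(cells, 2, 2, byrow = TRUE))$p.value
    expect_equal(ours, ref, tolerance = 1e-9,
                 info = paste(cells, collapse = ","))
  }
})

test_that("odds ratio and Katz interval reproduce the study's statistics", {
  res <- odds_ratio_katz_ci(19, 1, 9, 6)
  expect_equal(res$odds_ratio, 12.67, tolerance = 1e-2 / 12.67)
  expect_equal(res$ci_low, 1.32, tolerance = 0.01)
  expect_equal(res$ci_high, 121.47, tolerance = 0.01)
  # symmetric table: OR 1, CI symmetric about 1 on the log scale
  sym <- odds_ratio_katz_ci(1, 1, 1, 1)
  expect_equal(sym$odds_ratio, 1.0)
  expect_equal(log(sym$ci_low), -log(sym$ci_high), tolerance = 1e-12)
  # estimate always inside its interval when all cells are positive
  set.seed(5)
  for (i in 1:50) {
    cells <- sample(1:30, 4, replace = TRUE)
    r <- odds_ratio_katz_ci(cells[1], cells[2], cells[3], cells[4])
    expect_true(r$ci_low <= r$odds_ratio && r$odds_ratio <= r$ci_high)
  }
})

test_that("zero cells leave the OR undefined unless continuity is requested", {
  res <- odds_ratio_katz_ci(5, 0, 3, 4)
  expect_true(is.na(res$odds_ratio))
  res <- odds_ratio_katz_ci(5, 0, 3, 4, continuity = TRUE)
  expect_equal(res$odds_ratio, (5.5 * 4.5) / (0.5 * 3.5))
})

test_that("enrich() builds the study table from the fixture flags", {
  res <- enrich(study_variants(), "ATPase_motor_region")
  expect_equal(as.vector(t(res$table)), c(19, 1, 9, 6))
  expect_equal(res$excluded_unknowns, 1)  # the spanless splice variant
  expect_lt(abs(res$p_two_sided - 0.027), 5e-4)
  expect_equal(res$odds_ratio, 12.67, tolerance = 1e-2 / 12.67)
  td <- tidy(res)
  expect_equal(td$a, 19)
  expect_equal(td$p_two_sided, res$p_two_sided)
})

test_that("enrich() degenerate inputs are handled explicitly", {
  v <- study_variants()
  v$heart_anomaly <- "unknown"
  expect_error(enrich(v), "Empty table")
  v <- study_variants()
  v$heart_anomaly <- "yes"   # zero column margin
  res <- enrich(v)
  expect_true(is.na(res$p_two_sided))
  expect_match(res$message, "margin")
})

test_that("the recorded group counts equal the fixture-derived table", {
  counts <- chd4_anomaly_counts()
  expect_equal(unname(counts), c(19L, 1L, 9L, 6L))
  res <- enrich_table(counts[["a"]], counts[["b"]],
                      counts[["c"]], counts[["d"]])
  fix <- enrich(study_variants(), "ATPase_motor_region")
  expect_equal(res$p_two_sided, fix$p_two_sided)
  expect_equal(res$odds_ratio, fix$odds_ratio)
})

test_that("null simulation keeps the rejection rate at or below alpha", {
  spec <- cohort_spec(seed = 104,
                      region_anomaly_probs = c(ATPase_motor_region = 0.6,
                                               other = 0.6))
  rate <- power_of_enrichment(spec, n_reps = 2000, alpha = 0.05)
  expect_lte(rate, 0.05)
})

test_that("power grows with the effect and is 1 at alpha = 1", {
  null_spec <- cohort_spec(seed = 9,
                           region_anomaly_probs =
                             c(ATPase_motor_region = 0.6, other = 0.6))
  effect_spec <- cohort_spec(seed = 9,
                             region_anomaly_probs =
                               c(ATPase_motor_region = 0.95, other = 0.6))
  null_rate <- power_of_enrichment(null_spec, n_reps = 500)
  effect_rate <- power_of_enrichment(effect_spec, n_reps = 500)
  expect_gt(effect_rate, null_rate)
  expect_equal(power_of_enrichment(effect_spec, n_reps = 100, alpha = 1),
               1.0)
})

test_that("Katz interval coverage at the study cell sizes is near nominal", {
  set.seed(31)
  p1 <- 0.95; p2 <- 0.6
  true_or <- (p1 / (1 - p1)) / (p2 / (1 - p2))
  n_reps <- 400
  covered <- 0; informative <- 0
  for (i in seq_len(n_reps)) {
    a <- rbinom(1, 20, p1); cc <- rbinom(1, 15, p2)
    r <- odds_ratio_katz_ci(a, 20 - a, cc, 15 - cc)
    if (is.na(r$odds_ratio)) next
    informative <- informative + 1
    if (r$ci_low <= true_or && true_or <= r$ci_high) covered <- covered + 1
  }
  expect_gte(covered / informative, 0.90)
})
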
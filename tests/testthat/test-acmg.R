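test_that("evidence strings parse into sided, strength-tagged codes", {
  ev <- parse_evidence("PS2+PM2+PP3_strong")
  expect_equal(ev$code, c("PS2", "PM2", "PP3"))
  expect_equal(ev$side, c("pathogenic", "pathogenic", "pathogenic"))
  expect_equal(ev$strength, c("strong", "moderate", "strong"))
  expect_equal(nrow(parse_evidence("")), 0)
  expect_equal(nrow(parse_evidence(NA_character_)), 0)
  expect_equal(parse_evidence("BA1")$strength, "stand_alone")
  expect_equal(parse_evidence("PVS1")$strength, "very_strong")
  expect_error(parse_evidence("PS9"), "Unknown")
  expect_error(parse_evidence("PS2+PS2"), "Duplicate")
  expect_error(parse_evidence("PP3+BP4"), "co-occur")
  expect_error(parse_evidence("PS2_strong+PM2"), "only permitted")
  expect_error(parse_evidence("PS2&PM2"), "Malformed")
})

test_that("categorical combination reproduces the study's evidence patterns", {
  cases <- list(
    list("PS2+PS3+PM2+PP3_moderate", "Pathogenic"),
    list("PS2+PM2+PP3_strong", "Likely pathogenic"),   # tier collapsed
    list("PS2+PM2", "Likely pathogenic"),
    list("PM2+BS2+BP4_moderate", "Likely benign"),
    list("PS2+PM2+BP4_moderate", "Likely pathogenic"),
    list("PM2+PM6", "VUS"),
    list("PM2+PM6+PP3_moderate", "VUS"),
    list("PM2+PM6+PP2+PP3_moderate", "Likely pathogenic"),
    list("PM2+PP2+BP4_supporting", "VUS"),
    list("", "VUS")
  )
  for (case in cases) {
    expect_equal(combine_categorical(case[[1]]), case[[2]],
                 info = case[[1]])
  }
})

test_that("tier handling and conflict policy are configurable", {
  honor <- acmg_config(pp3_tier_handling = "honor_tier")
  # PP3_strong counted at strong level makes PS2+PM2+PP3_strong pathogenic
  expect_equal(combine_categorical("PS2+PM2+PP3_strong", honor),
               "Pathogenic")
  strict <- acmg_config(conflict_policy = "richards_vus")
  expect_equal(combine_categorical("PS2+PM2+BP4_moderate", strict), "VUS")
  expect_equal(combine_categorical("PM2+BS2+BP4_moderate", strict), "VUS")
})

test_that("point totals and classes follow the stated weights", {
  res <- combine_points("PS2+PS3+PM2+PP3_supporting")
  expect_equal(res$points, 11)
  expect_equal(res$classification, "Pathogenic")
  res <- combine_points("PM2+BS2+BP4_moderate")
  # BP4 tier collapses to supporting by default: 2 - 4 - 1
  expect_equal(res$points, -3)
  expect_equal(res$classification, "Likely benign")
  res <- combine_points("PM2+BS2+BP4_moderate",
                        acmg_config(mode = "points",
                                    pp3_tier_handling = "honor_tier"))
  expect_equal(res$points, -4)
  expect_equal(res$classification, "Likely benign")
  expect_equal(combine_points("")$points, 0)
  expect_equal(combine_points("")$classification, "VUS")
})

test_that("adding same-side evidence never weakens a single-side verdict", {
  rank <- function(cls) match(cls, c("Benign", "Likely benign", "VUS",
                                     "Likely pathogenic", "Pathogenic"))
  path_codes <- c("PVS1", "PS2", "PS3", "PM2", "PM6", "PP2", "PP3")
  benign_codes <- c("BA1", "BS2", "BS3", "BP4", "BP7")
  set.seed(7)
  for (i in 1:200) {
    base <- sample(path_codes, sample(0:4, 1))
    addition <- sample(setdiff(path_codes, base), 1)
    before <- combine_categorical(paste(base, collapse = "+"))
    after <- combine_categorical(paste(c(base, addition), collapse = "+"))
    expect_gte(rank(after), rank(before))
    base_b <- sample(benign_codes, sample(0:3, 1))
    addition_b <- sample(setdiff(benign_codes, base_b), 1)
    before_b <- combine_categorical(paste(base_b, collapse = "+"))
    after_b <- combine_categorical(paste(c(base_b, addition_b),
                                         collapse = "+"))
    expect_lte(rank(after_b), rank(before_b))
  }
})

test_that("the rule table is exhaustive over mixed evidence sets", {
  codes <- c("PVS1", "PS2", "PS3", "PM2", "PM6", "PP2", "PP3", "BS2", "BP4")
  classes <- c("Benign", "Likely benign", "VUS", "Likely pathogenic",
               "Pathogenic")
  for (k in 0:6) {
    combos <- utils::combn(codes, k, simplify = FALSE)
    for (combo in combos) {
      # the evidence-set invariant excludes co-occurring PP3 and BP4
      if (all(c("PP3", "BP4") %in% combo)) next
      out <- combine_categorical(paste(combo, collapse = "+"))
      expect_true(out %in% classes,
                  info = paste(combo, collapse = "+"))
      # pure function: same set, same verdict
      expect_identical(
        combine_categorical(paste(rev(combo), collapse = "+")), out
      )
    }
  }
})

test_that("ClinVar comparison handles ranges, conflicts and absences", {
  expect_equal(compare_to_clinvar("Pathogenic", "VUS"), "Upgraded")
  expect_equal(compare_to_clinvar("VUS", "LP"), "Downgraded")
  expect_equal(compare_to_clinvar("Likely pathogenic", "P/LP"), "Unchanged")
  expect_equal(compare_to_clinvar("Pathogenic", "P/LP"), "Unchanged")
  expect_equal(compare_to_clinvar("VUS", "P/LP"), "Downgraded")
  expect_equal(compare_to_clinvar("Likely pathogenic", "NP"),
               "First classification")
  expect_equal(compare_to_clinvar("Pathogenic", "CS"), "Upgraded")
  expect_equal(compare_to_clinvar("VUS", "CS"), "Unchanged")
  expect_equal(compare_to_clinvar("Likely benign", "B"), "Upgraded")
  expect_error(compare_to_clinvar("VUS", "odd"), "Unknown ClinVar")
})

test_that("per-variant comparisons and their recount match the printed table", {
  cl <- classify_variants(study_variants())
  mm <- cl[cl$type == "missense", ]
  expect_equal(mm$comparison, unname(printed_comparisons[mm$variant]))
  tally <- table(mm$comparison)
  expect_equal(unname(tally[["Unchanged"]]), 12)
  expect_equal(unname(tally[["First classification"]]), 10)
  expect_equal(unname(tally[["Upgraded"]]) + unname(tally[["Downgraded"]]),
               11)
})

test_that("classifying zero variants yields an empty result", {
  v <- study_variants()[0, ]
  cl <- classify_variants(v)
  expect_equal(nrow(cl), 0)
  expect_equal(sum(class_histogram(cl)), 0)
})
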
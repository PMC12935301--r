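test_that("REVEL tier mapping matches the calibrated interval bounds", {
  cases <- c(
    "0.968" = "PP3_strong", "0.933" = "PP3_strong",
    "0.932" = "PP3_strong",                       # strong bound inclusive
    "0.905" = "PP3_moderate", "0.788" = "PP3_moderate",
    "0.773" = "PP3_moderate",                     # moderate bound inclusive
    "0.76" = "PP3_supporting", "0.644" = "PP3_supporting",
    "0.643" = "undetermined", "0.5" = "undetermined",
    "0.294" = "undetermined",
    "0.290" = "BP4_supporting",                   # benign bound inclusive
    "0.239" = "BP4_supporting", "0.184" = "BP4_supporting",
    "0.183" = "BP4_moderate", "0.14" = "BP4_moderate", "0" = "BP4_moderate"
  )
  expect_equal(revel_to_evidence(as.numeric(names(cases))), unname(cases))
  expect_error(revel_to_evidence(1.2), "outside")
})

test_that("REVEL tier mapping is monotone in the score", {
  order_of <- c(
    BP4_moderate = 1, BP4_supporting = 2, undetermined = 3,
    PP3_supporting = 4, PP3_moderate = 5, PP3_strong = 6
  )
  grid <- seq(0, 1, by = 0.001)
  ranks <- order_of[revel_to_evidence(grid)]
  expect_true(all(diff(ranks) >= 0))
})

test_that("REVEL tiers reproduce the printed evidence column for all 33 rows", {
  mm <- study_missense()
  got <- revel_to_evidence(mm$revel)
  expect_equal(got, unname(printed_revel_labels[mm$variant]))
})

test_that("three-way tool calls honor each tool's thresholds", {
  expect_equal(tool_call("polyphen2", 0.02), "benign")
  expect_equal(tool_call("polyphen2", c(0.978, 0.113, 0.5)),
               c("pathogenic", "benign", "undetermined"))
  expect_equal(tool_call("metarnn", c(0.90, 0.85, 0.55, 0.49)),
               c("pathogenic", "pathogenic", "undetermined", "benign"))
  # the 0.5 benign cut is exclusive for MetaRNN/AlphaMissense
  expect_equal(tool_call("metarnn", 0.5), "undetermined")
  expect_equal(tool_call("alphamissense", c(1.0, 0.9, 0.5, 0.44)),
               c("pathogenic", "pathogenic", "undetermined", "benign"))
  expect_equal(tool_call("revel", c(0.644, 0.290, 0.5)),
               c("pathogenic", "benign", "undetermined"))
  expect_error(tool_call("sift", 0.5), "Unknown tool")
  expect_error(tool_call("revel", -0.1), "outside")
})

test_that("concordance profile reproduces the study's per-tool fractions", {
  cp <- concordance_profile(study_missense())
  frac <- function(tool, call) {
    cp$fractions$fraction[cp$fractions$tool == tool &
                            cp$fractions$call == call]
  }
  expect_equal(frac("revel", "pathogenic"), 23 / 33)
  expect_equal(frac("revel", "benign"), 3 / 33)
  expect_equal(frac("revel", "undetermined"), 7 / 33)
  expect_equal(frac("metarnn", "pathogenic"), 21 / 33)
  expect_equal(frac("alphamissense", "pathogenic"), 21 / 33)
  expect_equal(frac("polyphen2", "pathogenic"), 17 / 33)
  expect_equal(frac("polyphen2", "benign"), 5 / 33)
  expect_equal(frac("polyphen2", "undetermined"), 11 / 33)
})

test_that("fractions sum to one per tool and each score yields one call", {
  cp <- concordance_profile(study_missense())
  sums <- tapply(cp$fractions$fraction, cp$fractions$tool, sum)
  expect_true(all(abs(sums - 1) < 1e-12))
  calls <- cp$calls[c("metarnn", "polyphen2", "alphamissense", "revel")]
  expect_true(all(unlist(calls) %in%
                    c("pathogenic", "benign", "undetermined")))
})

test_that("full concordance counts identical determinate calls", {
  cp <- concordance_profile(study_missense())
  expect_equal(cp$n_full_concordance, 14)
  # one row (all four undetermined) separates the two counting rules
  expect_equal(cp$n_identical_calls, 15)
  expect_equal(cp$n_used, 33)

  one <- study_missense()[1, ]
  one$metarnn <- one$polyphen2 <- one$alphamissense <- one$revel <- 1.0
  expect_equal(concordance_profile(one)$n_full_concordance, 1)
})

test_that("variants with missing scores are excluded with a warning", {
  v <- study_missense()
  v$revel[1] <- NA
  expect_warning(cp <- concordance_profile(v), "excluded")
  expect_equal(cp$n_used, 32)
  expect_equal(cp$n_excluded, 1)
})
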
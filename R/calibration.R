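# Calibrated interpretation of in-silico predictor scores. REVEL is the only
# tool that generates classification evidence (PP3/BP4, with a strength
# modifier following the interval calibration of the computational-evidence
# framework); the other three tools produce descriptive three-way calls used
# for the concordance profile only.

#' Calibration table for the four predictors
#'
#' Thresholds are inclusive: a score equal to a pathogenic bound is called
#' pathogenic, a score equal to a benign bound is called benign — except for
#' MetaRNN and AlphaMissense, whose benign cut at 0.5 is exclusive
#' (`score < 0.5`). PolyPhen-2 (0.978 / 0.113) and REVEL (0.644 / 0.290)
#' bounds come from interval calibration of those tools; MetaRNN (0.85) and
#' AlphaMissense (0.9) have published pathogenic cuts only, and their benign
#' cut at 0.5 is this package's convention for concordance accounting.
#' REVEL additionally carries evidence-strength tier bounds: PP3 strong
#' at 0.932, moderate at 0.773, supporting at 0.644; BP4 moderate at 0.183,
#' supporting at 0.290.
#'
#' @return A tibble with one row per tool: `tool`, `pathogenic_ge`,
#'   `benign_le`, `benign_exclusive`.
#' @export
calibration_table <- function() {
  tibble::tibble(
    tool = c("metarnn", "polyphen2", "alphamissense", "revel"),
    pathogenic_ge = c(0.85, 0.978, 0.9, 0.644),
    benign_le = c(0.5, 0.113, 0.5, 0.290),
    benign_exclusive = c(TRUE, FALSE, TRUE, FALSE)
  )
}

REVEL_TIERS <- list(
  pp3_strong = 0.932, pp3_moderate = 0.773, pp3_supporting = 0.644,
  bp4_moderate = 0.183, bp4_supporting = 0.290
)

#' Map a REVEL score to tiered PP3/BP4 evidence
#'
#' Piecewise-constant mapping of a REVEL score to a strength-tiered
#' computational evidence code: `PP3_strong` for scores at or above 0.932,
#' `PP3_moderate` at or above 0.773, `PP3_supporting` at or above 0.644;
#' `BP4_moderate` at or below 0.183, `BP4_supporting` at or below 0.290;
#' anything in the open gap (0.290, 0.644) is `"undetermined"` and
#' generates no evidence. All bounds are inclusive. The mapping is monotone:
#' a higher score never yields weaker pathogenic support or stronger benign
#' support.
#'
#' @param score REVEL score(s) in `[0, 1]`; NA propagates.
#' @return A character vector of the same length with values among
#'   `PP3_strong`, `PP3_moderate`, `PP3_supporting`, `BP4_supporting`,
#'   `BP4_moderate`, `undetermined`.
#' @examples
#' revel_to_evidence(c(0.968, 0.773, 0.14, 0.5))
#' @export
revel_to_evidence <- function(score) {
  if (any(!is.na(score) & (score < 0 | score > 1))) {
    abort("REVEL score outside [0, 1]")
  }
  dplyr::case_when(
    is.na(score) ~ NA_character_,
    score >= REVEL_TIERS$pp3_strong ~ "PP3_strong",
    score >= REVEL_TIERS$pp3_moderate ~ "PP3_moderate",
    score >= REVEL_TIERS$pp3_supporting ~ "PP3_supporting",
    score <= REVEL_TIERS$bp4_moderate ~ "BP4_moderate",
    score <= REVEL_TIERS$bp4_supporting ~ "BP4_supporting",
    .default = "undetermined"
  )
}

#' Three-way categorical call for one predictor
#'
#' @param tool One of `"metarnn"`, `"polyphen2"`, `"alphamissense"`,
#'   `"revel"`.
#' @param score Score(s) in `[0, 1]`; NA propagates.
#' @return Character vector with values `pathogenic`, `benign`,
#'   `undetermined`.
#' @examples
#' tool_call("polyphen2", 0.02)
#' tool_call("revel", 0.644)
#' @export
tool_call <- function(tool, score) {
  cal <- calibration_table()
  row <- cal[cal$tool == tool, ]
  if (nrow(row) != 1) abort(paste0("Unknown tool '", tool, "'"))
  if (any(!is.na(score) & (score < 0 | score > 1))) {
    abort(sprintf("%s score outside [0, 1]", tool))
  }
  benign <- if (row$benign_exclusive) score < row$benign_le else {
    score <= row$benign_le
  }
  dplyr::case_when(
    is.na(score) ~ NA_character_,
    score >= row$pathogenic_ge ~ "pathogenic",
    benign ~ "benign",
    .default = "undetermined"
  )
}

#' Per-tool call profile and four-tool concordance
#'
#' Applies [tool_call()] to all four predictors for every variant and
#' summarises: the fraction of pathogenic / benign / undetermined calls per
#' tool, and the number of variants on which the tools fully agree. Full
#' concordance requires all four tools to make the same determinate call
#' (all pathogenic or all benign); a unanimous "undetermined" is not
#' counted as a concordant prediction, since an undetermined score is an
#' abstention rather than a prediction. The count of rows with four
#' identical calls including unanimous abstentions is also reported.
#' Variants with any missing score are excluded with a warning.
#'
#' @param variants A variant tibble with the four score columns.
#' @return A list with `calls` (per-variant call tibble), `fractions`
#'   (tool x call fractions, summing to 1 per tool), `n_full_concordance`,
#'   `n_identical_calls`, `n_used` and `n_excluded`.
#' @export
concordance_profile <- function(variants) {
  tools <- calibration_table()$tool
  complete <- stats::complete.cases(variants[tools])
  if (any(!complete)) {
    warn(sprintf("%d variant(s) excluded from concordance: missing score(s)",
                 sum(!complete)))
  }
  v <- variants[complete, , drop = FALSE]
  calls <- tibble::tibble(variant = v$variant)
  for (tl in tools) calls[[tl]] <- tool_call(tl, v[[tl]])
  long <- tidyr::pivot_longer(calls, -"variant",
                              names_to = "tool", values_to = "call")
  fractions <- long |>
    dplyr::count(.data$tool, .data$call) |>
    dplyr::group_by(.data$tool) |>
    dplyr::mutate(fraction = .data$n / sum(.data$n)) |>
    dplyr::ungroup() |>
    tidyr::complete(tool = tools,
                    call = c("pathogenic", "benign", "undetermined"),
                    fill = list(n = 0L, fraction = 0)) |>
    dplyr::mutate(fraction = ifelse(is.nan(.data$fraction), 0,
                                    .data$fraction))
  call_mat <- as.matrix(calls[tools])
  identical_rows <- apply(call_mat, 1, function(x) length(unique(x)) == 1)
  determinate <- apply(call_mat, 1, function(x) all(x != "undetermined"))
  list(
    calls = calls,
    fractions = fractions,
    n_full_concordance = sum(identical_rows & determinate),
    n_identical_calls = sum(identical_rows),
    n_used = nrow(calls),
    n_excluded = sum(!complete)
  )
}
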
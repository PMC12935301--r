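# Combination of ACMG/AMP evidence codes into five-tier classifications.
# Two modes: the categorical 2015 rule table, and the point-based refinement
# (very strong 8, strong 4, moderate 2, supporting 1; benign negated).
# Mixed pathogenic/benign evidence is resolved by a configurable policy
# before the categorical rules apply.

CLASS_LEVELS <- c("Benign", "Likely benign", "VUS", "Likely pathogenic",
                  "Pathogenic")

PATHOGENIC_CODES <- c(
  "PVS1", paste0("PS", 1:4), paste0("PM", 1:6), paste0("PP", 1:5)
)
BENIGN_CODES <- c("BA1", paste0("BS", 1:4), paste0("BP", 1:7))
STRENGTH_LEVELS <- c("supporting", "moderate", "strong", "very_strong",
                     "stand_alone")

default_strength <- function(code) {
  dplyr::case_when(
    code == "PVS1" ~ "very_strong",
    code == "BA1" ~ "stand_alone",
    stringr::str_starts(code, "PS") | stringr::str_starts(code, "BS") ~
      "strong",
    stringr::str_starts(code, "PM") ~ "moderate",
    .default = "supporting"   # PP and BP
  )
}

#' Parse a "+"-separated ACMG criteria string
#'
#' Turns a string such as `"PS2+PM2+PP3_moderate"` into an evidence tibble.
#' Each token is an ACMG criterion code, optionally carrying a strength
#' modifier suffix (`_supporting`, `_moderate`, `_strong`); modifiers are
#' only meaningful for the computational criteria PP3/BP4, where they record
#' the REVEL calibration tier. Duplicate criteria, unknown codes, and
#' co-occurring PP3 and BP4 are rejected.
#'
#' @param text Criteria string; empty or NA yields an empty evidence set.
#' @return A tibble with columns `code`, `side` (`"pathogenic"` or
#'   `"benign"`), `strength`.
#' @examples
#' parse_evidence("PS2+PM2+PP3_strong")
#' @export
parse_evidence <- function(text) {
  empty <- tibble::tibble(code = character(), side = character(),
                          strength = character())
  if (length(text) != 1 || is.na(text) || !nzchar(stringr::str_trim(text))) {
    return(empty)
  }
  tokens <- stringr::str_trim(stringr::str_split_1(text, "\\+"))
  m <- stringr::str_match(
    tokens, "^([A-Z]+\\d*)(?:_(supporting|moderate|strong|very_strong))?$"
  )
  if (any(is.na(m[, 1]))) {
    abort(paste0("Malformed evidence token '", tokens[is.na(m[, 1])][1], "'"))
  }
  codes <- m[, 2]
  unknown <- setdiff(codes, c(PATHOGENIC_CODES, BENIGN_CODES))
  if (length(unknown) > 0) {
    abort(paste0("Unknown ACMG criterion '", unknown[1], "'"))
  }
  if (anyDuplicated(codes)) {
    abort("Duplicate ACMG criterion in evidence string")
  }
  tier <- m[, 3]
  if (any(!is.na(tier) & !codes %in% c("PP3", "BP4"))) {
    abort("Strength modifiers are only permitted on PP3/BP4")
  }
  if (all(c("PP3", "BP4") %in% codes)) {
    abort("PP3 and BP4 cannot co-occur in one evidence set")
  }
  tibble::tibble(
    code = codes,
    side = ifelse(codes %in% PATHOGENIC_CODES, "pathogenic", "benign"),
    strength = ifelse(is.na(tier), default_strength(codes), tier)
  )
}

format_evidence <- function(ev) {
  if (nrow(ev) == 0) return("")
  paste(ifelse(
    ev$code %in% c("PP3", "BP4") & ev$strength != "supporting",
    paste0(ev$code, "_", ev$strength), ev$code
  ), collapse = "+")
}

#' Configuration for evidence combination
#'
#' @param mode `"categorical"` (rule table) or `"points"`.
#' @param pp3_tier_handling How a REVEL strength tier on PP3/BP4 enters the
#'   combination: `"collapse_to_supporting"` (the default; the criterion
#'   counts at its nominal supporting level regardless of tier — the
#'   behaviour that reproduces the study classifications) or `"honor_tier"`
#'   (the tier upgrades the criterion's effective strength).
#' @param conflict_policy Resolution of mixed pathogenic/benign evidence in
#'   categorical mode: `"dominant_side_by_points"` (drop the side with the
#'   smaller point mass, ties give VUS; the default, which reproduces the
#'   study's handling of PM2+BS2+BP4 and PS2+PM2+BP4) or `"richards_vus"`
#'   (any mixed-side set is VUS).
#' @param weights Named numeric point weights per strength.
#' @param thresholds Named numeric point cut-offs: total `>= pathogenic_min`
#'   is Pathogenic, `>= likely_pathogenic_min` Likely pathogenic,
#'   `<= benign_max` Benign, `<= likely_benign_max` Likely benign, else VUS.
#' @return A list of class `acmg_config`.
#' @export
acmg_config <- function(mode = c("categorical", "points"),
                        pp3_tier_handling = c("collapse_to_supporting",
                                              "honor_tier"),
                        conflict_policy = c("dominant_side_by_points",
                                            "richards_vus"),
                        weights = c(supporting = 1, moderate = 2, strong = 4,
                                    very_strong = 8, stand_alone = 8),
                        thresholds = c(pathogenic_min = 10,
                                       likely_pathogenic_min = 6,
                                       likely_benign_max = -1,
                                       benign_max = -7)) {
  cfg <- list(
    mode = match.arg(mode),
    pp3_tier_handling = match.arg(pp3_tier_handling),
    conflict_policy = match.arg(conflict_policy),
    weights = weights,
    thresholds = thresholds
  )
  structure(cfg, class = "acmg_config")
}

# Effective strength of each criterion under the configured tier handling.
effective_strength <- function(ev, cfg) {
  if (nrow(ev) == 0) return(character())
  ifelse(
    ev$code %in% c("PP3", "BP4") &
      cfg$pp3_tier_handling == "collapse_to_supporting",
    "supporting", ev$strength
  )
}

evidence_points <- function(ev, cfg) {
  if (nrow(ev) == 0) return(0)
  eff <- effective_strength(ev, cfg)
  w <- unname(cfg$weights[eff])
  sum(ifelse(ev$side == "benign", -w, w))
}

classify_one_side <- function(side, n) {
  # n: named counts by effective strength for a single-side evidence set
  if (side == "pathogenic") {
    vs <- n[["very_strong"]]; s <- n[["strong"]]; m <- n[["moderate"]]
    p <- n[["supporting"]]
    pathogenic <-
      (vs >= 1 && (s >= 1 || m >= 2 || (m == 1 && p >= 1) || p >= 2)) ||
      s >= 2 ||
      (s == 1 && (m >= 3 || (m == 2 && p >= 2) || (m == 1 && p >= 4)))
    if (pathogenic) return("Pathogenic")
    likely <-
      (vs == 1 && m == 1) ||
      (s == 1 && m >= 1 && m <= 2) ||
      (s == 1 && p >= 2) ||
      m >= 3 ||
      (m == 2 && p >= 2) ||
      (m == 1 && p >= 4)
    if (likely) return("Likely pathogenic")
    return("VUS")
  }
  sa <- n[["stand_alone"]]; bs <- n[["strong"]] + n[["moderate"]]
  bp <- n[["supporting"]]
  if (sa >= 1 || bs >= 2) return("Benign")
  if ((bs == 1 && bp >= 1) || bp >= 2) return("Likely benign")
  "VUS"
}

strength_counts <- function(ev, cfg) {
  eff <- effective_strength(ev, cfg)
  counts <- table(factor(eff, levels = STRENGTH_LEVELS))
  setNames(as.integer(counts), STRENGTH_LEVELS)
}

#' Combine evidence with the categorical ACMG rule table
#'
#' Applies the standard combining rules to an evidence set. When evidence
#' from both sides is present, the configured conflict policy is applied
#' first: under `"dominant_side_by_points"` the side with the smaller
#' absolute point mass is dropped (ties yield VUS) and the rules are applied
#' to the dominant side; under `"richards_vus"` any mixed set is VUS. An
#' empty evidence set is VUS.
#'
#' @param ev An evidence tibble from [parse_evidence()], or a criteria
#'   string.
#' @param cfg An [acmg_config()].
#' @return A single classification string: `"Benign"`, `"Likely benign"`,
#'   `"VUS"`, `"Likely pathogenic"` or `"Pathogenic"`.
#' @examples
#' combine_categorical("PS2+PS3+PM2+PP3_moderate")
#' combine_categorical("PM2+BS2+BP4_moderate")
#' @export
combine_categorical <- function(ev, cfg = acmg_config()) {
  if (is.character(ev)) ev <- parse_evidence(ev)
  if (nrow(ev) == 0) return("VUS")
  sides <- unique(ev$side)
  if (length(sides) == 2) {
    if (cfg$conflict_policy == "richards_vus") return("VUS")
    path_mass <- evidence_points(ev[ev$side == "pathogenic", ], cfg)
    benign_mass <- -evidence_points(ev[ev$side == "benign", ], cfg)
    if (path_mass == benign_mass) return("VUS")
    keep <- if (path_mass > benign_mass) "pathogenic" else "benign"
    ev <- ev[ev$side == keep, , drop = FALSE]
  }
  classify_one_side(ev$side[1], strength_counts(ev, cfg))
}

#' Combine evidence with the point system
#'
#' Sums signed point weights over the evidence set (pathogenic positive,
#' benign negative) and maps the total onto the five tiers via the
#' configured thresholds (defaults: Pathogenic at 10 or more, Likely
#' pathogenic 6 to 9, VUS 0 to 5, Likely benign -6 to -1, Benign at -7 or
#' below).
#'
#' @inheritParams combine_categorical
#' @return A list with `classification` and integer `points`.
#' @examples
#' combine_points("PS2+PS3+PM2+PP3_supporting")
#' @export
combine_points <- function(ev, cfg = acmg_config(mode = "points")) {
  if (is.character(ev)) ev <- parse_evidence(ev)
  pts <- evidence_points(ev, cfg)
  th <- cfg$thresholds
  cls <- if (pts >= th[["pathogenic_min"]]) "Pathogenic"
    else if (pts >= th[["likely_pathogenic_min"]]) "Likely pathogenic"
    else if (pts <= th[["benign_max"]]) "Benign"
    else if (pts <= th[["likely_benign_max"]]) "Likely benign"
    else "VUS"
  list(classification = cls, points = pts)
}

#' Compare a classification to a prior ClinVar label
#'
#' Directional comparison under the order Benign < Likely benign < VUS <
#' Likely pathogenic < Pathogenic. `NP` (no ClinVar record) yields
#' `"First classification"`; `CS` (conflicting submissions) is treated as
#' VUS-equivalent for direction; the range label `"P/LP"` is `"Unchanged"`
#' whenever the classification falls inside it.
#'
#' @param classification A classification string or abbreviation
#'   (`P`, `LP`, `VUS`, `LB`, `B`).
#' @param clinvar_label One of `P`, `LP`, `P/LP`, `VUS`, `CS`, `LB`, `B`,
#'   `NP` (NA is treated as `NP`).
#' @return One of `"Unchanged"`, `"Upgraded"`, `"Downgraded"`,
#'   `"First classification"`.
#' @examples
#' compare_to_clinvar("Pathogenic", "VUS")
#' compare_to_clinvar("Likely pathogenic", "P/LP")
#' @export
compare_to_clinvar <- function(classification, clinvar_label) {
  rank_of <- function(x) {
    x <- dplyr::case_when(
      x %in% c("P", "Pathogenic") ~ "Pathogenic",
      x %in% c("LP", "Likely pathogenic") ~ "Likely pathogenic",
      x %in% c("LB", "Likely benign") ~ "Likely benign",
      x %in% c("B", "Benign") ~ "Benign",
      x %in% c("VUS", "CS") ~ "VUS",
      .default = NA_character_
    )
    match(x, CLASS_LEVELS)
  }
  ours <- rank_of(classification)
  if (is.na(ours)) abort(paste0("Unknown classification '",
                                classification, "'"))
  if (is.na(clinvar_label) || clinvar_label == "NP") {
    return("First classification")
  }
  if (clinvar_label == "P/LP") {
    lo <- rank_of("LP"); hi <- rank_of("P")
    if (ours >= lo && ours <= hi) return("Unchanged")
    return(if (ours < lo) "Downgraded" else "Upgraded")
  }
  theirs <- rank_of(clinvar_label)
  if (is.na(theirs)) abort(paste0("Unknown ClinVar label '",
                                  clinvar_label, "'"))
  if (ours == theirs) "Unchanged"
  else if (ours > theirs) "Upgraded"
  else "Downgraded"
}

# Evidence set for one variant: asserted criteria with any PP3/BP4 replaced
# by the REVEL-calibrated tiered code (the calibration module is the sole
# source of computational evidence).
variant_evidence <- function(evidence_string, revel_score) {
  ev <- parse_evidence(evidence_string)
  ev <- ev[!ev$code %in% c("PP3", "BP4"), , drop = FALSE]
  if (!is.na(revel_score)) {
    tier <- revel_to_evidence(revel_score)
    if (tier != "undetermined") {
      parts <- stringr::str_split_1(tier, "_")
      ev <- dplyr::bind_rows(ev, tibble::tibble(
        code = parts[1],
        side = ifelse(parts[1] == "PP3", "pathogenic", "benign"),
        strength = parts[2]
      ))
    }
  }
  ev
}

#' Classify every variant in a table
#'
#' Builds each variant's evidence set as the union of its asserted
#' (curated) criteria and the REVEL-calibrated PP3/BP4 code, then combines
#' it under the configured mode. Returns a per-variant verdict table of
#' class `chd4_classification` with the class histogram, evidence strings
#' and ClinVar comparison attached.
#'
#' @param variants A variant tibble (see [read_variant_table()]).
#' @param cfg An [acmg_config()].
#' @return A tibble of class `chd4_classification` with columns `variant`,
#'   `type`, `evidence`, `revel_evidence`, `classification`, `points`
#'   (points mode only contributes non-NA values), `clinvar`, `comparison`.
#'   Use [glance()] for the class histogram.
#' @examples
#' classify_variants(chd4_variants()) |> glance()
#' @export
classify_variants <- function(variants, cfg = acmg_config()) {
  if (nrow(variants) == 0) {
    out <- tibble::tibble(
      variant = character(), type = character(), evidence = character(),
      revel_evidence = character(), classification = character(),
      points = numeric(), clinvar = character(), comparison = character()
    )
    class(out) <- c("chd4_classification", class(out))
    attr(out, "cfg") <- cfg
    return(out)
  }
  rows <- purrr::pmap(
    list(variants$variant, variants$evidence,
         variants$revel, variants$clinvar),
    function(id, evidence_string, revel, clinvar) {
      ev <- variant_evidence(evidence_string, revel)
      if (cfg$mode == "points") {
        res <- combine_points(ev, cfg)
        cls <- res$classification
        pts <- res$points
      } else {
        cls <- combine_categorical(ev, cfg)
        pts <- NA_real_
      }
      tibble::tibble(
        variant = id,
        evidence = format_evidence(ev),
        revel_evidence = if (is.na(revel)) NA_character_ else {
          revel_to_evidence(revel)
        },
        classification = cls,
        points = pts,
        clinvar = clinvar,
        comparison = compare_to_clinvar(cls, clinvar)
      )
    }
  )
  out <- dplyr::bind_rows(rows)
  out <- dplyr::bind_cols(tibble::tibble(type = variants$type), out) |>
    dplyr::relocate("variant")
  class(out) <- c("chd4_classification", class(out))
  attr(out, "cfg") <- cfg
  out
}

#' Histogram of classifications
#'
#' @param classified A `chd4_classification` tibble.
#' @return A named integer vector over the five classes (zero counts kept).
#' @export
class_histogram <- function(classified) {
  counts <- table(factor(classified$classification, levels = CLASS_LEVELS))
  setNames(as.integer(counts), CLASS_LEVELS)
}
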
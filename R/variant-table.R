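# Reading, validating and writing the tab-separated variant table that every
# pipeline stage consumes. One row per variant; protein-level coordinates
# come from parsing the `variant` column.

MANDATORY_COLUMNS <- c(
  "variant", "type", "metarnn", "polyphen2", "alphamissense", "revel",
  "evidence", "clinvar", "heart_anomaly"
)
VARIANT_TYPES <- c("missense", "splice_donor", "inframe_dup", "inframe_del")
CLINVAR_LABELS <- c("P", "LP", "P/LP", "VUS", "CS", "LB", "B", "NP")
SCORE_COLUMNS <- c("metarnn", "polyphen2", "alphamissense", "revel")

#' Read a variant table from TSV
#'
#' Reads a UTF-8, header-rowed, tab-separated variant table (lines starting
#' with `#` are comments), validates every row, and parses protein HGVS
#' notation into residue coordinates. Mandatory columns are `variant`,
#' `type`, the four predictor scores (`metarnn`, `polyphen2`,
#' `alphamissense`, `revel`), `evidence` (a `+`-separated ACMG criteria
#' string), `clinvar` and `heart_anomaly`; any additional columns are
#' preserved.
#'
#' @param path Path to a TSV file.
#' @param protein_length Residue bound used to validate coordinates.
#' @return A validated tibble, one row per input row, with parsed columns
#'   `ref_aa`, `alt_aa`, `residue_start`, `residue_end` appended (NA for the
#'   splice-donor variant, which has no protein span).
#' @seealso [chd4_variants()] for the packaged study table.
#' @export
read_variant_table <- function(path, protein_length = CHD4_LENGTH) {
  tab <- readr::read_tsv(
    path, comment = "#", show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(.default = readr::col_character())
  )
  missing <- setdiff(MANDATORY_COLUMNS, names(tab))
  if (length(missing) > 0) {
    abort(paste0("Variant table is missing mandatory column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (nrow(tab) == 0) {
    return(validate_variants(parse_variant_columns(tab, protein_length)))
  }
  for (col in c(SCORE_COLUMNS, "gnomad_af")) {
    if (!col %in% names(tab)) next
    raw <- tab[[col]]
    parsed <- suppressWarnings(as.numeric(raw))
    bad <- which(!is.na(raw) & nzchar(raw) & is.na(parsed))
    if (length(bad) > 0) {
      abort(sprintf("Row %d: cannot parse %s score '%s' as a number",
                    bad[1], col, raw[bad[1]]))
    }
    tab[[col]] <- parsed
  }
  validate_variants(parse_variant_columns(tab, protein_length))
}

parse_variant_columns <- function(tab, protein_length = CHD4_LENGTH) {
  if (nrow(tab) == 0) {
    return(dplyr::mutate(
      tab,
      ref_aa = character(), alt_aa = character(),
      residue_start = integer(), residue_end = integer()
    ))
  }
  parsed <- purrr::map2(tab$variant, tab$type, function(v, ty) {
    if (identical(ty, "splice_donor")) {
      tibble::tibble(ref_aa = NA_character_, alt_aa = NA_character_,
                     residue_start = NA_integer_, residue_end = NA_integer_)
    } else {
      p <- parse_protein_change(v, protein_length)
      tibble::tibble(ref_aa = p$ref_aa, alt_aa = p$alt_aa,
                     residue_start = p$residue_start,
                     residue_end = p$residue_end)
    }
  })
  dplyr::bind_cols(tab, dplyr::bind_rows(parsed))
}

#' Validate a variant tibble
#'
#' Checks the row-level invariants of the variant schema: known variant
#' type, scores and allele frequencies inside `[0, 1]`, residue spans inside
#' the protein, missense rows confined to a single residue with reference
#' and alternate amino acids, a protein span for every non-splice variant,
#' a cDNA string for the splice-donor variant, and controlled vocabularies
#' for `clinvar` and `heart_anomaly`.
#'
#' @param variants A variant tibble (as produced by [read_variant_table()]).
#' @param protein_length Residue bound.
#' @return The input, invisibly unchanged, for piping; errors name the
#'   offending row.
#' @export
validate_variants <- function(variants, protein_length = CHD4_LENGTH) {
  v <- variants
  fail <- function(i, msg) {
    abort(sprintf("Variant row %d (%s): %s", i, v$variant[i], msg))
  }
  for (i in seq_len(nrow(v))) {
    if (!v$type[i] %in% VARIANT_TYPES) {
      fail(i, paste0("unknown variant type '", v$type[i], "'"))
    }
    for (col in intersect(c(SCORE_COLUMNS, "gnomad_af"), names(v))) {
      x <- v[[col]][i]
      if (!is.na(x) && (x < 0 || x > 1)) {
        fail(i, sprintf("%s = %g is outside [0, 1]", col, x))
      }
    }
    if (!is.na(v$clinvar[i]) && !v$clinvar[i] %in% CLINVAR_LABELS) {
      fail(i, paste0("unknown ClinVar label '", v$clinvar[i], "'"))
    }
    if (!v$heart_anomaly[i] %in% c("yes", "no", "unknown")) {
      fail(i, paste0("heart_anomaly must be yes/no/unknown, got '",
                     v$heart_anomaly[i], "'"))
    }
    if (v$type[i] == "splice_donor") {
      if (!"cdna" %in% names(v) || is.na(v$cdna[i]) || !nzchar(v$cdna[i])) {
        fail(i, "splice-donor variant requires a cdna string")
      }
      next
    }
    if (is.na(v$residue_start[i]) || is.na(v$residue_end[i])) {
      fail(i, "non-splice variant requires a protein span")
    }
    if (v$residue_start[i] > v$residue_end[i] ||
        v$residue_start[i] < 1 || v$residue_end[i] > protein_length) {
      fail(i, sprintf("span [%d, %d] is invalid for a %d-residue protein",
                      v$residue_start[i], v$residue_end[i], protein_length))
    }
    if (v$type[i] == "missense") {
      if (v$residue_start[i] != v$residue_end[i]) {
        fail(i, "missense variant must span a single residue")
      }
      if (is.na(v$ref_aa[i]) || !nzchar(v$ref_aa[i]) ||
          is.na(v$alt_aa[i]) || !nzchar(v$alt_aa[i])) {
        fail(i, "missense variant requires ref and alt amino acids")
      }
    }
  }
  invisible(variants)
}

#' Write a variant table to TSV
#'
#' Inverse of [read_variant_table()]: drops the parsed helper columns and
#' writes the remaining columns as tab-separated UTF-8 with a header row, so
#' that reading the result back reproduces the original tibble.
#'
#' @param variants A variant tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_variant_table <- function(variants, path) {
  out <- dplyr::select(
    variants,
    -dplyr::any_of(c("ref_aa", "alt_aa", "residue_start", "residue_end"))
  )
  readr::write_tsv(out, path, na = "", progress = FALSE)
  invisible(path)
}

#' The packaged 36-variant CHD4 study table
#'
#' Loads the transcription of the study's printed variant table: 33
#' missense variants with predictor scores and ACMG criteria strings, plus
#' one splice-donor variant (`c.1686+1G>T`), one in-frame duplication
#' (`p.L1009_V1011dup`) and one in-frame deletion (`p.C1012del`). See the
#' fixture header (`system.file("extdata", "chd4_table1.tsv", package =
#' "chd4var")`) for provenance notes, including which per-variant
#' heart-anomaly flags are editorial.
#'
#' @return A validated 36-row variant tibble.
#' @examples
#' chd4_variants() |> dplyr::count(type)
#' @export
chd4_variants <- function() {
  read_variant_table(
    system.file("extdata", "chd4_table1.tsv", package = "chd4var")
  )
}

#' Filter variants on population allele frequency
#'
#' Removes variants whose gnomAD allele frequency exceeds `af_threshold`;
#' variants with no recorded frequency (absent from the population
#' database) are kept. The default threshold of 0.001 is the rare-variant
#' cut used to select the study cohort.
#'
#' @param variants A variant tibble with an optional `gnomad_af` column.
#' @param af_threshold Frequency threshold in `(0, 1)`.
#' @return A list with tibbles `kept` and `removed`.
#' @export
frequency_filter <- function(variants, af_threshold = 0.001) {
  stopifnot(af_threshold > 0, af_threshold < 1)
  af <- if ("gnomad_af" %in% names(variants)) variants$gnomad_af else {
    rep(NA_real_, nrow(variants))
  }
  drop <- !is.na(af) & af > af_threshold
  list(kept = variants[!drop, , drop = FALSE],
       removed = variants[drop, , drop = FALSE])
}
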
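# Protein-level HGVS parsing. Only the grammar needed for the study is
# implemented: single-residue substitutions ("p.M202I", "p.Met202Ile"),
# in-frame duplications and deletions of a residue or residue span
# ("p.L1009_V1011dup", "p.C1012del"). No cDNA validation beyond pattern
# capture, and no genomic coordinates.

AA_THREE_TO_ONE <- c(
  Ala = "A", Arg = "R", Asn = "N", Asp = "D", Cys = "C", Gln = "Q",
  Glu = "E", Gly = "G", His = "H", Ile = "I", Leu = "L", Lys = "K",
  Met = "M", Phe = "F", Pro = "P", Ser = "S", Thr = "T", Trp = "W",
  Tyr = "Y", Val = "V"
)
AA_ONE <- unname(AA_THREE_TO_ONE)

# Accepts a one-letter or three-letter amino-acid token, returns one-letter.
normalize_aa <- function(token, context) {
  if (token %in% AA_ONE) return(token)
  three <- paste0(
    toupper(substr(token, 1, 1)), tolower(substr(token, 2, nchar(token)))
  )
  if (three %in% names(AA_THREE_TO_ONE)) {
    return(unname(AA_THREE_TO_ONE[three]))
  }
  abort(sprintf("Unrecognized amino-acid code '%s' in '%s'", token, context))
}

check_residue <- function(pos, text, protein_length) {
  if (pos < 1L || pos > protein_length) {
    abort(sprintf(
      "Residue %d in '%s' is outside the protein bounds [1, %d]",
      pos, text, protein_length
    ))
  }
  pos
}

#' Parse a protein-level HGVS string
#'
#' Parses substitutions (`p.M202I`), in-frame duplications
#' (`p.Leu1009_Val1011dup`) and in-frame deletions (`p.C1012del`) into a
#' normalized one-letter record. Three-letter amino-acid codes are accepted
#' and converted; the leading `p.` is optional. A substitution whose
#' reference and alternate residues coincide is flagged as synonymous at the
#' protein level rather than rejected.
#'
#' @param text A single HGVS-like protein string.
#' @param protein_length Upper bound on residue coordinates (defaults to the
#'   1912-residue CHD4 protein).
#' @return A one-row tibble with columns `ref_aa`, `residue_start`,
#'   `residue_end`, `alt_aa`, `vtype` (one of `"missense"`, `"inframe_dup"`,
#'   `"inframe_del"`) and `synonymous` (logical).
#' @examples
#' parse_protein_change("p.M202I")
#' parse_protein_change("p.Leu1009_Val1011dup")
#' @export
parse_protein_change <- function(text, protein_length = CHD4_LENGTH) {
  stopifnot(is.character(text), length(text) == 1L)
  raw <- text
  s <- stringr::str_trim(text)
  s <- stringr::str_remove(s, "^p\\.\\s*")
  if (!nzchar(s)) abort("Empty protein change string")

  aa_pat <- "([A-Za-z]{1,3})"
  span_pat <- paste0("^", aa_pat, "(\\d+)(?:_", aa_pat, "(\\d+))?(dup|del)$")
  sub_pat <- paste0("^", aa_pat, "(\\d+)", aa_pat, "$")

  m <- stringr::str_match(s, span_pat)
  if (!is.na(m[1, 1])) {
    start <- check_residue(as.integer(m[1, 3]), raw, protein_length)
    end <- if (is.na(m[1, 5])) start else {
      check_residue(as.integer(m[1, 5]), raw, protein_length)
    }
    if (start > end) {
      abort(sprintf("Span start %d exceeds end %d in '%s'", start, end, raw))
    }
    ref <- normalize_aa(m[1, 2], raw)
    ref_end <- if (is.na(m[1, 4])) "" else normalize_aa(m[1, 4], raw)
    vtype <- if (m[1, 6] == "dup") "inframe_dup" else "inframe_del"
    return(tibble::tibble(
      ref_aa = ref, ref_aa_end = ref_end, residue_start = start,
      residue_end = end, alt_aa = "", vtype = vtype, synonymous = FALSE
    ))
  }

  m <- stringr::str_match(s, sub_pat)
  if (!is.na(m[1, 1])) {
    pos <- check_residue(as.integer(m[1, 3]), raw, protein_length)
    ref <- normalize_aa(m[1, 2], raw)
    alt <- normalize_aa(m[1, 4], raw)
    return(tibble::tibble(
      ref_aa = ref, ref_aa_end = "", residue_start = pos, residue_end = pos,
      alt_aa = alt, vtype = "missense", synonymous = ref == alt
    ))
  }

  abort(sprintf("Cannot parse protein change '%s': unrecognized token '%s'",
                raw, s))
}

#' Format a parsed protein change back to HGVS
#'
#' Inverse of [parse_protein_change()] on its normalized output: one-letter
#' codes with a `p.` prefix.
#'
#' @param change A one-row data frame as returned by [parse_protein_change()].
#' @return A single string such as `"p.M202I"` or `"p.L1009_V1011dup"`.
#' @export
format_protein_change <- function(change) {
  stopifnot(nrow(change) == 1L)
  with(change, {
    if (vtype == "missense") {
      sprintf("p.%s%d%s", ref_aa, residue_start, alt_aa)
    } else {
      suffix <- if (vtype == "inframe_dup") "dup" else "del"
      if (residue_start == residue_end) {
        sprintf("p.%s%d%s", ref_aa, residue_start, suffix)
      } else {
        sprintf("p.%s%d_%s%d%s", ref_aa, residue_start, ref_aa_end,
                residue_end, suffix)
      }
    }
  })
}
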
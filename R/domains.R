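# The CHD4 domain architecture as named residue intervals, plus interval
# location and region counting. The architecture ships as a versioned TSV so
# other proteins can be described in the same format.

#' Read a domain architecture TSV
#'
#' The format is tab-separated with columns `name`, `parent`, `start`,
#' `end`, `role` (`domain` for top-level non-overlapping regions,
#' `subdomain` for nested intervals, `composite` for named unions used only
#' for grouping) and free-text `note`. Invariants checked: coordinates
#' within `[1, protein_length]`, top-level domains pairwise disjoint,
#' subdomains contained in their parent.
#'
#' @param path TSV path.
#' @param protein_length Protein residue bound.
#' @return A tibble with one interval per row and a `width` column.
#' @export
read_domain_architecture <- function(path, protein_length = CHD4_LENGTH) {
  arch <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                          progress = FALSE)
  stopifnot(all(c("name", "parent", "start", "end", "role") %in% names(arch)))
  arch <- dplyr::mutate(
    arch,
    start = as.integer(.data$start), end = as.integer(.data$end),
    width = .data$end - .data$start + 1L
  )
  bad <- arch$start < 1 | arch$end > protein_length | arch$start > arch$end
  if (any(bad)) {
    abort(paste0("Invalid interval for domain '", arch$name[bad][1], "'"))
  }
  top <- arch[arch$role == "domain", ]
  if (nrow(top) > 1) {
    o <- order(top$start)
    if (any(top$start[o][-1] <= top$end[o][-nrow(top)])) {
      abort("Top-level domains overlap")
    }
  }
  sub <- arch[arch$role == "subdomain" & !is.na(arch$parent), ]
  for (i in seq_len(nrow(sub))) {
    par <- arch[arch$name == sub$parent[i], ]
    if (nrow(par) == 1 &&
        (sub$start[i] < par$start || sub$end[i] > par$end)) {
      abort(paste0("Subdomain '", sub$name[i],
                   "' is not contained in its parent"))
    }
  }
  arch
}

#' The packaged CHD4 domain architecture
#'
#' Residue intervals of the 1912-aa CHD4 protein: the N-terminal region
#' (1-354, containing the approximate 82-aa HMG box), PHD fingers (363-410,
#' 442-482), chromodomains (522-579, 615-676), the bilobed SNF2-family
#' motor (ATPase 731-915, helicase 1047-1192) with the composite
#' `ATPase_motor_region` spanning 731-1192, and the C-terminal region
#' (1230-1912) with its CTD1/CTD2 subregions, disordered linkers and the
#' `APR2` aggregation-prone region (1735-1742).
#'
#' @return An architecture tibble (see [read_domain_architecture()]).
#' @export
chd4_domains <- function() {
  read_domain_architecture(
    system.file("extdata", "chd4_domains.tsv", package = "chd4var")
  )
}

#' Locate a residue span in the architecture
#'
#' Returns all architecture intervals intersecting the span, most specific
#' (smallest) first, ties broken by start coordinate. The `assignment` is
#' the smallest intersecting non-composite interval; a span hitting no
#' domain or subdomain is assigned `"interdomain(left,right)"` naming the
#' flanking top-level domains (composite regions still appear among the
#' hits).
#'
#' @param residue_start,residue_end 1-based inclusive span inside the
#'   protein.
#' @param arch Architecture tibble; defaults to [chd4_domains()].
#' @param protein_length Protein residue bound.
#' @return A list with `hits` (intersecting intervals, most specific first)
#'   and `assignment` (a single name).
#' @examples
#' locate_domain(467, 467)$assignment
#' locate_domain(1000, 1000)$assignment
#' @export
locate_domain <- function(residue_start, residue_end = residue_start,
                          arch = chd4_domains(),
                          protein_length = CHD4_LENGTH) {
  if (residue_start < 1 || residue_end > protein_length ||
      residue_start > residue_end) {
    abort(sprintf("Span [%s, %s] is outside the protein bounds [1, %d]",
                  residue_start, residue_end, protein_length))
  }
  hits <- arch |>
    dplyr::filter(.data$start <= residue_end, .data$end >= residue_start) |>
    dplyr::arrange(.data$width, .data$start)
  concrete <- dplyr::filter(hits, .data$role != "composite")
  assignment <- if (nrow(concrete) > 0) concrete$name[1] else {
    top <- arch[arch$role == "domain", ]
    left <- top[top$end < residue_start, ]
    right <- top[top$start > residue_end, ]
    sprintf(
      "interdomain(%s,%s)",
      if (nrow(left) > 0) left$name[which.max(left$end)] else "N_end",
      if (nrow(right) > 0) right$name[which.min(right$start)] else "C_end"
    )
  }
  list(hits = hits, assignment = assignment)
}

#' Annotate variants with their domain assignment
#'
#' @param variants A variant tibble with `residue_start`/`residue_end`
#'   columns; splice variants (no protein span) are assigned
#'   `"no_protein_span"`.
#' @param arch Architecture tibble.
#' @return The input with a `domain` column appended.
#' @export
annotate_domains <- function(variants, arch = chd4_domains()) {
  assignment <- purrr::map2_chr(
    variants$residue_start, variants$residue_end,
    function(s, e) {
      if (is.na(s)) return("no_protein_span")
      locate_domain(s, e, arch)$assignment
    }
  )
  dplyr::mutate(variants, domain = assignment)
}

#' Count variants intersecting a named region
#'
#' A variant counts when its protein span intersects the region's interval;
#' variants without a protein span (the splice-donor variant) never count.
#'
#' @param variants A variant tibble.
#' @param region A region name present in the architecture (composites
#'   allowed, e.g. `"ATPase_motor_region"`).
#' @param arch Architecture tibble.
#' @return An integer count.
#' @examples
#' count_by_region(chd4_variants(), "ATPase_motor_region")
#' @export
count_by_region <- function(variants, region, arch = chd4_domains()) {
  row <- arch[arch$name == region, ]
  if (nrow(row) != 1) abort(paste0("Unknown region '", region, "'"))
  sum(!is.na(variants$residue_start) &
        variants$residue_start <= row$end &
        variants$residue_end >= row$start)
}

#' Does each variant intersect a region?
#'
#' Vectorised membership used to group variants for enrichment; spanless
#' variants give NA.
#'
#' @inheritParams count_by_region
#' @return A logical vector along the rows of `variants`.
#' @export
in_region <- function(variants, region, arch = chd4_domains()) {
  row <- arch[arch$name == region, ]
  if (nrow(row) != 1) abort(paste0("Unknown region '", region, "'"))
  ifelse(
    is.na(variants$residue_start), NA,
    variants$residue_start <= row$end & variants$residue_end >= row$start
  )
}
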
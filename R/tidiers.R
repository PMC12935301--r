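# broom-style tidiers for the package's result objects.

#' Tidy a classification table
#'
#' @param x A `chd4_classification` tibble.
#' @param ... Unused.
#' @return A plain tibble with one row per variant.
#' @export
tidy.chd4_classification <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "chd4_classification")
  attr(out, "cfg") <- NULL
  out
}

#' One-row summary of a classification table
#'
#' @param x A `chd4_classification` tibble.
#' @param ... Unused.
#' @return A one-row tibble: counts per class, number of variants, and the
#'   combination mode used.
#' @export
glance.chd4_classification <- function(x, ...) {
  h <- class_histogram(x)
  cfg <- attr(x, "cfg")
  tibble::tibble(
    n = nrow(x),
    pathogenic = h[["Pathogenic"]],
    likely_pathogenic = h[["Likely pathogenic"]],
    vus = h[["VUS"]],
    likely_benign = h[["Likely benign"]],
    benign = h[["Benign"]],
    mode = if (is.null(cfg)) NA_character_ else cfg$mode
  )
}

#' Tidy an enrichment result
#'
#' @param x A `chd4_enrichment` object.
#' @param ... Unused.
#' @return A one-row tibble: the four cells, p-value, odds ratio and
#'   confidence bounds.
#' @export
tidy.chd4_enrichment <- function(x, ...) {
  tibble::tibble(
    a = x$table[1, 1], b = x$table[1, 2],
    c = x$table[2, 1], d = x$table[2, 2],
    p_two_sided = x$p_two_sided,
    odds_ratio = x$odds_ratio,
    ci_low = x$ci_low, ci_high = x$ci_high,
    alpha = x$alpha,
    excluded_unknowns = x$excluded_unknowns
  )
}

#' @rdname tidy.chd4_enrichment
#' @export
glance.chd4_enrichment <- function(x, ...) tidy.chd4_enrichment(x)
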
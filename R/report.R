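# End-to-end orchestration: frequency filter -> calibration -> ACMG engine
# -> ClinVar comparison -> domain mapping -> enrichment, collected into a
# single reproducible report object. Every number in the report is
# recomputable from the input table and the configuration.

REPORT_SCHEMA_VERSION <- "1.0"

#' Run the full interpretation pipeline
#'
#' Filters on allele frequency, classifies every retained variant, maps
#' variants onto the domain architecture, profiles predictor concordance
#' (over variants with all four scores), tallies ClinVar comparisons and
#' computes the heart-anomaly enrichment both from the per-variant flags
#' and from the recorded group-level study counts
#' ([chd4_anomaly_counts()]).
#'
#' @param variants A variant tibble; defaults to the packaged study table.
#' @param cfg An [acmg_config()].
#' @param region Region for the enrichment contrast.
#' @param arch Domain architecture.
#' @param af_threshold Allele-frequency filter threshold.
#' @return A list of class `chd4_report`: `input_summary`,
#'   `classifications` (a `chd4_classification` tibble with a `domain`
#'   column), `histogram`, `concordance`, `clinvar_comparison`,
#'   `enrichment` (from per-variant flags), `enrichment_recorded` (from the
#'   recorded group counts), `config`, `schema_version`.
#' @examples
#' rep <- chd4_report()
#' rep$histogram
#' @export
chd4_report <- function(variants = chd4_variants(), cfg = acmg_config(),
                        region = "ATPase_motor_region",
                        arch = chd4_domains(), af_threshold = 0.001) {
  filtered <- frequency_filter(variants, af_threshold)
  v <- filtered$kept
  classified <- classify_variants(v, cfg)
  classified$domain <- annotate_domains(v, arch)$domain
  missense <- v[v$type == "missense", , drop = FALSE]
  concordance <- if (nrow(missense) > 0) concordance_profile(missense) else {
    NULL
  }
  enr <- if (nrow(v) > 0) enrich(v, region, arch) else NULL
  counts <- chd4_anomaly_counts()
  enr_recorded <- enrich_table(counts[["a"]], counts[["b"]],
                               counts[["c"]], counts[["d"]])
  structure(
    list(
      input_summary = list(
        n_input = nrow(variants),
        n_removed_by_af = nrow(filtered$removed),
        by_type = as.list(table(v$type))
      ),
      classifications = classified,
      histogram = class_histogram(classified),
      concordance = concordance,
      clinvar_comparison = as.list(table(classified$comparison)),
      enrichment = enr,
      enrichment_recorded = enr_recorded,
      config = cfg,
      schema_version = REPORT_SCHEMA_VERSION
    ),
    class = "chd4_report"
  )
}

#' @export
print.chd4_report <- function(x, ...) {
  cat("CHD4 variant interpretation report (schema ",
      x$schema_version, ")\n", sep = "")
  cat("Input: ", x$input_summary$n_input, " variant(s), ",
      x$input_summary$n_removed_by_af, " removed by frequency filter\n",
      sep = "")
  cat("Classification histogram:\n")
  print(x$histogram)
  if (!is.null(x$concordance)) {
    cat(sprintf("Four-tool full concordance: %d/%d\n",
                x$concordance$n_full_concordance, x$concordance$n_used))
  }
  cat("ClinVar comparison:\n")
  print(unlist(x$clinvar_comparison))
  if (!is.null(x$enrichment)) print(x$enrichment)
  invisible(x)
}

report_to_list <- function(report) {
  enr_list <- function(e) {
    if (is.null(e)) return(NULL)
    list(table = as.vector(t(e$table)), p_two_sided = e$p_two_sided,
         odds_ratio = e$odds_ratio, ci_low = e$ci_low, ci_high = e$ci_high,
         excluded_unknowns = e$excluded_unknowns)
  }
  list(
    schema_version = report$schema_version,
    input_summary = report$input_summary,
    histogram = as.list(report$histogram),
    classifications = as.data.frame(report$classifications),
    concordance = if (!is.null(report$concordance)) list(
      fractions = as.data.frame(report$concordance$fractions),
      n_full_concordance = report$concordance$n_full_concordance,
      n_identical_calls = report$concordance$n_identical_calls,
      n_used = report$concordance$n_used
    ),
    clinvar_comparison = report$clinvar_comparison,
    enrichment = enr_list(report$enrichment),
    enrichment_recorded = enr_list(report$enrichment_recorded),
    config = list(mode = report$config$mode,
                  pp3_tier_handling = report$config$pp3_tier_handling,
                  conflict_policy = report$config$conflict_policy)
  )
}

#' Write a report as JSON
#'
#' Serialises a `chd4_report` to a stable, versioned JSON document;
#' re-running the pipeline on identical inputs writes an identical file.
#'
#' @param report A `chd4_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(report_to_list(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")
  invisible(path)
}

#' Write the per-variant report as TSV
#'
#' @param report A `chd4_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_tsv <- function(report, path) {
  readr::write_tsv(report$classifications, path, na = "", progress = FALSE)
  invisible(path)
}

#' Read an ACMG configuration from a YAML file
#'
#' Recognised keys: `mode`, `pp3_tier_handling`, `conflict_policy`,
#' `weights`, `thresholds`; missing keys keep the [acmg_config()] defaults.
#'
#' @param path YAML file path.
#' @return An [acmg_config()].
#' @export
read_acmg_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    abort("Package 'yaml' is required to read configuration files")
  }
  raw <- yaml::read_yaml(path)
  defaults <- acmg_config()
  acmg_config(
    mode = raw$mode %||% defaults$mode,
    pp3_tier_handling = raw$pp3_tier_handling %||%
      defaults$pp3_tier_handling,
    conflict_policy = raw$conflict_policy %||% defaults$conflict_policy,
    weights = if (!is.null(raw$weights)) unlist(raw$weights) else {
      defaults$weights
    },
    thresholds = if (!is.null(raw$thresholds)) unlist(raw$thresholds) else {
      defaults$thresholds
    }
  )
}
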
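# Shared fixtures: the packaged study table, its missense subset, and the
# printed per-row columns it must reproduce (transcribed once here, frozen).

study_variants <- function() chd4_variants()

study_missense <- function() {
  v <- chd4_variants()
  v[v$type == "missense", , drop = FALSE]
}

# Printed REVEL evidence labels, one per missense row (fixture order).
printed_revel_labels <- c(
  "p.P8S" = "undetermined", "p.M202I" = "PP3_moderate",
  "p.P286A" = "BP4_supporting", "p.C467Y" = "PP3_strong",
  "p.T494M" = "BP4_moderate", "p.K533E" = "undetermined",
  "p.K810N" = "undetermined", "p.S851Y" = "PP3_strong",
  "p.R887W" = "PP3_moderate", "p.M954I" = "PP3_moderate",
  "p.M954V" = "PP3_strong", "p.M966K" = "PP3_moderate",
  "p.R992Q" = "PP3_supporting", "p.G1003D" = "PP3_moderate",
  "p.N1020S" = "PP3_moderate", "p.R1068H" = "PP3_strong",
  "p.E1094K" = "PP3_strong", "p.D1147E" = "PP3_moderate",
  "p.W1148L" = "PP3_supporting", "p.A1178V" = "undetermined",
  "p.R1183H" = "PP3_supporting", "p.R1183C" = "PP3_moderate",
  "p.A1188V" = "PP3_moderate", "p.M1192R" = "PP3_moderate",
  "p.Y1249D" = "PP3_moderate", "p.Y1345D" = "PP3_moderate",
  "p.R1419H" = "PP3_moderate", "p.V1608I" = "BP4_moderate",
  "p.E1646K" = "undetermined", "p.D1659E" = "undetermined",
  "p.I1741V" = "undetermined", "p.Y1758C" = "PP3_supporting",
  "p.P1880S" = "PP3_moderate"
)

# Printed five-tier verdicts for the 33 missense rows.
printed_classifications <- c(
  "p.P8S" = "VUS", "p.M202I" = "Pathogenic", "p.P286A" = "VUS",
  "p.C467Y" = "Pathogenic", "p.T494M" = "Likely benign",
  "p.K533E" = "Likely pathogenic", "p.K810N" = "Likely pathogenic",
  "p.S851Y" = "Likely pathogenic", "p.R887W" = "Likely pathogenic",
  "p.M954I" = "Likely pathogenic", "p.M954V" = "Pathogenic",
  "p.M966K" = "Likely pathogenic", "p.R992Q" = "Pathogenic",
  "p.G1003D" = "Pathogenic", "p.N1020S" = "Likely pathogenic",
  "p.R1068H" = "Pathogenic", "p.E1094K" = "Pathogenic",
  "p.D1147E" = "Likely pathogenic", "p.W1148L" = "Likely pathogenic",
  "p.A1178V" = "Likely pathogenic", "p.R1183H" = "Likely pathogenic",
  "p.R1183C" = "Likely pathogenic", "p.A1188V" = "Likely pathogenic",
  "p.M1192R" = "Likely pathogenic", "p.Y1249D" = "Likely pathogenic",
  "p.Y1345D" = "Likely pathogenic", "p.R1419H" = "Likely pathogenic",
  "p.V1608I" = "Likely pathogenic", "p.E1646K" = "Likely pathogenic",
  "p.D1659E" = "VUS", "p.I1741V" = "VUS", "p.Y1758C" = "VUS",
  "p.P1880S" = "VUS"
)

# Printed ClinVar-comparison categories for the 33 missense rows.
printed_comparisons <- c(
  "p.P8S" = "Downgraded", "p.M202I" = "Upgraded",
  "p.P286A" = "First classification", "p.C467Y" = "First classification",
  "p.T494M" = "Downgraded", "p.K533E" = "Upgraded",
  "p.K810N" = "First classification", "p.S851Y" = "Downgraded",
  "p.R887W" = "Downgraded", "p.M954I" = "Downgraded",
  "p.M954V" = "First classification", "p.M966K" = "Unchanged",
  "p.R992Q" = "Upgraded", "p.G1003D" = "First classification",
  "p.N1020S" = "Unchanged", "p.R1068H" = "Unchanged",
  "p.E1094K" = "Unchanged", "p.D1147E" = "Unchanged",
  "p.W1148L" = "Downgraded", "p.A1178V" = "Unchanged",
  "p.R1183H" = "Unchanged", "p.R1183C" = "Unchanged",
  "p.A1188V" = "First classification",
  "p.M1192R" = "First classification", "p.Y1249D" = "Unchanged",
  "p.Y1345D" = "First classification", "p.R1419H" = "Unchanged",
  "p.V1608I" = "Upgraded", "p.E1646K" = "First classification",
  "p.D1659E" = "First classification", "p.I1741V" = "Downgraded",
  "p.Y1758C" = "Unchanged", "p.P1880S" = "Unchanged"
)
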
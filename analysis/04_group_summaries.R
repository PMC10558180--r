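#!/usr/bin/env Rscript
# Group summaries and exact nonparametric comparisons, twice over:
#   (a) the packaged published 13-tumor score table — reproducing the printed
#       medians, percent changes and p-values;
#   (b) the synthetic per-tumor scores from 03_segment_and_score.R.
# Writes summary and comparison TSVs for both.

library(tumorburden)

dir.create("results", showWarnings = FALSE)

report <- function(scores, label) {
  s <- summarize_cohort(scores)
  write_tsv_table(s$summary, file.path("results", paste0(label, "_summary.tsv")))
  write_tsv_table(s$comparisons, file.path("results", paste0(label, "_comparisons.tsv")))
  med <- function(group, modality, metric) {
    round_half_up(s$summary[
      s$summary$group == group & s$summary$modality == modality &
        s$summary$metric == metric, "median"
    ], 2)
  }
  cat("\n== ", label, " ==\n", sep = "")
  cat(
    "Overall median sensitivity:  PET ", med("overall", "PET", "sensitivity"),
    ", MRI ", med("overall", "T1+T2", "sensitivity"),
    ", MRI+PET ", med("overall", "MRI+PET", "sensitivity"), "\n",
    "Overall median specificity:  PET ", med("overall", "PET", "specificity"),
    ", MRI ", med("overall", "T1+T2", "specificity"),
    ", MRI+PET ", med("overall", "MRI+PET", "specificity"), "\n",
    sep = ""
  )
  cmp <- s$comparisons
  for (i in seq_len(nrow(cmp))) {
    cat(sprintf(
      "  %-30s %-12s medians %.2f vs %.2f  p = %s\n",
      cmp$comparison[i], cmp$metric[i], cmp$median_a[i], cmp$median_b[i],
      format_p_value(cmp$p_value[i])
    ))
  }
  invisible(s)
}

cat("Published per-tumor table (packaged fixture):")
fixture_summary <- report(table1_fixture(), "table1")

scores_path <- file.path("results", "per_tumor_scores.tsv")
if (file.exists(scores_path)) {
  synth <- read_tsv_table(scores_path)
  synth$gd_status <- as.logical(synth$gd_status)
  cat("\nSynthetic cohort:")
  report(synth, "synthetic")
} else {
  cat("\n(no synthetic scores found; run analysis/03_segment_and_score.R for them)\n")
}
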
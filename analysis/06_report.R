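#!/usr/bin/env Rscript

# Stage 6 — figures and summary.
#
# Renders the figure set (boxplot, correlation heatmap, PCA scatter,
# dendrogram, MS-vs-MS scatter, fold-change scatter with regression band)
# and summary.md from the tables written by stages 1-5. Every figure is
# backed by a TSV, so its numbers are testable without image parsing.

suppressPackageStartupMessages(library(concordx))

# render_summary expects the concordance summary JSON and precision table
# that run_pipeline() writes; assemble them from the stage outputs
prec <- local({
  meta <- read_sample_table("results/metadata_qc.csv")
  norm <- read_expression_matrix("results/count_normalized.tsv")
  panel <- read_panel_annotation("results/data/panel.csv")
  endo_hk <- panel$probe_id[panel$code_class %in%
                              c("Endogenous", "Housekeeping")]
  keep <- meta$sample_id[meta$qc_pass]
  m_norm <- subset_expr(norm, genes = endo_hk, samples = keep)
  pr <- precision_report(m_norm, meta[meta$sample_id %in% keep, ])
  lab1 <- meta[meta$qc_pass & meta$lab == "Lab1", ]
  partner <- sprintf("%s_Lab2_D%d", lab1$case_id, lab1$day)
  ok <- partner %in% keep
  site <- between_group_scatter_r(
    log2_transform(m_norm), log2_transform(m_norm),
    setNames(partner[ok], lab1$sample_id[ok]))
  data.frame(metric = c("median_intra_cv", "median_inter_cv",
                        "replicate_r2_min", "between_site_r"),
             value = c(pr$median_intra_cv, pr$median_inter_cv,
                       pr$replicate_r2_min, site))
})
write.table(prec, "results/precision_summary.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

fc <- read.delim("results/foldchange_table.tsv")
strat <- sapply(split(fc, fc$stratum), function(s) {
  cor(s$log2fc_count, s$log2fc_array)
})
jsonlite::write_json(
  list(fc_correlation = list(overall = cor(fc$log2fc_count,
                                           fc$log2fc_array),
                             by_stratum = strat[c("low", "medium", "high")]),
       twofold = list(concordant_fraction =
                        mean(fc$tier_twofold != "discordant")),
       band = list(concordant_fraction =
                     mean(fc$tier_band != "out_band_opposite"))),
  "results/concordance_summary.json", auto_unbox = TRUE, digits = NA)

render_summary("results")
cat(readLines("results/summary.md"), sep = "\n")
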
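#!/usr/bin/env Rscript

# Stage 2 — lane QC and normalization of the count platform.
#
# Reads the RCC-lite lane files written by 01_simulate.R, applies the
# standard lane QC metrics (FOV ratio, binding density, positive-control
# linearity, limit of detection), and runs the three-step normalization
# chain: positive-control geometric-mean scaling, negative-control
# mean+2sd background subtraction, housekeeping geometric-mean scaling.
# QC-failed lanes are reported; the normalized matrix and QC report go to
# results/.

suppressPackageStartupMessages(library(concordx))

panel <- read_panel_annotation("results/data/panel.csv")
meta <- read_sample_table("results/data/metadata.csv")
lanes <- lapply(file.path("results/data/rcc",
                          paste0(meta$sample_id, ".csv")),
                read_rcc_lite, panel = panel)
names(lanes) <- meta$sample_id

qc <- qc_lanes(lanes, panel)
write.csv(qc, "results/lane_qc.csv", row.names = FALSE)
failed <- qc[!qc$pass, ]
cat(sprintf("lane QC: %d/%d lanes pass; failed: %s\n",
            sum(qc$pass), nrow(qc),
            if (nrow(failed)) paste(failed$sample_id, " (", failed$flags,
                                    ")", sep = "", collapse = ", ")
            else "none"))

raw <- read_expression_matrix("results/data/count_raw.tsv")
chain <- suppressWarnings(normalize_chain(raw, panel))
write_expression_matrix(chain$matrix, "results/count_normalized.tsv")
write.table(chain$factors, "results/normalization_factors.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

hk <- panel$probe_id[panel$code_class == "Housekeeping"]
hk_geo <- apply(chain$matrix$values[hk, ], 2, function(x) exp(mean(log(x))))
cat(sprintf("housekeeping geomean spread after normalization: %.2e (relative)\n",
            diff(range(hk_geo)) / mean(hk_geo)))

meta$qc_pass <- qc$pass[match(meta$sample_id, qc$sample_id)]
write_sample_table(meta, "results/metadata_qc.csv")
cat("wrote results/lane_qc.csv, results/count_normalized.tsv, results/metadata_qc.csv\n")
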
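#!/usr/bin/env Rscript
# Stage 5 — qPCR validation by delta-delta-Ct.
# Collapses triplicate Ct values (dropping replicates with Ct > 35 cycles),
# normalizes to the reference assay, expresses each sample as fold change
# relative to the responder group, and compares groups per marker with the
# Mann-Whitney U test.
source("analysis/00_config.R")

ct <- read_ct_table(file.path(COHORT_DIR, "ct_table.tsv"))
rel <- relative_quantification(ct, reference_gene = "RNU48")
write.table(rel, file.path(RESULTS_DIR, "qpcr_relative_expression.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

report <- qpcr_group_report(rel)
write.table(report, file.path(RESULTS_DIR, "qpcr_group_report.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
message("per-marker NR vs R comparison (fold relative to R):")
for (i in seq_len(nrow(report))) {
  message(sprintf("  %-22s median fold R=%.2f NR=%.2f  U=%g  p=%.3g",
                  report$target[i], report$median_fold_R[i],
                  report$median_fold_NR[i], report$U[i], report$p[i]))
}
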
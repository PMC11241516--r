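#!/usr/bin/env Rscript
# Stage 6 — biomarker panels and ROC analysis.
# Builds a -deltaCt marker matrix from the qPCR stage, fits logistic models
# for every single marker and marker pair, and ranks panels by in-sample AUC
# (midrank / Mann-Whitney convention).
source("analysis/00_config.R")

rel <- read.delim(file.path(RESULTS_DIR, "qpcr_relative_expression.tsv"))
mm <- marker_matrix_from_relexp(rel)

panels <- c(as.list(colnames(mm$markers)),
            utils::combn(colnames(mm$markers), 2, simplify = FALSE))
res <- evaluate_panels(mm$markers, mm$labels, panels)
write.table(res, file.path(RESULTS_DIR, "panel_aucs.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

message("panel ranking by in-sample AUC:")
for (i in seq_len(nrow(res))) {
  message(sprintf("  %-45s AUC = %.3f", res$panel[i], res$auc[i]))
}
best <- res[1, ]
message("best panel: ", best$panel, " (AUC = ", round(best$auc, 3), ")")
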
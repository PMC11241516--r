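#!/usr/bin/env Rscript
# Stage 2 — two-group differential expression.
# Welch-tests every miRNA and gene between NR and R samples and applies the
# conventional gates (>1.5-fold change and p < 0.05, both strict). Writes one
# signed DE table per feature class.
source("analysis/00_config.R")

labels_path <- file.path(COHORT_DIR, "samples.tsv")
de_mi <- differential_expression(
  read_expression_tsv(file.path(COHORT_DIR, "mirna_matrix.tsv"), labels_path))
de_ge <- differential_expression(
  read_expression_tsv(file.path(COHORT_DIR, "gene_matrix.tsv"), labels_path))

write_de_table(de_mi, file.path(RESULTS_DIR, "de_mirnas.tsv"))
write_de_table(de_ge, file.path(RESULTS_DIR, "de_genes.tsv"))

for (x in list(c("miRNAs", "de_mi"), c("genes", "de_ge"))) {
  de <- get(x[2])
  message(sum(de$passes), " / ", nrow(de), " ", x[1],
          " pass the gates (", sum(de$direction == "up"), " up, ",
          sum(de$direction == "down"), " down in NR)")
}
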
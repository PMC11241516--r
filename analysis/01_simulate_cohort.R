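#!/usr/bin/env Rscript
# Stage 1 — simulate the study cohort.
# Generates a synthetic two-group (responder / non-responder) cohort with
# planted reciprocal miRNA-target effects, a validated-interaction table,
# triplicate qPCR Ct measurements and censored survival records, and writes
# every component as TSV so the later stages can run from files.
source("analysis/00_config.R")

cohort <- generate_cohort(COHORT_CONFIG)
paths <- write_cohort(cohort, COHORT_DIR)

message("cohort: ", ncol(cohort$mirna_matrix$values), " samples (",
        sum(cohort$mirna_matrix$labels == "R"), " R / ",
        sum(cohort$mirna_matrix$labels == "NR"), " NR)")
message("features: ", nrow(cohort$mirna_matrix$values), " miRNAs, ",
        nrow(cohort$gene_matrix$values), " genes; planted reciprocal pairs: ",
        nrow(cohort$truth_pairs))
message("interaction table: ", nrow(cohort$interactions$records),
        " validated pairs (", nrow(cohort$truth_pairs), " true + decoys)")
message("written: ", paste(basename(paths), collapse = ", "))
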
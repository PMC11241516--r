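# Shared settings for the analysis scripts: one seeded cohort configuration
# and the output layout. Source()d by every numbered script so the whole
# workflow is reproducible end to end.
library(mirtarnet)

RESULTS_DIR <- "results"
COHORT_DIR <- file.path(RESULTS_DIR, "cohort")

# Study-condition defaults: 5 R vs 9 NR arrays, planted reciprocal pairs,
# log2-scale Gaussian noise, exponential survival (R median 134 months,
# NR hazard ratio 4.8), 30% censoring.
COHORT_CONFIG <- cohort_config(seed = 20260929)

dir.create(COHORT_DIR, showWarnings = FALSE, recursive = TRUE)
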
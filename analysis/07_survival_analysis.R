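#!/usr/bin/env Rscript
# Stage 7 — overall survival.
# Kaplan-Meier curves per response group with the log-rank comparison, and a
# marker dichotomization example: median split of the top qPCR marker's
# -deltaCt against overall survival.
source("analysis/00_config.R")

sv <- read.delim(file.path(COHORT_DIR, "survival.tsv"))
lr <- logrank_test(sv$time_months, sv$event, sv$group)
message(sprintf("log-rank NR vs R: chi2 = %.2f, p = %.3g", lr$chi2, lr$p))
message(sprintf("median OS: R = %s, NR = %s months",
                format(lr$medians[["R"]], digits = 3),
                format(lr$medians[["NR"]], digits = 3)))
for (g in c("R", "NR")) {
  km <- km_estimate(sv$time_months[sv$group == g], sv$event[sv$group == g])
  write_km_table(km, file.path(RESULTS_DIR, sprintf("km_%s.tsv", g)))
}
write.table(data.frame(chi2 = lr$chi2, df = lr$df, p = lr$p,
                       median_R = lr$medians[["R"]],
                       median_NR = lr$medians[["NR"]]),
            file.path(RESULTS_DIR, "survival_logrank.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

# dichotomize the first qPCR marker by median split
rel <- read.delim(file.path(RESULTS_DIR, "qpcr_relative_expression.tsv"))
marker <- sort(unique(rel$target))[1]
x <- rel[rel$target == marker, ]
x <- x[match(sv$sample, x$sample), ]
grp <- dichotomize(-x$delta_ct)
lr2 <- logrank_test(sv$time_months, sv$event, as.character(grp))
message(sprintf("median split of %s (-deltaCt): chi2 = %.2f, p = %.3g",
                marker, lr2$chi2, lr2$p))
write.table(data.frame(marker = marker, cutpoint = attr(grp, "cutpoint"),
                       chi2 = lr2$chi2, p = lr2$p,
                       median_low = lr2$medians[["low"]],
                       median_high = lr2$medians[["high"]]),
            file.path(RESULTS_DIR, "survival_marker_split.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
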
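#!/usr/bin/env Rscript
# Descriptive screen of the healthy cohort: means, SDs, ranges, skewness and
# excess kurtosis with the |1| / |3| normality flags, and the full
# correlation matrix (point-biserial for gender). Mirrors the sample-
# descriptives table a norming study reports before any modelling.

suppressMessages(library(memnorms))
cohort <- read_cohort_csv("results/cohort_healthy.csv")
scr <- descriptive_screen(cohort)

write.csv(scr$summary, "results/descriptives.csv", row.names = FALSE)
write.csv(round(scr$corr, 3), "results/correlations.csv")

cat("variable summary:\n")
print(scr$summary[, c("variable", "mean", "sd", "min", "max",
                      "skewness", "kurtosis", "abnormal")], digits = 3)
flagged <- scr$summary$variable[scr$summary$abnormal]
cat(if (length(flagged) == 0) "no variable flagged non-normal\n" else
    paste("flagged:", paste(flagged, collapse = ", "), "\n"))
cat("wrote results/descriptives.csv, results/correlations.csv\n")
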
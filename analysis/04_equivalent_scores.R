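#!/usr/bin/env Rscript
# Normative scoring of the adjusted scores: exact-binomial outer/inner
# tolerance limits on the 5th centile (95% confidence), Equivalent Score
# bands 0-4 (ES 0 bounded by the OTL, ES 4 above the median, rank-tertile
# intermediate bands), and the percentile lookup tables.

suppressMessages(library(memnorms))
cohort <- read_cohort_csv("results/cohort_healthy.csv")

es_rows <- list()
for (t in test_catalog()$test) {
  eq <- read_equation_json(sprintf("results/equation_%s.json", t))
  adjusted <- adjust_cohort(eq, cohort)
  th <- es_thresholds(adjusted)
  th$test <- t
  write_thresholds_json(th, sprintf("results/thresholds_%s.json", t))
  pt <- percentile_table(adjusted)
  write.csv(pt, sprintf("results/percentiles_%s.csv", t), row.names = FALSE)
  cf <- round_half_away(th$cutoffs, 2)
  es_rows[[t]] <- data.frame(
    test = t, es0_max = cf[1], es1_max = cf[2], es2_max = cf[3],
    es3_max = cf[4],
    otl = round_half_away(th$limits$otl, 2),
    itl = round_half_away(th$limits$itl, 2))
  cat(sprintf("%s: ES0 <= %.2f | ES1 <= %.2f | ES2 <= %.2f | ES3 <= %.2f | ES4 above; ITL %.2f\n",
              t, cf[1], cf[2], cf[3], cf[4], th$limits$itl))
}
es_table <- do.call(rbind, es_rows)
write.csv(es_table, "results/es_cutoffs.csv", row.names = FALSE)
cat("wrote results/thresholds_*.json, results/percentiles_*.csv, results/es_cutoffs.csv\n")
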
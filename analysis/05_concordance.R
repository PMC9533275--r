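#!/usr/bin/env Rscript
# Compare the freshly fitted normative system against stand-in reference
# norms on the simulated patient cohort: 2x2 confusion matrices, accuracy,
# Mann-Whitney AUC with DeLong CIs, Cohen's kappa and Gwet's AC1. The
# reference systems are synthetic stand-ins (see ?standin_reference_systems);
# the metrics exercise the comparison machinery, not historical norms.

suppressMessages(library(memnorms))
patients <- read_cohort_csv("results/cohort_patients.csv")

tests <- test_catalog()$test
systems_new <- lapply(setNames(tests, tests), function(t) {
  normative_system(
    paste0("fitted_", t),
    read_equation_json(sprintf("results/equation_%s.json", t)),
    thresholds = read_thresholds_json(sprintf("results/thresholds_%s.json", t)))
})

cmp <- run_comparison(patients, systems_new, standin_reference_systems(),
                      tests = tests, seed = 2026)

metrics <- do.call(rbind, lapply(names(cmp), function(t) {
  s <- cmp[[t]]$stats
  data.frame(test = t, accuracy = round(s$accuracy, 2),
             auc = round(s$auc, 2),
             auc_ci = sprintf("%.2f-%.2f", s$auc_ci[1], s$auc_ci[2]),
             kappa = round(s$kappa, 2),
             kappa_ci = sprintf("%.2f-%.2f", s$kappa_ci[1], s$kappa_ci[2]),
             ac1 = round(s$ac1, 2),
             ac1_ci = sprintf("%.2f-%.2f", s$ac1_ci[1], s$ac1_ci[2]))
}))
print(metrics, row.names = FALSE)
write.csv(metrics, "results/concordance_metrics.csv", row.names = FALSE)

cms <- do.call(rbind, lapply(names(cmp), function(t) {
  m <- cmp[[t]]$cm
  data.frame(test = t, both_impaired = m$a, ref_only = m$b,
             pred_only = m$c, both_normal = m$d)
}))
write.csv(cms, "results/confusion_matrices.csv", row.names = FALSE)
roc <- do.call(rbind, lapply(names(cmp), function(t) cbind(test = t, cmp[[t]]$roc)))
write.csv(roc, "results/roc_points.csv", row.names = FALSE)
cat("wrote results/concordance_metrics.csv, results/confusion_matrices.csv, results/roc_points.csv\n")
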
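#!/usr/bin/env Rscript
# Generate the two synthetic cohorts every later step consumes: a healthy
# normative cohort calibrated to the published sample structure (N = 204,
# 127 F / 77 M, the published correlation matrix over demographics and the
# five memory scores) and a simulated amnestic-MCI patient cohort (n = 100,
# stand-in clinical score distributions, age-education correlation -0.22).

suppressMessages(library(memnorms))
dir.create("results", showWarnings = FALSE)
seed <- 2026

healthy <- simulate_healthy_cohort(healthy_spec(seed = seed))
write_cohort_csv(healthy, "results/cohort_healthy.csv")
cat(sprintf("healthy cohort: %d rows, %d female\n",
            nrow(healthy), sum(healthy$gender)))
cat(sprintf("  age %0.1f (%0.1f), education %0.1f (%0.1f)\n",
            mean(healthy$age), sd(healthy$age),
            mean(healthy$education), sd(healthy$education)))
cat(sprintf("  corr(age, education) = %0.2f (target -0.49)\n",
            cor(healthy$age, healthy$education)))
cat(sprintf("  corr(ravl_i, ravl_d) = %0.2f (target 0.78)\n",
            cor(healthy$ravl_i, healthy$ravl_d)))

patients <- simulate_patient_cohort(patient_spec(seed = seed + 1))
write_cohort_csv(patients, "results/cohort_patients.csv")
cat(sprintf("patient cohort: %d rows, corr(age, education) = %0.3f (target -0.22)\n",
            nrow(patients), cor(patients$age, patients$education)))
cat("wrote results/cohort_healthy.csv, results/cohort_patients.csv\n")
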
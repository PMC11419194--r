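#!/usr/bin/env Rscript
# Run the full quantification pipeline on every cohort phantom and summarize
# the cortical metabolite ratios by tier, mirroring how the clinical analysis
# groups allografts by biopsy finding.

suppressPackageStartupMessages(library(hp13c))

cohort <- utils::read.csv("results/cohort_ground_truth.csv")
results <- lapply(seq_len(nrow(cohort)), function(i) {
  run_pipeline(study_config(
    subject_id = cohort$subject_id[i], seed = cohort$seed[i],
    kinetics = list(kpl = c(cohort$kpl[i], 0.7 * cohort$kpl[i], 0))
  ))
})

report <- quant_report(results)
rows <- merge(cohort, report$subjects, by = "subject_id")
utils::write.csv(rows, "results/subject_ratios.csv", row.names = FALSE)
cat("Per-subject cortical ratios (results/subject_ratios.csv):\n")
print(rows[, c("subject_id", "tier", "kpl", "lac_pyr_mean", "bic_pyr_mean",
               "bolus_time_s", "pyr_auc_snr")])

groups <- do.call(rbind, lapply(split(rows, rows$tier), function(g) {
  s <- group_summary(g$lac_pyr_mean)
  data.frame(tier = g$tier[1], n = s$n_subjects,
             lp_mean = round(s$mean, 3),
             lp_min = round(s$min, 3), lp_max = round(s$max, 3))
}))
utils::write.csv(groups, "results/group_summary.csv", row.names = FALSE)
cat("\nTier summaries (results/group_summary.csv):\n")
print(groups)
cat("\nThe normal tier should sit well below the abnormal tiers; the ordering\n")
cat("follows the ground-truth conversion rates by construction.\n")
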
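#!/usr/bin/env Rscript
# Ingest the simulated claims (drop patients with missing demographics, map
# national drug codes onto the ATC hierarchy, attach specialties and age
# categories), label every patient T2DM / non-T2DM with the rule framework,
# and censor antidiabetic drugs from non-T2DM patients.

suppressMessages(library(rxmine))
suppressMessages(library(data.table))

cfg <- synthetic_claims_config()
ing <- ingest_claims("scratch/claims.csv", "scratch/formulary.csv",
                     "scratch/specialties.csv", cfg)
preds <- drug_predicates(cfg)
labels <- label_t2dm(ing$claims, preds)
censored <- censor_a10(ing$claims, labels)

fwrite(ing$claims, "scratch/claims_mapped.csv")
fwrite(censored, "scratch/claims_censored.csv")
fwrite(labels, "scratch/labels.csv")

summary_tab <- data.table(
  metric = c("input_records", "retained_records",
             "dropped_missing_demographics", "dropped_unmapped_drug",
             "patients_labelled", "patients_t2dm", "t2dm_prevalence_pct",
             "flag_t1dm_male", "flag_t1dm_female", "flag_pcos",
             "flag_pregnancy", "censored_a10_records"),
  value = c(ing$log$n_input, ing$log$n_retained, ing$log$n_dropped_missing,
            ing$log$n_dropped_unmapped, nrow(labels), sum(labels$is_t2dm),
            round(100 * mean(labels$is_t2dm), 3),
            sum(labels$t1dm_male), sum(labels$t1dm_female),
            sum(labels$pcos), sum(labels$pregnancy),
            attr(censored, "n_censored_records"))
)
fwrite(summary_tab, "results/02_phenotype_summary.tsv", sep = "\t")

truth <- fread("scratch/truth.csv")
m <- merge(truth[missing_demo == FALSE], labels[, .(patient_id, is_t2dm)],
           by = "patient_id")
cat(sprintf("Labelled %d patients: %d T2DM (%.2f%%).\n", nrow(labels),
            sum(labels$is_t2dm), 100 * mean(labels$is_t2dm)))
cat(sprintf("Agreement with latent truth: %.3f%% (%d ambiguous by construction).\n",
            100 * mean(m$is_t2dm == m$t2dm), sum(m$ambiguous)))
cat(sprintf("Exclusions: %d T1DM-male, %d T1DM-female, %d PCOS, %d pregnancy.\n",
            sum(labels$t1dm_male), sum(labels$t1dm_female),
            sum(labels$pcos), sum(labels$pregnancy)))
cat("Wrote results/02_phenotype_summary.tsv\n")
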
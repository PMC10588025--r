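#!/usr/bin/env Rscript
# Simulate a pharmacy-claims cohort with planted co-prescription structure:
# ~10% diabetic prevalence (diabetics mostly old and female), comorbidity
# enrichment (statins, renin-angiotensin agents, antithrombotics in
# diabetics), confounder subpopulations (young type 1 diabetics, PCOS
# metformin from gynecologists, pregnancy human insulin) and 2% missing
# demographics. Raw claims go to scratch/ (they are inputs, not results);
# the cohort summary table goes to results/.

suppressMessages(library(rxmine))
suppressMessages(library(data.table))

dir.create("scratch", showWarnings = FALSE)
dir.create("results", showWarnings = FALSE)

spec <- cohort_spec(n_patients = 20000L, seed = 20260922L)
cohort <- generate_cohort(spec)

fwrite(cohort$claims, "scratch/claims.csv")
fwrite(cohort$truth, "scratch/truth.csv")
fwrite(synthetic_formulary(), "scratch/formulary.csv")
fwrite(synthetic_specialty_mapping(), "scratch/specialties.csv")

truth <- cohort$truth
summary_tab <- truth[, .(
  n_patients = .N,
  n_t2dm = sum(t2dm),
  n_t1dm = sum(t1dm),
  n_pcos = sum(pcos),
  n_pregnancy = sum(pregnancy),
  n_missing_demo = sum(missing_demo),
  n_ambiguous = sum(ambiguous)
), by = .(gender, age_category)][order(gender, age_category)]
fwrite(summary_tab, "results/01_cohort_summary.tsv", sep = "\t")

cat(sprintf("Simulated %d patients (%d claim rows).\n",
            nrow(truth), nrow(cohort$claims)))
cat(sprintf("Latent T2DM prevalence: %.2f%% (%d patients).\n",
            100 * mean(truth$t2dm), sum(truth$t2dm)))
cat(sprintf("Confounders: %d T1DM, %d PCOS, %d pregnancy; %d patients with missing demographics.\n",
            sum(truth$t1dm), sum(truth$pcos), sum(truth$pregnancy),
            sum(truth$missing_demo)))
cat("Wrote scratch/claims.csv and results/01_cohort_summary.tsv\n")
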
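#!/usr/bin/env Rscript
# Grid search over the mining thresholds at ATC level 2: how many frequent
# itemsets, rules and diabetes-anchored rules survive at each (minimum
# support, minimum confidence) combination. The counts are monotone
# non-increasing along both axes; the working point (support 0.0001,
# confidence 0.1) sits where the diabetes-anchored rule set stabilises.

suppressMessages(library(rxmine))
suppressMessages(library(data.table))

censored <- fread("scratch/claims_censored.csv", colClasses = "character")
censored[, age := as.integer(age)]
labels <- fread("scratch/labels.csv")

ts <- build_transactions(censored, 2, labels)
sweep <- threshold_sweep(ts,
                         support_grid = c(0.0001, 0.001, 0.01, 0.05),
                         confidence_grid = c(0.1, 0.3, 0.5))
fwrite(sweep, "results/06_threshold_sweep.tsv", sep = "\t")

cat("Threshold sweep at ATC level 2:\n")
print(sweep)
cat("Wrote results/06_threshold_sweep.tsv\n")
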
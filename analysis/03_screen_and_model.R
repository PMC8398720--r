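#!/usr/bin/env Rscript
# Step 3: screening and predictive modeling.
#
# Runs the full pipeline on the simulated cohort: screening labels from
# the exit LSAS / GAD-7 / PHQ-8 scores (thresholds 60 / 10 / 10),
# exclusion of subjects with four or more missing features, repeated
# stratified 5x20 cross-validation of a logistic screening model per
# disorder (100 fold-level AUROCs each), the corrected resampled t-test
# against an uninformative AUROC of 0.5, and full-data models for the
# x-standardized coefficients. Artifacts land in results/run/.

suppressPackageStartupMessages(library(phenoscreen))

SEED <- 20240817
cohort_dir <- "scratch/cohort"
if (!dir.exists(cohort_dir)) {
  stop("no cohort found; run analysis/01_simulate_cohort.R first")
}

res <- run_pipeline(cohort_dir, "results/run", seed = SEED)
report("results/run")
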
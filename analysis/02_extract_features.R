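#!/usr/bin/env Rscript
# Step 2: extract the eight behavioral features.
#
# Reads the cohort written by 01_simulate_cohort.R, applies the stream
# sufficiency rule (a stream with fewer than half its expected samples
# contributes no features), and computes per-subject features. Writes
# the feature table and prints a summary in the style of a cohort
# descriptives table (mean, SD, quartiles).

suppressPackageStartupMessages(library(phenoscreen))

cohort_dir <- "scratch/cohort"
if (!dir.exists(cohort_dir)) {
  stop("no cohort found; run analysis/01_simulate_cohort.R first")
}

cohort <- read_cohort(cohort_dir)
cat(sprintf("Read %d subjects.\n", length(cohort)))

feats <- extract_cohort_features(cohort)
suff <- attr(feats, "sufficiency")

dir.create("results/tables", recursive = TRUE, showWarnings = FALSE)
write.csv(feats, "results/tables/features.csv", row.names = FALSE)
write.csv(suff, "results/tables/stream_sufficiency.csv", row.names = FALSE)

insuff <- with(suff, tapply(!sufficient, stream, sum))
cat("Insufficient streams (subjects):",
    paste(names(insuff), insuff, collapse = ", "), "\n")

miss <- rowSums(is.na(feats[, pheno_features()]))
cat(sprintf("Subjects with >= 4 missing features (to be excluded): %d of %d\n",
            sum(miss >= 4), nrow(feats)))

cat("\nFeature summary over subjects with < 4 missing features:\n")
keep <- feats[miss < 4, pheno_features()]
summ <- t(sapply(keep, function(x) {
  q <- quantile(x, c(0, 0.25, 0.5, 0.75, 1), na.rm = TRUE)
  c(mean = mean(x, na.rm = TRUE), sd = sd(x, na.rm = TRUE), q)
}))
print(round(summ, 3))
write.csv(round(summ, 4), "results/tables/feature_summary.csv")
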
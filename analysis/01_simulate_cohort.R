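#!/usr/bin/env Rscript
# Step 1: synthesize the study cohort.
#
# 112 subjects observed for 14 days each, with correlated latent
# severities driving both the exit self-report scores and the behavioral
# parameters of every sensor stream. Roughly a quarter of subjects are
# "lossy recorders" whose streams fall under the half-of-expected
# sufficiency bar. The cohort is written in the on-disk layout under
# scratch/ (it is large and fully regenerable from the seed); the ground
# truth table goes with it.

suppressPackageStartupMessages(library(phenoscreen))

SEED <- 20240817
out_dir <- "scratch/cohort"

cfg <- generator_config(seed = SEED)
cat(sprintf("Generating %d subjects x %d days (seed %d)...\n",
            cfg$n_subjects, cfg$window_days, cfg$seed))
g <- generate_cohort(cfg)

write_cohort(g$cohort, out_dir)
dir.create("scratch", showWarnings = FALSE)
write.csv(g$truth, "scratch/ground_truth.csv", row.names = FALSE)

lossy <- sum(g$truth$lossy)
cat(sprintf("Wrote cohort to %s (%d subjects, %d lossy recorders).\n",
            out_dir, length(g$cohort), lossy))
cat(sprintf("Ground-truth location sites: median %d (range %d-%d); exits: median %d.\n",
            median(g$truth$n_sites), min(g$truth$n_sites),
            max(g$truth$n_sites), median(g$truth$n_exits)))
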
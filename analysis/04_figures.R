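#!/usr/bin/env Rscript
# Step 4: figures.
#
# Coefficient comparison chart (full-data x-standardized logistic
# coefficients by disorder; negative = associated with decreased odds of
# a positive screen) and the distribution of fold-level AUROCs per
# disorder from the repeated cross-validation.

suppressPackageStartupMessages({
  library(phenoscreen)
  library(ggplot2)
})

run_dir <- "results/run"
if (!file.exists(file.path(run_dir, "coefficients.csv"))) {
  stop("no run artifacts; run analysis/03_screen_and_model.R first")
}
dir.create("results/figures", recursive = TRUE, showWarnings = FALSE)

coefs <- read.csv(file.path(run_dir, "coefficients.csv"))
coefs <- coefs[coefs$term != "(Intercept)", ]
coefs$term <- factor(coefs$term, levels = rev(pheno_features()))

p1 <- ggplot(coefs, aes(x = coefficient, y = term, fill = disorder)) +
  geom_col(position = position_dodge(width = 0.8), width = 0.7) +
  geom_vline(xintercept = 0, linewidth = 0.3) +
  labs(x = "x-standardized logistic coefficient", y = NULL,
       title = "Screening model coefficients by disorder",
       subtitle = "negative = lower odds of a positive screen") +
  theme_minimal(base_size = 11)
ggsave("results/figures/coefficients.png", p1, width = 7, height = 4.5,
       dpi = 150)

aurocs <- read.csv(file.path(run_dir, "cv_aurocs.csv"))
p2 <- ggplot(aurocs, aes(x = disorder, y = auroc)) +
  geom_boxplot(width = 0.45, outlier.size = 0.8) +
  geom_hline(yintercept = 0.5, linetype = 2) +
  labs(y = "fold-level AUROC (5 folds x 20 repeats)", x = NULL,
       title = "Cross-validated screening performance") +
  theme_minimal(base_size = 11)
ggsave("results/figures/cv_auroc.png", p2, width = 5, height = 4, dpi = 150)

cat("Wrote results/figures/coefficients.png and results/figures/cv_auroc.png\n")
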
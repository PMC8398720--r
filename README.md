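# phenoscreen

Digital phenotyping asks whether passively collected smartphone data can
stand in for clinical screening instruments. This package implements, as a
tested and fully reproducible pipeline, an analysis in that mold: eight
behavioral features are extracted from five passive sensor streams
collected over a 14-day observation window, subjects are screened for
social anxiety disorder (SAD), generalized anxiety disorder (GAD), and
major depressive disorder (MDD) from exit self-report scores, and
logistic-regression screening models are evaluated with repeated k-fold
cross-validation and a corrected resampled t-test.

Because raw participant sensor data of this kind is privacy-sensitive and
not publicly shareable, the package includes a synthetic cohort generator
with known ground truth: latent per-subject severities (correlated across
disorders, emulating comorbidity) drive both the self-report scores and
the behavioral parameters of every simulated sensor stream. Every stage of
the pipeline is validated against that ground truth and against
independent oracle implementations.

## The analysis

**Streams** (per subject, nominal rates): ambient-audio volume + binary
speech label every 5 min; an order-destroyed bag of speech-recognized
words; GPS fixes every 5 min; screen on/off transition events; light
sensor samples every 10 min.

**Features** (one vector per subject):

| feature | definition |
|---|---|
| daily similarity | autocorrelation of the binned audio-volume series at a 24 h lag (Pearson over complete lag pairs) |
| speech presence | fraction of recordings labeled as containing speech |
| weeknight sleep disturbance | SD of volume during weeknight 00:00–06:00 local time |
| death-related words | % of word tokens matching an open death-category lexicon |
| locations visited | clusters of stationary GPS points (speed < 1 km/h), DBSCAN with ε = 150 m |
| exits from home | transitions out of the home cluster (most nighttime dwell) |
| screen use | proportion of the window with the screen on |
| time in darkness | fraction of light samples < 5 lux |

**Missing data**: a stream with fewer than half its nominally expected
samples contributes no features; subjects with ≥ 4 missing features are
excluded. Remaining gaps are median-imputed inside each training fold.

**Screening**: LSAS ≥ 60 (SAD), GAD-7 ≥ 10 (GAD), PHQ-8 ≥ 10 (MDD).

**Models**: per disorder, an unpenalized logistic regression on the eight
x-standardized features, evaluated by stratified 5-fold cross-validation
repeated 20 times (100 fold-level AUROCs). Significance against an
uninformative model (AUROC 0.5) uses the corrected resampled t-test

> t = d̄ / √[(1/(k·r) + n₂/n₁) · s²_d],  df = k·r − 1

with d_j = AUROC_j − 0.5 and n₂/n₁ = 1/(k−1), one-tailed. Feature
importance comes from a single full-data model per disorder, whose
x-standardized coefficients are directly comparable across features.

## Worked example

The numbered scripts under `analysis/` run the whole study on a synthetic
cohort (the large raw cohort lives under `scratch/`, summary tables under
`results/`):

```sh
Rscript analysis/01_simulate_cohort.R   # 112 subjects x 14 days
Rscript analysis/02_extract_features.R
Rscript analysis/03_screen_and_model.R
Rscript analysis/04_figures.R
Rscript analysis/05_calibration.R
```

Step 3 prints (seed 20240817):

```
Subjects: 112; included 87 (77.7%), excluded 25

Screening prevalence:
  SAD  33/87 positive (37.9%)
  GAD  28/87 positive (32.2%)
  MDD  38/87 positive (43.7%)

Cross-validated screening performance:
  SAD  AUROC 0.88 (SD 0.07), t(99) = 10.23, p = 1.73e-17
  GAD  AUROC 0.67 (SD 0.14), t(99) = 2.48, p = 0.00737
  MDD  AUROC 0.89 (SD 0.06), t(99) = 11.81, p = 6.5e-21
```

Reading this: 25 of the 112 simulated subjects were "lossy recorders"
whose streams fell under the half-of-expected bar, leaving 87 analyzed;
prevalences scatter around the generator's targets (38/26/37%) within
binomial sampling noise at n = 87; all three
models beat chance on this cohort — the synthetic severity signal is
deliberately strong — and the full-model coefficients (printed below
these lines, and drawn by step 4) recover the injected effect directions,
e.g. speech presence strongly protective for MDD. Step 5 measures type-I
calibration of the corrected t-test on 500 null cohorts and prints the
rejection rate next to the (severely inflated) naive test.

The same machinery is available programmatically:

```r
library(phenoscreen)
g <- generate_cohort(generator_config(seed = 1))
res <- run_pipeline(g$cohort, "my_run", seed = 1)
report("my_run")
```

## Package layout

- `R/` — sensor domain types and cohort I/O, geoclustering
  (stationary points, DBSCAN, home inference), feature extraction,
  screening + CV + corrected t-test, synthetic cohort generator,
  pipeline orchestration
- `analysis/` — the numbered study scripts above
- `vignettes/phenoscreen-methods.Rmd` — model assumptions, parameter
  choices, numerical decisions, and known limitations
- `tests/testthat/` — unit, property, and oracle-equivalence tests plus
  the end-to-end acceptance suite
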
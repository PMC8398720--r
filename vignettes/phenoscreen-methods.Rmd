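---
title: "Methods: passive sensing features and screening models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: passive sensing features and screening models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(phenoscreen)
```

This vignette is the package's own account of its methods: the model and
its assumptions, the parameters that matter and why they default where
they do, the numerical decisions, what the synthetic cohort generator
does and does not emulate, and the known limitations.

## The analysis in one paragraph

Each subject contributes five passive smartphone streams over a 14-day
observation window — ambient-audio volume with binary speech labels, an
order-destroyed word bag, GPS fixes, screen on/off events, and light
sensor samples — plus exit scores on three self-report instruments
(LSAS, GAD-7, PHQ-8). Eight behavioral features summarize the streams;
fixed thresholds on the scale scores (60 / 10 / 10) define positive
screens for social anxiety disorder (SAD), generalized anxiety disorder
(GAD), and major depressive disorder (MDD). Per disorder, a logistic
regression on the x-standardized features is evaluated by stratified
5-fold cross-validation repeated 20 times; the 100 fold-level AUROCs are
tested against 0.5 with the corrected resampled t-test, and a single
full-data model per disorder supplies comparable signed coefficients.

## Feature definitions and their assumptions

**Daily similarity.** The irregular volume samples are binned onto a
5-minute grid anchored at the window start (the bin width mirrors the
nominal sampling period); the feature is the Pearson correlation between
the binned series and itself shifted by 24 h (288 bins), over bin pairs
where both values are present. We deliberately use lag-paired Pearson
rather than the full-series autocovariance ratio: with dropout the
series has holes, and pairwise-complete Pearson degrades gracefully
while the biased estimator does not. The estimator is affine-invariant
in volume, which matters because volume units are device-relative.
Degenerate inputs (fewer than two complete pairs, zero variance in
either slice) yield a missing value rather than an arbitrary number.

**Speech presence** is the labeled fraction of recordings — a pure
count ratio, no smoothing.

**Weeknight sleep disturbance** is the sample SD (n−1) of volumes whose
local time falls in [00:00, 06:00) on a weeknight morning. "Weeknight"
defaults to the mornings of Tuesday–Saturday, i.e. the nights that
*follow* Monday–Friday evenings, on the reasoning that a
Saturday-morning 2 AM sample belongs to a Friday work-week night; the
configuration (`weeknight_wdays = 1:5`) switches to plain Monday–Friday
mornings. The SD rather than the mean is used because absolute volume
depends on the microphone and automatic gain control; only
within-subject dispersion is meaningful.

**Death-related words.** Percentage of word-bag tokens matching a death
lexicon; entries ending in `*` match by prefix, everything else matches
exactly. The bundled list (`inst/extdata/death_lexicon.txt`) is an open
word list written for this package; proprietary category dictionaries
cannot be redistributed, so counts here are comparable in spirit, not
numerically identical to tools built on them. Forms like *dying* that a
naive `die*` prefix would miss are listed explicitly, and exact entries
(*grave*, *die*) avoid prefix false positives (*gravel*, *diet*).

**Locations visited and exits from home.** GPS fixes moving slower than
1 km/h relative to the previous fix (direct-line, haversine on a
6,371,000 m sphere — ellipsoidal error is irrelevant at a 150 m
clustering radius) are stationary; the first fix, with no predecessor,
counts as stationary. Stationary points are clustered with DBSCAN at
ε = 150 m and `min_pts = 5`. ε comes with the method; `min_pts` is a
common DBSCAN default, exposed in configuration, and deliberately small
enough that a single 45-minute visit (8–9 fixes) founds a cluster. Each
stationary point carries a dwell time — the gap to the next fix, capped
at 30 minutes so data gaps cannot fabricate hours of dwell. Home is the
cluster with the most dwell in local [00:00, 06:00); ties go to total
dwell, then lowest id. Locations visited is the number of clusters;
exits from home counts home→non-home transitions in the time-ordered,
noise-free label sequence. Noise points are *excluded* from that
sequence rather than treated as "away": an unassigned point is absence
of evidence, not evidence of a distinct location. When no clustered
point overlaps the night window, home is undefined and both location
features are missing.

Our DBSCAN is written in-house (no suitable clustering dependency is
declared) with one deviation from textbook implementations: border
points join the *lowest-id* reachable cluster, and cluster ids are
assigned by each cluster's earliest core-point timestamp. Textbook
DBSCAN assigns border points to whichever cluster reaches them first in
iteration order, which makes labels depend on input order; our rule
makes the labeling a pure function of the point set, which the test
suite exploits (permutation-invariance property, brute-force
density-reachability oracle on all instances ≤ 50 points).

**Screen use** integrates on-time over the window. The state before the
first event is the complement of that event's state; the last state
persists to the window end; repeated same-state events are collapsed.
The screen stream is event-driven, so it is exempt from the
expected-sample sufficiency rule; screen use is missing only when there
are no events at all.

**Time in darkness** is the fraction of light samples strictly below
5 lux. The threshold is strict by definition: a reading of exactly
5 lux is not darkness.

## Missing data

For audio, GPS, and light, the expected count over the window is
`floor(window_minutes / period)` with periods 5 / 5 / 10 minutes. A
stream with fewer than half its expected samples contributes no
features: "less than half" is read literally, so exactly half is
sufficient. Audio insufficiency removes four features (the three
volume/speech features and death-related words, whose word bag rides on
the same recordings); GPS insufficiency (or an undefined home) removes
two; light insufficiency removes one. Subjects with four or more missing
features are excluded before modeling — so a subject who loses audio
alone is excluded, which is the dominant exclusion path. Subjects with
one to three missing features are retained and their gaps are imputed
with the *training-fold* median inside each CV fold, then scaled by the
training-fold mean and SD. Preprocessing never sees held-out rows; a
test in the suite recomputes a fold by hand from the recorded
assignment to witness this.

## Cross-validation and the corrected t-test

Folds are stratified: fold totals differ by at most one (at n = 84,
sizes are 16 or 17) and positives are spread so every fold contains both
classes — without stratification, a 26%-prevalence disorder at n = 84
produces single-class folds often enough to leave AUROC undefined.
Unstratified assignment remains available in configuration.

The logistic fits are unpenalized maximum likelihood, because the
analysis interprets raw standardized coefficients and any regularization
would shrink exactly the quantity being reported. When a fold is
(quasi-)separated — common at fold sizes of ~67 training subjects with
strong features — the fit falls back to a weak ridge (λ = 1e−4) via
IRLS, with a warning. AUROC uses the Mann–Whitney midrank formulation,
so ties count one half.

With k-fold CV repeated r times, the k·r performance values share
training data and are far from independent; a naive t-test on them is
badly anticonservative. The corrected resampled t-test divides the mean
difference d̄ (from the null AUROC of 0.5) by
√[(1/(k·r) + n₂/n₁)·s²_d] with the equal-fold approximation
n₂/n₁ = 1/(k−1) — the bracket is (1/100 + 1/4) at the 5×20 default —
with df = k·r − 1 = 99, one-tailed.

**What our calibration experiment shows.** On 500 null cohorts (zero
effect map, n = 84, default prevalences; 5-fold CV with 5 repeats per
cohort to keep 500 cohorts tractable) the naive test rejects about 30%
of the time at α = 0.05. The corrected test removes most of that
inflation but not all of it: we measure rejection rates of roughly
7–9% rather than 5%, stable across 5, 10, or 20 repeats and across
stratified or unstratified folds. The mean CV AUROC under the null is
unbiased (≈ 0.498), so the residual inflation is a variance phenomenon:
the fixed 1/(k−1) overlap term is a heuristic, and for AUROC at this
sample size it underestimates the dataset-level variance component,
leaving the t statistic over-dispersed (SD ≈ 1.3 instead of ≈ 1.04).
This is a documented property of the correction, not an implementation
artifact — the oracle tests pin the statistic to its closed form — and
it is worth keeping in mind when reading borderline p-values from this
design: the effective size of the one-tailed 5% test is nearer 8%.
`analysis/05_calibration.R` reproduces the experiment.

## The synthetic cohort generator

The generator exists so that every pipeline stage can be tested against
known ground truth. Three latent severities per subject (SAD, GAD, MDD)
are drawn from a standard multivariate normal with pairwise correlation
0.5 — screening comorbidity in real cohorts is substantial, and the
correlation makes co-positive screens common, as they would be.

**Scale scores** are monotone maps of severity plus noise, rounded and
clipped to the instrument range. The intercept is calibrated in closed
form so that the thresholded score hits the target prevalence exactly
for a standard-normal severity: mean = (threshold − ½) −
z₁₋p·√(slope² + noise²). Defaults target 38% / 26% / 37% positive
screens; a 2,000-subject draw lands within a percentage point or two.

**Behavioral parameters** are links of t_f = Σ_d effects[f, d]·severity_d
plus subject-level noise: logit links for rates (speech, screen-on,
darkness), log links for positive quantities (death-word rate, site and
excursion counts, night noise SD, phase jitter). The default effect map
encodes the direction pattern the screening models are expected to
recover — regularity, mobility, and darkness protective for both SAD
and MDD; death words and screen use risk factors for both; speech
presence strongly protective for MDD but slightly adverse for SAD;
sleep disturbance a risk factor for MDD but protective for SAD; GAD
effects zero (behavioral features carry little direct GAD signal;
whatever GAD picks up flows through the severity correlation).
Magnitudes are free parameters chosen once to give a clearly detectable
signal.

**Streams.** Audio volume is a diurnal sinusoid (peak mid-afternoon
local time) with per-day phase and amplitude jitter plus noise; phase
jitter is what erodes daily similarity, and with zero jitter and zero
noise the extracted feature is exactly 1, which the suite asserts. Night
samples get their own noise SD, driving the sleep-disturbance feature.
The GPS trajectory dwells at a home site — always occupied during local
night — and makes excursions to visit sites placed 500 m apart
(> 3ε, so clusters cannot merge); travel fixes advance fast enough to be
non-stationary, so the pipeline's recovered location and exit counts
equal the generator's by construction, and the suite asserts exact
equality on dropout-free subjects. Screen state is an alternating
exponential renewal process with a 13-minute mean cycle; light samples
are dark with probability 0.95 at night and a daytime probability solved
so the expected dark fraction meets the subject's target. Baseline
levels sit at realistic cohort means (speech 0.15, death words 0.16%,
~12 sites, ~15 exits, screen 0.23, darkness 0.63).

**Dropout.** Default is i.i.d. thinning per stream, with a per-subject
mixture: 25% of subjects are lossy recorders retaining 20–45% of
samples (under the sufficiency bar), the rest retain 80–98%. This
reproduces the intended ~75% inclusion rate. A block-dropout mode drops
one contiguous chunk instead, to exercise the sufficiency rule with
realistic outage patterns.

**The feature-level arm.** `simulate_feature_cohort()` shares the
latent-severity and scale-score machinery but emits features directly as
x_f = t_f + N(0, 1), skipping stream synthesis. Experiments that need
hundreds of cohorts (type-I calibration, power across seeds) use this
arm; raw-stream synthesis for 500 cohorts would cost hours without
changing what those experiments measure, which is the modeling layer.

**What the generator does not emulate**: speech-recognition error and
vocabulary drift, device heterogeneity in volume gain, map-realistic
movement (sites sit on a line; travel is piecewise-linear), light-sensor
occlusion (pockets), or diurnal structure in screen use. Passing tests
therefore demonstrate correctness of the pipeline's computations and
recoverability of injected structure — not that real cohorts carry this
much signal. On default synthetic cohorts the models reach mean AUROCs
around 0.8; real smartphone-sensing cohorts of this size typically sit
meaningfully lower, so absolute performance on synthetic data should
not be read as a forecast.

## Numerical and edge-case decisions

- Expected counts use `floor` over the whole window, not per-day
  tallies.
- Duplicate-timestamp GPS fixes drop the later fix with a warning
  (speed would need division by zero).
- Consecutive same-state screen events keep the first; duration
  accounting is unaffected.
- A zero-variance training feature scales to an all-zero column with a
  warning; an all-missing training feature is fatal.
- Zero variance across fold AUROCs with a nonzero mean gives p = 0 with
  a warning; with a zero mean, p = 1.
- All timestamps are stored in UTC with one fixed UTC offset per
  subject; every night/weeknight rule evaluates in that local time.
  Subjects span time zones, and a fixed per-subject offset is the
  simplest model that keeps local-time semantics exact (daylight-saving
  transitions inside a window are ignored).
- Problem sizes in the test suite: oracle checks run on instances of
  ≤ 576 bins / ≤ 50 points; calibration uses 500 feature-level cohorts
  at 5×5 CV; power uses 50 seeds at 5×20; stream-level checks use a
  handful of full 14-day subjects. These sizes were chosen so the whole
  suite completes in a few minutes while keeping every Monte-Carlo
  margin (±2 SE) meaningful.

## Known limitations

- The corrected t-test's residual anticonservatism under these
  conditions (above) is inherent to the fixed-overlap heuristic; an
  exact test does not exist for overlapping-training resampling, and
  alternatives (e.g. 5×2 CV) change the design rather than fix it.
- The half-of-expected sufficiency rule is all-or-nothing per stream; a
  stream at 51% retention contributes features computed from half the
  intended data with no downweighting.
- Home inference assumes the subject sleeps at one location; shift
  workers or split residences would misattribute exits.
- The death lexicon is a fixed word list; it cannot resolve sense
  ambiguity ("dying to see you").
- Volume-derived features assume the phone stays near its owner;
  a phone left in another room all night looks like quiet sleep.
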
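---
title: "Single-case representational similarity analysis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-case representational similarity analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

casersa implements a complete analysis chain for asking whether a single
patient's time-resolved neural representational geometry differs from that of
a small control group — the design used in single-case EEG studies of
acquired prosopagnosia, where one patient viewing a fixed stimulus set (49
images: 24 faces spanning 8 identities × 3 expressions, plus animals,
objects and scenes) is compared against ~18 neurotypical controls. This
vignette documents the models, the estimators, the tunable parameters, and
the design decisions behind each stage.

```{r setup, message = FALSE}
library(casersa)
```

## Decoding-based representational dissimilarity matrices

The representational unit is the time-resolved RDM: for every pair of
stimuli $(i, j)$ and every timepoint $t$, a Fisher linear discriminant is
trained to distinguish single trials of $i$ from single trials of $j$ using
all sensor channels as features, under stratified $k$-fold cross-validation
($k = 5$) repeated 5 times. The dissimilarity is the cross-validated AUC of
the held-out decision values, averaged over folds and then repetitions:
0.5 means the two stimuli evoke indistinguishable sensor patterns, 1 means
perfectly separable. With 49 stimuli there are
$\binom{49}{2} = 1176$ pairs per timepoint.

The discriminant direction is $w = S^{-1}(\mu_j - \mu_i)$ with $S$ the
pooled within-class covariance of the training trials. With 128 channels
and tens of trials the sample covariance is singular, so $S$ is shrunk
toward a scaled identity $\nu I$ ($\nu = \mathrm{tr}(S)/c$) with
analytically chosen Ledoit–Wolf intensity. When the within-class variance
is exactly zero (noiseless toy data) the identity is used, which reduces
$w$ to the mean difference.

Choices a user can change, and their defaults:

* `folds = 5`, `repetitions = 5` — the cross-validation plan.
* `exclude_repeats = TRUE` — one-back repetition trials (the trials that
  carry key presses and stimulus adaptation) are dropped before decoding.
  Whether such trials belong in the decoded set is genuinely open; both
  behaviors are exposed.
* `time_range = c(-200, 800)` ms — the decoded window.
* Class imbalance is resolved by subsampling the larger class to the
  smaller, with a seeded draw, so folds stay stratified.

Two reproducibility contracts are worth stating explicitly because they are
tested, not just intended. First, fold assignments are seeded by the
*unordered* stimulus pair, so decoding $(a,b)$ and $(b,a)$ gives bitwise
identical results. Second, trials are ordered internally by their content
(sums and sums of squares) before any seeded draw, so the result is
invariant to the storage order of the input trials.

At 256 Hz each sample spans 3.906 ms, so "one bin per sample" realizes a
~4 ms analysis grid; a coarser window-averaging mode is deliberately left
out of the default path.

## Temporal generalization of representational geometry

A TGM entry $[s, t]$ is the correlation between the vectorized RDM at time
$s$ and at time $t$: high off-diagonal values mean the geometry at one
latency recurs at another. The correlation is Pearson by default — the
minimal reading of "cross-correlating" RDM vectors — with Spearman as an
option (`metric = "spearman"`), which additionally makes the TGM invariant
to any strictly monotone transform of the dissimilarities. Timepoints whose
dissimilarity vector is constant have no defined correlation; their rows
and columns are set to `NA` and reported, never silently zeroed.

Group TGMs average controls after Fisher z-transform by default (raw
averaging is available); the patient never enters a group mean. TGMs and
all case contrasts are computed on 0–800 ms post-onset; the decoded RDM
series retains the full epoch for plotting.

## Case-versus-controls inference

A patient cannot be compared to controls with a two-sample t-test — the
"sample" of one has no variance. The Crawford–Howell modified t-test treats
the case as a draw from the control population:

$$t = \frac{x^* - \bar{x}}{s\sqrt{(n+1)/n}}, \qquad df = n - 1,$$

which with 18 controls gives $t(17)$. The test is exact under Gaussian
controls, and its type-I error at $\alpha = 0.05$ is verified by Monte
Carlo (10,000 replicates) in the acceptance suite. The same statistic is
mapped over TGM cells (`tgm_case_contrast()`) and over model-correlation
timecourses (`timecourse_case_contrast()`), two-tailed, uncorrected by
default to mirror the field's reporting convention; Benjamini–Hochberg FDR
is available per map. Group-level (non-case) effects use nonparametric
permutation tests, sign-flip across subjects by default, with exhaustive
enumeration whenever $2^n$ does not exceed the requested permutation count.

## Model RDMs and partial Spearman comparison

Model RDMs stand in for hypotheses about *what* the neural geometry
reflects: layer activations of vision networks (`rdm_from_features()` with
`1 - Pearson`), caption-level semantic embeddings (`cosine_distance`), and
binary categorical codes (`categorical_rdm()`, one-hot for a single
dimension or multi-hot concatenation over several, with Euclidean distance
on the codes by default and Hamming as an option). Brain and model RDMs are
aligned through a shared pair index object; a misaligned index is an error,
never a silent positional match — silent misalignment being the classic RSA
bug.

Brain–model correlation uses Spearman's rank correlation with average ranks
for ties (ties are the norm for binary categorical RDMs). Because visual
and semantic models are themselves correlated, the interesting quantity is
the *partial* Spearman correlation: rank-transform all three vectors and
compute the first-order partial
$\rho_{ab\cdot c} = (r_{ab} - r_{ac} r_{bc}) / \sqrt{(1-r_{ac}^2)(1-r_{bc}^2)}$.
The analysis scheme follows the visual/semantic cross-partialling design:
each layer RDM is correlated with the brain partialling out the semantic
RDM, and the semantic RDM partialling out the top visual layer. The formula
is verified against a rank-residualization oracle (residualize ranks by OLS,
Pearson on residuals) to 1e-12; a constant control reduces to the plain
Spearman; a control rank-collinear with an input is flagged `NA`.

## The synthetic cohort generator

No patient recordings are distributable, so the package carries a
first-class generator that emulates the study's data structure end to end:

* **Catalog** (`sim_catalog()`): 49 stimuli, 24 faces (8 identities, 4
  female, × neutral/happy/fearful), 8 animals, 8 objects, 9 scenes.
* **Trial stream** (`sim_epochs()`): a balanced shuffled one-back sequence
  with repetition trials inserted at probability 0.1 (flagged, not counted
  toward the per-stimulus trial budget). The default of ~60 trials per
  stimulus reconstructs ~3,200 trials over two sessions; per-condition
  counts after exclusions are not reported anywhere, so this is a
  reconstruction, not a measured value.
* **Geometry** (`geometry_schedule()`): latency windows each carrying a
  latent pattern matrix (stimuli × latent dimensions) and a gain, with
  20 ms linear cross-fades at window edges. Latent patterns are mapped to
  sensors through a seeded random orthonormal mixing matrix, so pairwise
  pattern distances are preserved exactly in sensor space — the property
  that makes ground-truth recovery checks sharp.
* **Persistence**: after a window closes, a fraction `persistence` of its
  gain survives to the end of the epoch (0 = the control regime). A
  per-window `persistence` column lets only the early representation
  persist, which is the canonical patient abnormality: it produces exactly
  the early×late excess in the patient-minus-controls TGM contrast that
  motivates the analysis.
* **Noise**: i.i.d. Gaussian per sample by default (`noise_sd`), with an
  optional AR(1) temporal correlation (`noise_ar`). No forward head model,
  no ocular or muscle artifacts: passing tests on this generator shows the
  estimators recover known geometry under well-behaved noise, not that they
  are robust to structured artifacts of real EEG.
* **Model features** (`sim_model_features()`): an `abstraction` dial from 0
  (exemplar-unique i.i.d. features, no categorical structure) to 1 (every
  stimulus collapses onto its category prototype), standing in for low
  versus high network layers and semantic embeddings.
* **Behavior** (`sim_behavior()`): one-back accuracy/RT per condition and a
  CFMT+-like score out of 102, with the patient's face-specific measures
  shifted by a configurable number of control standard deviations, and the
  default 18 controls split 15 young + 3 age-matched.

Control means and dispersions (accuracy ~0.90/0.92 with SD 0.04, RTs
~520/510 ms with SD 40 ms, recognition score 88 ± 7) were chosen once as
typical of healthy adults on speeded one-back tasks; they are not fitted to
any dataset.

## Behavioral face-specificity score

Face-specific performance is summarized per participant as
$(\mathrm{face} - \mathrm{nonface})/(\mathrm{face} + \mathrm{nonface})$
separately for accuracy and RT. The RT contrast is negated (faster on faces
= better), both contrasts are standardized, and the first principal
component across participants is the face-specificity score. PCA is
computed on the correlation rather than covariance matrix because accuracy
and RT contrasts have incommensurate scales; the component sign is fixed so
a higher score means better face-specific accuracy. The percent variance
explained by the first component is reported but depends on the cohort at
hand.

## Preprocessing

The minimal ERP chain, in the order re-reference → band-pass → epoch →
downsample: subtraction of a reference channel; a zero-phase Butterworth
band-pass (default 0.01–80 Hz) realized as a high-pass/low-pass cascade —
a single band-pass section at a 0.01 Hz corner and kHz sampling rates is
numerically fragile in transfer-function form, the cascade is not;
segmentation on the half-open window $[-200, 1100)$ ms with the onset
sample included at $t = 0$ (1331 samples at 1024 Hz); and anti-aliased
integer decimation to 256 Hz on a grid aligned to the onset sample.
Filtering is done around the signal mean to avoid DC edge transients, so a
constant channel stays exactly constant. No artifact rejection and no
baseline correction are applied by default, matching the minimal stated
chain; both stages are deliberately out of scope rather than hidden
defaults.

## Numerical and engineering choices

* All randomness flows from explicit integer seeds; per-pair decoding seeds
  are derived from (master seed, unordered pair) and stay below $2^{31}$.
* `run_pipeline()` writes every stage's outputs as CSV/JSON plus a manifest
  with the package version, a configuration hash and per-artifact content
  hashes; rerunning with the same configuration and seed reproduces every
  artifact byte for byte.
* Epoch containers, RDM series and TGMs serialize to plain-text CSV + JSON
  sidecars; the epoch writer uses shortest-round-trip double formatting so
  the round trip is lossless.
* Degenerate inputs fail loudly: zero-variance controls, constant feature
  rows under a correlation metric, constant dissimilarity vectors,
  misaligned pair indices and missing stimuli all raise errors or flagged
  `NA`s rather than producing arbitrary numbers.

## Problem sizes used in the test and acceptance suites

The study-scale configuration (49 stimuli, 128 channels, 256 Hz, ~60 trials
per stimulus, 18 controls) is what the defaults describe, but the verified
ground-truth recovery suites run reduced cohorts chosen as the smallest
sizes at which the phenomena are unambiguous: 8–12 stimuli, 40 trials per
stimulus, 12–16 channels, a 64 Hz grid (52 post-onset bins over 0–800 ms),
6–8 controls per cohort, and 20 simulated cohorts for the
persistence-contrast signature. Calibration checks use 10,000 Monte-Carlo
replicates for the single-case test and 8 simulated null cohorts for the
TGM contrast mask (whose cells are mutually dependent, so the observed mask
fraction is expected near — not exactly at — the nominal 5%).

## Known limitations

* The generator's sensor model is linear mixing plus (optionally AR(1))
  Gaussian noise; real EEG nonstationarities, artifacts and volume
  conduction structure are not emulated.
* Temporal generalization here is RDM cross-correlation, not
  train-at-$t$/test-at-$t'$ classifier generalization.
* Only first-order partial correlations are implemented; variance
  partitioning across more than one control model and noise-ceiling
  estimation are out of scope.
* Cluster-based multiple-comparison correction for contrast maps is not
  implemented; per-cell uncorrected and FDR-adjusted thresholds are.
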
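---
title: "Speech-embedding features for Parkinson's disease and the overlap significance test"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Speech-embedding features for Parkinson's disease and the overlap significance test}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdspeech)
```

## The scientific problem

Hypokinetic dysarthria — reduced loudness, monopitch, imprecise articulation
and a slowed speaking rate — is among the earliest motor signs of
Parkinson's disease (PD), which makes recorded speech an attractive
non-invasive biomarker. A now-standard modelling recipe replaces
hand-crafted acoustic features with the frame-level latent representation of
a self-supervised speech model: each recording becomes a $T \times D$ matrix
of embedding frames (here $D = 512$ channels at a nominal 100 frames/s),
which is collapsed over time into a fixed $D$-vector per subject and fed to
ordinary classifiers and regressors.

Two questions drive the analyses this package implements:

1. **Generalisation.** Does a classifier trained on one speech corpus
   (language, task, recording setup) discriminate healthy controls (HC) from
   PD on a completely unseen corpus?
2. **Shared representations.** Do models trained for *different* tasks
   (HC/PD classification in two languages; regression of age or articulation
   rate) rely on the *same* embedding channels? The package's core statistic
   makes this question testable: it measures the overlap between the top-$k$
   most important features of two fitted models and asks whether that
   overlap exceeds what two random $k$-subsets of the $N$-channel pool would
   share.

## The overlap statistic

Let $A$ and $B$ be the top-$k_1$ and top-$k_2$ importance sets of two models
over the same pool of $N$ features, and $m = |A \cap B|$. Under the null
hypothesis that the two sets are independent uniform draws, the overlap is
hypergeometric:

$$P(X = i) = \frac{\binom{k_1}{i}\binom{N-k_1}{k_2-i}}{\binom{N}{k_2}},
\qquad p = P(X \ge m) = \sum_{i=m}^{\min(k_1,k_2)} P(X = i).$$

This upper tail is exactly the one-sided Fisher exact test on the
$2 \times 2$ table that cross-classifies features by membership in $A$ and
$B$ (`overlap_test()` and `fisher.test(..., alternative = "greater")` agree
to machine precision; the test suite checks this). The test is one-sided
because the scientific question is *enrichment* — whether models share
**more** features than chance. `hypergeom_tail()` accumulates the sum in log
space (`lchoose` + log-sum-exp), so the p-values of near-complete overlaps
(of order $10^{-49}$ for $m = 30$, $N = 512$) remain exact.

Three derived quantities are used throughout:

* **`mc_null()`** — the simulation counterpart: draw two uniform
  $k$-subsets, record $|A \cap B|$, repeat (10,000 runs by default). Its
  mean converges to $k^2/N$ ($30^2/512 = 1.758$ for the default pool), and
  its 99th percentile (5 for $N = 512$, $k = 30$) gives a percentile-based
  significance rule. The exact tail is the reference; the Monte-Carlo null
  is retained because percentile thresholds generalise to statistics with
  no closed form, and because it provides an independent check of the tail.
* **`min_significant_overlap()`** — the smallest $m$ with
  $c \cdot P(X \ge m) < \alpha$, where $c$ is a Bonferroni factor. At
  $\alpha = 0.05$, $c = 1$, $N = 512$ this gives $m^* = 2, 3, 5, 9$ for
  $k = 10, 20, 30, 50$; with $c = 3$ (the three pairwise tests of a
  three-set Venn diagram) and $k = 30$ it gives $m^* = 6$.
* **`overlap_matrix()`** — all pairwise tests for a family of rankings plus
  Venn region counts, with $c$ defaulting to the number of pairs in the
  family.

Two boundary conventions are worth stating. First, `overlap_test()` uses a
strict comparison (`corrected p < alpha`). Second,
`min_significant_overlap(alpha = 1)` returns 0 by convention: with
$\alpha \ge 1$ every overlap is declared significant even though
$P(X \ge 0) = 1$ never satisfies the strict inequality; the degenerate case
is special-cased rather than propagating an `NA`.

For small pools the exact-tail thresholds can differ by one or two features
from thresholds derived from simulation percentiles or from two-sided
tests; e.g. for a 50-feature pool the exact tail at $\alpha = 0.05$ gives
$m^* = 3, 5, 8, 12$ for $k = 5, 10, 15, 20$. This package always uses the
exact one-sided tail and reports it alongside any simulation output, so the
criterion in use is unambiguous.

### Repeated-overlap stability

A single pair of rankings can overlap by luck of one model fit.
`repeated_overlap_experiment()` refits the importance model of both tasks
(by default the random-forest impurity variant, whose refits genuinely
differ) with seeds derived from one master seed, extracts top-$k$ sets at
several $k$, and reports mean ± sd overlap per $k$. A column is flagged
`**` when the *mean* overlap reaches $m^*(N, k)$ (significant on average)
and `*` when mean + 1 sd reaches it (significant within one standard
deviation). Thresholds come from the exact tail at $\alpha = 0.05$.

## Feature construction

* **Loud-region duration** (`loud_region_duration()`): a deliberately naive
  proxy for reading duration. Each sample is encoded 1 iff its absolute
  value *strictly* exceeds the signal's mean absolute value ("exceeds"
  is read as strict; ties, including the all-zero signal, encode 0). The
  binary vector is smoothed by a 10,000-sample rolling average and summed.
  Two conventions were genuinely open and are exposed as arguments:
  * *Edge mode*: trailing full windows only (`n - window + 1` values) is
    the default; a centered `"same"` mode with partial windows is optional.
  * *Units*: the smoothed sum is divided by the sampling rate and reported
    in seconds, which is what a duration distribution plot should show; the
    raw sample-unit sum is attached as the `"raw_sum"` attribute.
* **Embedding pooling** (`aggregate_frames()`): per-channel mean, standard
  deviation or sum over the time axis. The std divisor is the population
  one (divide by $T$), matching the default of the array libraries this
  representation usually comes from; a single frame therefore pools to a
  zero std vector. Note that `sum` pooling is duration-sensitive while
  `mean` is not — that is a feature, not an accident: articulation-rate
  targets are partly encoded in recording length.
* **MFCC means** (`extract_mfcc_mean()`): 50 coefficients (Hann STFT,
  128-band triangular mel filterbank on the HTK mel scale, log energies,
  orthonormal DCT-II), each averaged over frames. The extractor lives in
  the package because the installed R stack offers none; the output
  contract (50 finite values, deterministic, 16 kHz input enforced) is what
  downstream code relies on, not the filterbank internals.
* **PCA combo** (`pca_combo()`): 10 leading components of the embedding
  block concatenated with 10 of the MFCC block, after per-feature
  standardization. Cumulative explained variance per block is reported and
  a warning fires below 90%. Where the PCA is *fitted* was an open design
  point: for modelling, the rotation is fitted on training rows only
  (`fit_rows`) to avoid leakage; for visualisation it may be fitted on all
  rows. The rotation's sign ambiguity is harmless downstream (classifiers
  and importance magnitudes are sign-invariant).

## Model harness

Classification uses stratified 5-fold cross-validation with 5 repeated
fits (stratification is a package choice — with 16–30 subjects per class,
unstratified folds can lose a class), random forest (100 trees, Gini) as
the default model, gradient boosting reduced to a binary logistic
objective, and a ridge-stabilised logistic baseline. AUROC is computed by
the rank formulation ($P(s^+ > s^-) + \tfrac12 P(\text{tie})$) and averaged
over fold × repeat; all scores are out-of-fold. Cross-corpus rows are *not*
cross-validated: the model is fitted once on the full training corpus
(or pooled pair) and scored on every row of the unseen corpus, which is the
honest external-validation protocol. `scenario_grid()` enumerates the 15
rows: 3 intra, 3 mixed-pool, 6 single-cross, 3 pair-cross. No
hyperparameter tuning happens anywhere.

Regression uses the lasso with a fixed L1 penalty of 0.01 on standardized
features (`glmnet` with `lambda = 0.01`, matching the `1/(2n)`-scaled
objective of the common Python implementation at `alpha = 0.01`), 5-fold
unstratified CV, and reports Spearman rho, $r^2 = 1 - SSE/SST$ and MAE per
fold. A constant prediction vector has no defined rank correlation; rho is
`NA` with a warning rather than a silent 0.

## Importance methods

* `rank_linear()`: absolute standardized logistic coefficients.
  Magnitude, not signed value, is ranked — the question is *whether* a
  channel matters, not in which direction. With $D = 512$ channels and a
  few dozen subjects the unpenalized MLE does not exist, so a small ridge
  penalty (0.01) is applied whenever the plain fit is rank-deficient,
  separated or non-converged, with a message. This also gives duplicated
  columns finite, evenly split scores.
* `shapley_mc()`: Monte-Carlo Shapley values by permutation sampling. For
  each instance and each sampled ordering, features switch one at a time
  from a random background row to the instance; the marginals telescope, so
  efficiency ($\sum_j \phi_j = f(x) - \bar f(\text{background sample})$)
  holds *exactly* per instance against the sampled baseline — the test
  suite asserts this at $10^{-10}$, and the additive-game closed form
  $\phi_j = w_j (x_j - \bar z_j)$ within 3 Monte-Carlo standard errors.
  Global importance is the mean absolute attribution over instances, the
  standard global reduction; the background is the training set (optionally
  subsampled with a seed) and importances are computed on training rows.
* `rank_impurity()`: random-forest impurity importance, included because
  the repeated-overlap experiments need a method whose refits vary.

Ties in every ranking break by (score descending, index ascending), making
`top_k()` deterministic and nested ($\text{top}_k \subseteq
\text{top}_{k+1}$).

## What the synthetic cohorts emulate — and what they do not

`make_three_dataset_suite()` generates the three study cohorts at their
real sizes: 60 subjects (30 HC / 30 PD, a syllable-repetition cohort),
50 subjects (22 elderly HC / 28 PD) plus 15 young HC used only for
regression (65 in all), and 37 subjects (21 HC / 16 PD; no age or gender
metadata, mirroring the third corpus's documentation). Per subject, channel
means are drawn $N(0, \sigma^2)$; PD subjects are shifted by
$\text{effect\_size} \cdot \sigma$ on 30 planted channels; frames are
i.i.d. around the subject mean (optionally AR(1)-correlated across
channels, since real embedding channels are far from independent).
Quantitative targets are linear in the planted target channels plus noise:
age (intercept 70, bimodal via a negative shift on the age channels for the
young group, reproducing the 19–29 vs 60–80 two-cluster age structure and
the model-gap limitation it causes), characters per second (intercept 12
chars/s) and loud-region duration (intercept 25 s). The two read-text
cohorts share their planted class channels; the syllable cohort's are
disjoint — the cross-lingual sharing pattern the overlap pipeline should
recover. Defaults (`effect_size = 3`, `noise_sd = 1`, 30 planted channels,
frame counts uniform in 60–120 to keep aggregation ragged-proof) were fixed
once as the package's study conditions.

The generator reproduces only the *statistical* structure the analysis
assumes: planted discriminative channels, linear target drivers,
controllable sharing. It has no phonetics — no formants, no phones, no
speaker or recording-channel effects, no heavy-tailed noise. Passing tests
therefore certify the machinery (calibration, recovery, determinism), not
clinical performance on real speech; real-corpus AUROCs cannot be inferred
from it.

The synthetic `embedding_provider()` is the same idea one level down: a
fixed, seeded random projection of 40-band log-mel energies to 512
channels with a tanh squashing. It is deterministic, preserves loudness
and duration information, and stands behind the same contract a pretrained
adapter would (`embed_fn`), so every downstream stage is testable offline.

## Numerical and testing choices

Determinism is end to end: every stochastic step takes a seed, child seeds
are derived from one master seed by a fixed affine map modulo $2^{31}$, and
reruns of `run_pipeline()` produce byte-identical tables. Test problem
sizes were chosen to keep the default suite around a minute: null
calibration uses 200 three-channel cohorts; the planted-overlap recovery
experiment uses 50 seeds of 20-per-class cohorts at full 512-channel width
with short frame streams; the end-to-end sharing-pattern check runs the
full-size suite over 25 seeds. The brute-force oracles (explicit-loop
loud-region duration up to $10^5$ samples, $O(n^2)$ AUROC pair counting up
to $n = 200$, full enumeration of the overlap tail up to $N = 12$) are
kept deliberately independent of the vectorised implementations they
check.

Known limitations: the MFCC extractor is a plain HTK-style implementation,
adequate as a baseline feature but not bit-compatible with any specific
Python library; `signal::resample`'s polyphase filter leaves a few edge
samples of transient, so resampled lengths are trimmed to the expected
count; the gradient-boosting backend underperforms on very small folds
(it is not the default model); and with ridge-regularised logistic
importance, cross-task overlap tests on *linear* models can be anti-
conservative when cohorts share subject-level confounders — the synthetic
suite has none, real corpora might.
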
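# pdspeech

Cross-corpus speech-embedding analysis for Parkinson's disease (PD), with
an exact significance test for the overlap of important-feature sets
across models.

## What problem this solves, and for whom

Hypokinetic dysarthria makes speech one of the earliest measurable signs
of PD. A common modelling recipe pools the frame-level output of a
self-supervised speech model (a T × 512 embedding matrix per recording)
into one fixed vector per subject — per-channel mean, standard deviation
or sum — and trains ordinary classifiers (HC vs PD) and regressors (age,
articulation rate) on those vectors. Two questions follow for anyone
building such models:

* does a classifier trained on one corpus transfer to a completely unseen
  corpus (different language, speech task, recording setup)?
* do models trained for different tasks rely on the **same** embedding
  channels — i.e. is there a shared latent speech representation of PD?

`pdspeech` implements the full analysis pipeline for both questions:
feature construction from raw audio and frame matrices, a repeated
stratified cross-validation and cross-corpus evaluation harness, global
feature-importance rankings (standardized logistic coefficients,
Monte-Carlo Shapley attribution, random-forest impurity), and — the core
statistic — a one-sided exact hypergeometric (Fisher) test for the overlap
of two top-k importance sets, with a Monte-Carlo null, Bonferroni
correction, minimum-significant-overlap thresholds, Venn summaries and a
repeated-refit stability experiment. A synthetic cohort generator with
planted discriminative channels makes every stage testable with known
ground truth, offline.

## The core statistic

For top-k sets A and B from an N-feature pool with overlap m = |A ∩ B|,
the null distribution of the overlap is hypergeometric and the one-sided
p-value is the exact upper tail

P(X ≥ m) = Σ_{i=m}^{min(k1,k2)} C(k1, i) · C(N−k1, k2−i) / C(N, k2),

computed in log space (`hypergeom_tail()`). For the default pool
(N = 512, k = 30) the null overlap has mean k²/N ≈ 1.76 and 99th
percentile 5; the smallest overlap significant at α = 0.05 is 5, rising
to 6 after a ×3 Bonferroni correction for the three pairwise tests of a
three-model Venn diagram (`min_significant_overlap()`).

## Worked example

```r
library(pdspeech)

suite <- make_three_dataset_suite(seed = 1)   # three cohorts, planted truth
suite
#> <cohort_suite>
#>  pa: 60 subjects
#>  italian: 65 subjects
#>  english: 37 subjects

tables <- lapply(suite, pooled_feature_table, classification_only = TRUE)

# intra-corpus: 5-fold x 5-repeat stratified CV, random forest
cv_classify(tables$italian, "random_forest", seed = 1)
#> <pd_eval intra: train=italian test=italian model=random_forest features=emb_mean>
#>   mean AUROC = 1.000 over 25 fold-fits

# cross-corpus: fit once on one corpus, score the unseen one
crossdb_classify(tables$english, tables$italian, "random_forest", seed = 1)
#> <pd_eval cross: train=english test=italian model=random_forest features=emb_mean>
#>   mean AUROC = 1.000 over 1 fold-fits

# regression of articulation rate (characters per second), lasso + 5-fold CV
cv_regress(pooled_feature_table(suite$italian), "chps", seed = 1)
#> <pd_reg target=chps lasso(lambda=0.01)>
#>   mean rho = 0.737, r2 = 0.507, MAE = 0.847 over 5 folds

# do the three classification models share important channels?
rks <- lapply(tables, rank_features, task = "classification",
              method = "linear_coef")
overlap_matrix(rks, k = 30, N = 512)
#> <overlap_matrix: k = 30, N = 512, correction = 3>
#>        a       b  m            p  p_corrected significant
#>       pa italian  0 1.000000e+00 1.000000e+00       FALSE
#>       pa english  0 1.000000e+00 1.000000e+00       FALSE
#>  italian english 30 3.325369e-49 9.976108e-49        TRUE

mc_null(512, 30, runs = 10000, seed = 1)
#> <overlap_null: N = 512, k = 30, 10000 runs>
#>   mean overlap = 1.758 (analytic k^2/N = 1.758)
#>   percentiles: 50% = 2, 95% = 4, 99% = 5

min_significant_overlap(512, 30, correction = 3)
#> [1] 6
```

Reading the output: the two read-text cohorts were generated with shared
planted class channels and the syllable cohort with disjoint ones, so the
pipeline correctly flags only the italian–english pair — their models
share all 30 top channels (p ≈ 3×10⁻⁴⁹ after correction), while the pa
pairs share none. Any overlap of 6 or more would have survived the
corrected threshold; two random 30-channel sets share only ~1.76 channels
on average.

`run_pipeline(pipeline_config(seed = 1))` orchestrates all of the above
(scenario grid, regression metrics, rankings, overlap tables, null
distribution, duration summaries) and writes tab-delimited tables plus a
JSON manifest stamped with the config hash and master seed.

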
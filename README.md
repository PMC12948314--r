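# omicsCAE

Multi-omics cancer subtype discovery with attention-augmented
convolutional autoencoders and survival-driven feature selection.

## What it does, and for whom

Given a cohort profiled on several omics layers (mRNA expression,
miRNA expression, DNA methylation) together with survival follow-up,
omicsCAE stratifies patients into molecular subtypes with distinct
prognoses.  It is aimed at computational biologists who want a
self-contained, seeded, testable R implementation of this integration
strategy — including its ablation variants and baseline reducers — rather
than a cloud-scale deep-learning stack.

The pipeline, per omics layer and then jointly:

1. **Preprocess** — keep the most variable features (3000 RNA / 100
   miRNA / 1000 methylation by default), min–max normalize
   (`x' = (x − x_min)/(x_max − x_min)`), and reorder features by the
   geometric mean of their absolute Pearson correlations
   `ρ_i = (∏_j |r_ij|)^(1/n)` so convolution windows cover correlated
   neighbourhoods.
2. **Encode** — a 1-D convolutional autoencoder (two strided
   convolutions → channel attention → dense latent; mirrored decoder)
   trained to minimize reconstruction MSE.  The channel-attention block
   pools each channel globally by average and max, runs both pooled
   vectors through one shared bottleneck MLP, adds the branches
   (`M = M_avg + M_max`) and gates the feature map once:
   `F' = F ⊙ σ(M)`.  PCA and NMF are drop-in baseline reducers.
3. **Select** — L1-penalized Cox partial likelihood (cross-validated
   penalty) keeps latent features with non-zero coefficients; a
   univariate Cox screen then keeps those with p < 0.05.  Selected
   features from all layers are concatenated.
4. **Cluster** — K-means over k ∈ {2,3,4,5}; k chosen by
   silhouette-gated minimum log-rank p, with CH, DB and GMM-BIC
   diagnostics reported for every k.
5. **Evaluate** — Kaplan–Meier curves, the k-sample log-rank test
   (`Z = (O₁−E₁)/√V₁` at k = 2, χ² with k−1 df beyond), Harrell's
   concordance index with a percentile-bootstrap 95% CI, an SVM
   pseudo-label classifier (stratified 70/30, grid-searched), χ²
   clinical associations with Cramér's V and Benjamini–Hochberg FDR, and
   ARI/NMI agreement against any reference labeling.

Ablation variants mirror the method's own: `no_attention` (attention
block → identity) and `no_cox` (survival feature filtering skipped).
A seeded synthetic-cohort generator with planted subtypes,
block-correlated features and subtype-dependent censored survival is a
first-class module and the test bed for everything above.

## Worked example

```r
library(omicsCAE)

## A seeded synthetic cohort: 300 patients, 3 planted subtypes with
## hazard ratios 1:2:4, three omics layers, 30% censoring.
sim <- generateCohort(simulationConfig(seed = 1))
sim$cohort
#> MultiOmicsCohort: 300 samples, 3 layer(s)
#>   rna          [rna] 300 features
#>   methylation  [methylation] 200 features
#>   mirna        [mirna] 100 features
#>   survival: 219 events, 81 censored

## Desk-scale pipeline settings shared by tests and acceptance script.
bm <- standardBenchmark(seed = 1)
report <- runPipeline(sim$cohort, bm$pipeConfig,
                      referenceLabels = sim$truth$subtype)
report
#> EvaluationReport (full, reducer cae, seed 1)
#>   n = 300, chosen k = 3
#>   log-rank: chi-square = 73.579, df = 2, p = 1.05e-16
#>   C-index = 0.678 (95% CI 0.632-0.716)
#>   SVM test accuracy = 0.989
#>   agreement vs reference: ARI = 0.981, NMI = 0.970
```

Reading the output: the pipeline chose k = 3 (the true number of
planted subtypes); the log-rank χ² of 73.6 on 2 df says the three
recovered subtypes have sharply different survival; the C-index of 0.68
is the concordance of the Cox linear predictor built on the selected
latent features; ARI/NMI near 1 mean the recovered labels almost
perfectly match the planted ground truth.  `report$perK` holds the
per-k silhouette, log-rank p, CH, DB and BIC table behind the k choice.

Ablations and baselines run through the same interface:

```r
tab <- compareVariants(sim$cohort, bm$pipeConfig,
                       variants = c("full", "no_attention", "no_cox"),
                       referenceLabels = sim$truth$subtype)
```

Real cohorts enter through `readOmicsMatrix()` (Xena-style
features-as-rows TSV), `readSurvivalTable()` (`sample`, `time`,
`event`), `readClinicalTable()`, then `dropMissing()` and
`alignCohort()`.  A thin CLI wraps the same functions:

```sh
inst/exec/omicscae simulate --out cohort/ --seed 7
inst/exec/omicscae run --rna cohort/rna.tsv --mirna cohort/mirna.tsv \
    --meth cohort/methylation.tsv --survival cohort/survival.tsv \
    --out results/ --seed 7
```

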
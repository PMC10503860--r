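---
title: "Disentangling accelerated cognitive decline: model and methods"
author: "neuroslope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disentangling accelerated cognitive decline: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neuroslope)
```

## The problem

Cognitive decline in an aging cohort mixes two processes: the decline everyone
experiences with normal brain aging, and the accelerated decline driven by
neurodegenerative disease. A cognitive battery such as the ADAS-Cog13 (0-85
points, higher is worse) measures their sum. `neuroslope` separates them with
longitudinal structural MRI: a model trained to predict cognitive scores from
brain images of cognitively normal subjects learns the *aging-related* part of
the score, so the residual of a subject's measured decline slope on the
model-predicted slope isolates the *accelerated* component, which then serves
as a quantitative trait for a genetic association scan.

The pipeline has six stages, each exposed as plain functions and chained by
`run_pipeline()`:

1. **Pairing** — link each score to the nearest scan within 45 days, keep
   subjects with at least three matched visits whose diagnosis moves only
   forward along CN → MCI → AD, and enumerate all visit pairs (adjacent or
   not) separated by 6 to 24 months.
2. **Dual-loss Siamese model** — fit the shared-weight encoder with a
   regression head on the first-visit score and a contrastive head on the
   embedding distance; select the epoch with the lowest validation
   MSE + contrastive sum on a by-subject 70/30 split.
3. **Slope derivation** — per-pair predicted slopes, per-subject medians,
   rank-based inverse normal transformation, and residualization.
4. **Genotype QC** — info score, missingness, MAF and exact-HWE filters;
   KING-robust kinship with greedy removal of pairs above 0.0884; LD pruning
   (`window 50, step 5, r^2 0.2`); principal components.
5. **Association** — per-variant OLS of the transformed slope phenotype on
   ALT dosage with sex, transformed median age, 10 PCs, and (Model 1) the
   transformed predicted aging slope as covariates.
6. **Loci** — candidates at `p < 1e-5`, greedy clumping at `r^2 >= 0.6`,
   re-pruning of clump leads at `r^2 >= 0.1`, and merging of loci separated
   by less than 250 kb.

## The dual-loss Siamese model

A pair of volumes $(X_{t_i}, X_{t_j})$ from one subject passes through the
same encoder $G_w$ (weight sharing makes the two embeddings comparable). Two
losses act simultaneously:

* **Regression (MSE)**: a linear head on the embedding predicts the
  ADAS-Cog13 score at the *first* time point, anchoring the embedding scale
  to the cognitive baseline.
* **Contrastive**: with $D_w = \lVert G_w(X_{t_i}) - G_w(X_{t_j}) \rVert_2$
  and pair label $Y$ (1 when the absolute score change is at least the
  change threshold, 4 points by default),
  $L = (1-Y)\,D_w^2 + Y\,\max(0, m - D_w)^2.$
  Same-class pairs are pulled together; different-class pairs are pushed
  beyond the margin $m$.

The total training loss is `mse_weight * MSE + contrastive_weight * L`
(defaults 1 and 1); model selection always uses the unweighted sum of the two
validation losses. Training uses Adam with mini-batches of 4, an initial
learning rate of `1e-4` and a step schedule multiplying by 0.1 every 10
epochs over 200 epochs — these defaults describe full-scale training; the
compact studies below use a shorter schedule.

The predicted *aging slope* of a pair applies the shared regression head to
each image independently and differences the outputs:
$(\hat y(X_{t_j}) - \hat y(X_{t_i})) / \Delta t$. Weight sharing makes this
well-defined: identical images give exactly zero slope. The per-pair
normalized predicted error (NPE) is $(\hat y_i - y_i)/\Delta t$, summarized
by its mean and sd over validation pairs.

### Encoder architecture

The encoder is a fixed block-average-pooling front end (default to an
$8^3$ grid) followed by a configurable dense multilayer perceptron
(default one hidden layer of 32 ReLU units into a 16-dimensional linear
embedding). This design was chosen over a deep 3D convolutional encoder
deliberately: the scientific content of the method lives in the dual-loss
pairing scheme, not in the convolution; a pooled dense encoder fits in
seconds on one CPU thread, is exactly reproducible (no non-deterministic
reductions), and is expressive enough to read out the regional mean
intensities that carry the signal in both the phantom cohorts and, to first
order, real atrophy patterns. Forward and backward passes are hand-written
base-R matrix algebra; gradients are validated against finite differences in
the test suite. Depth and width are configurable through
`siamese_control(hidden = ...)` for users who want a larger encoder.

### Numerical choices

* Inputs are min-max scaled to $[0,1]$ per volume. The phantom generator
  guarantees near-0 (air) and near-1 (bright rim) anchor voxels in every
  volume, so this scaling is a near-identity map and cannot erase the linear
  intensity encoding.
* Features are standardized (mean/sd over the *training* scans, stored with
  the model), and the regression head's bias starts at the mean training
  score. Both are standard conditioning devices; without them the inverse of
  the small intensity-per-point encoding slope would demand implausibly
  large weights from a short optimization run.
* The training/validation split is by subject, never by pair; 414 subjects
  at fraction 0.7 give 289 training and 125 validation subjects
  (`floor(n * fraction)` training subjects of a seeded permutation).
* The contrastive gradient at $D \to 0$ uses a guarded denominator
  (`max(D, 1e-12)`); the $Y=0$ branch differentiates $D^2$ directly and
  needs no guard.
* A single global seed drives every stochastic stage through
  `derive_seed(seed, stage)`, a deterministic string hash, so one integer
  reproduces the whole pipeline bit for bit.

### Mini-training configuration

The recovery studies in the tests and the acceptance script use 60 subjects,
$32^3$ phantoms, 30 epochs, learning rate `1e-3` and decay factor 0.5 every
10 epochs. The shorter, warmer schedule is the appropriate optimization
setting for a small dense encoder on a few hundred pairs (the full-scale default
schedule of `1e-4`/0.1 is tuned for a very deep network over 200 epochs and
leaves a 30-epoch run undertrained). Problem sizes were chosen so the whole
suite runs in well under a minute of training time.

## The synthetic cohort

`simulate_cohort()` draws, per subject, a baseline score, a normal-aging
slope (points/year), and an acceleration
$a = \sum_k \beta_k g_k + \varepsilon$ built from planted causal variants
plus a normal residual, then generates visits at jittered ~6-month intervals
with scores
$\mathrm{score}(t) = \mathrm{baseline} + (\mathrm{aging} + a)\,t + \mathrm{noise}$,
clipped to $[0, 85]$. Diagnoses (CN/MCI/AD) are assigned by tertiles of the
true acceleration so group contrasts exist by construction. Each visit gets a
phantom volume: air background, bright rim, an *aging region* whose mean
intensity decreases linearly with the aging score component
($0.8 - 0.006$/point by default) and a disjoint *disease region* encoding
the disease component. Genotypes are Hardy-Weinberg draws (two Bernoulli
haplotypes per sample) with optional LD blocks in which haplotype alleles
copy from the previous variant with a configurable probability.

What the phantoms deliberately do **not** emulate: anatomy, bias fields,
registration error, partial-volume effects, or overlapping atrophy patterns
between aging and disease. Passing the recovery tests therefore shows that
the estimator is correct when its assumptions hold — a linearly encoded,
spatially separated signal — not that a small dense encoder would match a
deep 3D CNN on real MRI.

The noise-controlled recovery study sets score noise, volume noise *and*
acceleration to zero. Zeroing the acceleration is the simulation analogue of
training on cognitively normal subjects only: with a nonzero acceleration the
phantom's disease region legitimately encodes part of the total slope, and a
well-fitting score predictor will use it, so its predicted slope tracks the
*total* rather than the *aging* slope. On the noise-controlled cohort the
held-out Spearman correlation between predicted and true aging slopes is
~0.98-1.00 across seeds.

## Slope analysis and association

The inverse normal transformation maps values through their ranks to normal
quantiles, $\Phi^{-1}\!\big((r - k)/(n - 2k + 1)\big)$ with Blom's offset
$k = 3/8$ and average ranks for ties (deterministic; no random tie
breaking). It is applied to the median measured slope, the median predicted
slope and the median age; sex stays binary. The accelerated slope is the OLS
residual of the transformed measured slope on the transformed predicted
slope — by default without further covariates, which keeps the residual a
pure "decline beyond normal aging" summary; covariates can be supplied where
a fully adjusted residual is wanted. The association scan itself offers
two designs: Model 1 adjusts for the predicted aging slope, Model
2 omits it; p-values come from the finite-sample t distribution.

Missing dosages are left missing for MAF and HWE counting, mean-imputed for
PCs, and handled per variant in the scan (complete-case by default, matching
the per-variant `n` bookkeeping; mean imputation available). A variant whose
design is rank-deficient is flagged and reported with `NA` statistics rather
than silently dropped.

The HWE filter uses the exact conditional test (summing the probabilities of
all heterozygote counts no more probable than the observed one); kinship uses
the KING between-family robust estimator
$\phi = (N_{Aa,Aa} - 2N_{AA,aa}) / (N_{Aa}^{(i)} + N_{Aa}^{(j)})$; both are
verified against independent enumeration/simulation oracles in the tests.
Kinship needs a genome-scale marker count to be usable with the 0.0884
second-degree cutoff: its null sd is ≈0.013 at 5,000 independent markers,
so small-panel kinship estimates should not be fed to `remove_related()`.
Ancestry projection onto an external reference panel is replaced by PCs
computed on the study sample itself (computed after relatedness removal);
`compute_pcs()` accepts any pruned genotype set, so projecting onto a
reference cohort remains possible by stacking samples.

Design details the procedure leaves open, resolved here and tested: the scan-matching tie (equidistant scans) goes to the *earlier*
scan; "no more than 2 data points" is read together with "more than two
visits" as requiring ≥ 3 matched visits; a month is 30.4375 days and the
6-24-month pair window is inclusive on both ends; the pair label uses the
absolute score change with a configurable 4-point threshold (a commonly used
clinically meaningful ADAS-Cog change); LD pruning removes the lower-MAF
member of an offending pair (tie: later position); clumping computes LD
within a 1,000-kb window; the margin defaults to $m = 1$ with unnormalized
embeddings.

## Worked example

```{r example, eval = FALSE}
cfg <- sim_config(n_subjects = 60, score_noise_sd = 0, volume_noise_sd = 0,
                  acceleration_sd = 0, seed = 11)
cohort <- simulate_cohort(cfg)
visits <- cohort$visits
scans <- data.frame(subject_id = visits$subject_id,
                    scan_day = visits$visit_day, scan_id = visits$scan_id)
matched <- match_scores_to_scans(visits[setdiff(names(visits), "scan_id")],
                                 scans, 45)
pairs <- build_pairs(filter_subjects(matched))
fit <- fit_siamese(pairs, cohort$scans,
                   siamese_control(learning_rate = 1e-3, decay_factor = 0.5,
                                   epochs = 30, seed = 99))
preds <- predict(fit, pairs, cohort$scans)
val <- preds[preds$subject_id %in% fit$split$val, ]
med <- median_subject_slope(val, "predicted_slope")
truth <- cohort$truth$subjects
cor(med$median_slope,
    truth$aging_slope[match(med$subject_id, truth$subject_id)],
    method = "spearman")
```

## Limitations

* The encoder is not a deep 3D CNN; real-MRI performance claims are out of
  scope, and full-data error levels from deep-CNN studies are not
  reproduced here.
* The kinship estimator implements only the between-family form; inbred or
  admixed-family structures are not modeled.
* Gene-level aggregation, imputation, external-reference ancestry analysis,
  PRS, genetic correlation and colocalization are intentionally outside the
  package; only the Bonferroni threshold utility for gene-level scans is
  provided.
* Loci are defined from sample LD of the analysis cohort; with very small
  samples the r² estimates, and hence clump membership, are noisy.
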
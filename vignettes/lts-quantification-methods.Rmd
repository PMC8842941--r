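---
title: "Quantifying Lewy-type synucleinopathy in whole-slide images: models and design"
author: "LTSquant authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying Lewy-type synucleinopathy: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(LTSquant)
```

LTSquant quantifies Lewy-type synucleinopathy (LTS) — α-synuclein-positive
neuritic objects revealed by DAB immunohistochemistry — on digitized
submandibular-gland biopsy slides, and predicts Parkinson's-disease status
and stage from the resulting per-slide features. This vignette is the
package's own account of the models it implements, the parameters that
matter, and the design decisions taken where the problem left room.

## 1. The detection model

### Confidence-ranked ground truth

Neuritic objects are annotated with a class (`foreground` LTS vs
`background` immunopositive structures such as granules or macrophages) and,
for foreground, a confidence rank reflecting annotator certainty:
`definite` (clear linear neurites), `probable` (intermediate), `possible`
(dot-like cross-sections). Ground-truth quality is quantified with Fleiss'
kappa and raw percent agreement over an items × raters table
(`fleissKappa()`, `pairwiseAgreement()`); `excludeRank()` reproduces the
sensitivity analysis in which ambiguous `possible` objects are removed.
Kappa is computed after dropping categories never used by any rater, so
empty categories cannot distort the chance-agreement term; a unanimous
table returns exactly 1.

### Weighted patch classification

Rather than localizing individual objects — often small, densely packed and
ambiguous in section — the detector answers a simpler question per
151 × 151-pixel patch: does this window contain any LTS object? The
annotation rank sets the loss weight of each training patch:

| patch content                    | weight |
|----------------------------------|--------|
| definite LTS                     | 5      |
| probable LTS                     | 4      |
| possible LTS                     | 3      |
| false-positive replay            | 2      |
| background / artifact / nothing  | 1      |

with the label `LTS` iff the window intersects at least one foreground
object and the weight equal to the maximum over intersecting objects (any
non-zero geometric overlap counts; no area cutoff). The training objective
is the batch mean of `weightedCrossEntropy()`, so a mispredicted
definite-rank patch incurs exactly five times the penalty of an identically
mispredicted weight-1 patch, and all-unit weights recover plain
cross-entropy — both properties are asserted to machine precision in the
test suite.

The backbone is pluggable: anything exposing
`predictProba(model, window)` satisfies the inference contract. The
shipped reference network is a single-hidden-layer perceptron over
stain-aware pooled features: each window is colour-deconvolved with the
fixed H-DAB basis and the hematoxylin (mean-pooled) and DAB (mean- and
max-pooled) concentration maps on a 12 × 12 grid form the input. The
max-pooled DAB map is what lets 2–3-pixel-wide neurite strokes survive the
pooling. Rotation and flip augmentation is applied as an exact 8-fold
dihedral expansion of the pooled maps, which teaches position invariance
cheaply; smoothing, sharpening, contrast, brightness and a
quantization-based stand-in for JPEG compression operate on raw windows.
Training uses Adam with decoupled weight decay; the full-scale defaults
(learning rate 1e-5, weight decay 1e-3, batch 32, 80 epochs) are retained
in `trainConfig()` for documentation, while desk-scale runs use a higher
learning rate and fewer epochs. A GPU-scale convolutional backbone is
deliberately out of scope; the weighted-loss and inference contracts are
the portable part.

### Strided inference

`inferSlide()` scans the slide with full 151 × 151 windows at a 40-pixel
stride (row-major from the top-left; partial edge windows are skipped
because the classifier has a fixed input size — boundary cells inherit
coverage from the last full windows). Each window's probability is written
to its pixel footprint and overlapping windows are combined with `max`
(configurable to `mean`); max preserves the detector's high-recall
behaviour, since one confident window suffices to flag a focus. A 40 × 40
cell of the patch grid is positive when the aggregated mask reaches the
threshold anywhere inside it. The default binarization threshold of 0.5 is
a plain convention, exposed in the API. The positive-cell geometry is
verified against brute-force window enumeration in the tests.

## 2. Stain separation

Brightfield intensities follow the Lambert–Beer relation
`I_c = I0_c · 10^(−OD_c)`; `odTransform()` inverts it per channel (zero
intensities clamped to 1 grey level and counted) and
`deconvolveStains()` solves `OD = c_H v_H + c_D v_D + c_R v_R` per pixel
against the standard H-DAB optical-density basis
(H ≈ (0.650, 0.704, 0.286), DAB ≈ (0.269, 0.568, 0.778), both normalized;
residual = their normalized cross product). The 3 × 3 system is exactly
determined, so the solve is also the least-squares solution; negative
concentrations are clamped to zero and counted. Per-slide blind basis
estimation and cross-scanner normalization are out of scope.
`stainStatistics()` pools all pixels inside detector-positive cells and
reports sum, mean, median and SD per channel; whether to pool pixels or
average per-patch statistics was left open by the problem, so pooling is
the default and per-patch averaging sits behind `perPatch = TRUE`. All SDs
in the package use the population denominator `n` — a fixed, documented
convention. `tissueMask()` calls a pixel tissue when the median-smoothed
OD magnitude reaches 0.05, a threshold low enough to catch lightly
counterstained gland parenchyma and high enough to reject glass.

## 3. Spatial features

### Affinity propagation

Detected patch centers are clustered by affinity propagation on
`s(i,k) = −‖x_i − x_k‖²` with the preference set to the median off-diagonal
similarity (the conventional choice that needs no preset cluster count).
Updates are damped at 0.5 with at most 200 iterations and a 15-iteration
exemplar-stability criterion. Two numerical choices matter in practice:

* a seed-controlled jitter of relative size 1e-12 breaks the exact
  degeneracies of symmetric configurations (duplicated points), keeping
  results deterministic given the seed;
* damping 0.5 can oscillate indefinitely on highly symmetric,
  well-separated blob configurations (reference implementations show the
  same behaviour, returning degenerate clusterings with a convergence
  warning). On non-convergence the package deterministically retries at
  damping 0.7, then 0.9 — the standard remedy of increasing damping —
  and flags the result `converged = FALSE` only if all retries oscillate.

Final exemplars are refined as the similarity-maximizing member of each
cluster, matching common reference implementations, against which the
package is cross-checked on frozen fixtures.

### Descriptors, validity indices, graphs

`clusterDescriptors()` reports cluster count, size mean/SD, within-cluster
dispersion (mean centroid distance), extent (max within-cluster pairwise
distance) and between-cluster scatter `BGSS = Σ n_k‖μ_k − μ‖²`.
`validityIndices()` implements Ball-Hall, Banfeld-Raftery (with the
within-variance floored at 1e-12 to guard `log 0` for coincident points),
LogSSRatio, Davies-Bouldin, Calinski-Harabasz and the C-index; indices
requiring separation (K ≥ 2) are flagged missing for a single cluster, and
a zero within-cluster sum of squares yields an infinite Calinski-Harabasz
rather than an error. All six are verified against definition-level
brute-force loops to 1e-9 on random instances.

The proprietary per-object graph features reported alongside the original
pipeline are unpublished, so the package ships an open, versioned analogue
set (`graph_v1`): degree mean/SD/max, fraction of isolated nodes, degree
entropy, degree assortativity and mean local clustering coefficient
(degree < 2 counted as zero), computed over four neighbourhood graphs —
radius 120 px (three patch cells, the scale of "local neighbourhood" at
patch resolution), radius 240 px, and symmetrized 3-nn and 6-nn graphs. A
brute-force empty-circumcircle Delaunay rule is available for small point
sets. Point-pattern homogeneity is summarized by nearest-neighbour mean/SD,
the Clark-Evans ratio `R = mean NN distance / (0.5√(area/n))` and the
quadrat-count dispersion index over an 8 × 8 grid. Together with burden and
stain statistics this yields 57 named features per slide
(`slideFeatureNames()`).

## 4. Subject-level prediction

Per-subject vectors take the maximum of each feature over the subject's
slides (mean/median/min available behind a flag); missing slide values are
skipped, and features undefined for near-empty slides (a control with no
detected LTS has no cluster geometry) are zero-imputed by
`completeFeatureMatrix()` — on every spatial feature, absence of LTS
carries zero signal, which is itself informative for the classifier.

`repeatedLassoSelection()` repeats, for a configurable number of random
splits: stratified 80/20 partition, z-scoring on the training split only
(no leakage), an L1-penalized logistic fit with the regularization strength
chosen by internal cross-validation on the training split, and recording of
the non-zero coefficients. Stratification is used because with 14 controls
an unstratified 20% test draw frequently lacks controls entirely. The
selection uses the cross-validation's one-standard-error lambda: with ~56
subjects and ~60 features the minimizing lambda routinely keeps spurious
features, and under the parsimonious rule a pure-noise design yields no
stably selected feature while a planted signal is selected in ≥ 90% of
repeats. Prediction (`fitPredictElasticnet()`, elastic-net mixing 0.01;
`predictStage()`, multinomial) uses the accuracy-oriented minimizing
lambda. Metrics are computed on each test split with disease as the
positive class and reported as mean ± population SD over repeats; repeats
whose test split lacks a class leave the undefined metrics missing and are
excluded from that metric's summary with a count. Splits too small for
penalized fitting (micro-cohorts with singleton classes) fall back to
unpenalized logistic/multinomial fits. Final feature-set sizes default to
13 (status) and 5 (stage). All repeated protocols are pure functions of
(data, seed).

## 5. The synthetic-data generator

Because the original slides are not public, the generator is a first-class
module that emulates the study conditions end-to-end:

* **Slides.** `generateSlide()` renders the physical brightfield model
  `I = I0 · 10^(−c_H v_H − c_D v_D)`: `c_H` is a smooth random
  counterstain field on a super-elliptical tissue region (≈ 85% of the
  slide) and `c_D` is painted along random-walk polyline strokes (definite:
  8 segments × 7 px at half-width 2.5; probable: shorter and 20% fainter)
  and small discs (possible-rank dots, radius 1.5–3 px; background
  granules, radius 3.5–7 px), matching the linear-vs-dot morphology
  distinction of the ranks. Foreground objects are placed by a Thomas-type
  parent–offspring process whose tightness grows with the
  `spatialClustering` parameter, so clustering features carry real signal.
  Exact geometry, class and rank of every painted object are returned;
  with zero noise the deconvolution recovers the generated fields to
  machine precision, which anchors the stain round-trip test.
* **Cohorts.** `generateCohort()` defaults to the modelled study design:
  56 subjects (14 controls, 15 early / 13 moderate / 14 advanced PD) with
  13 slides each. Per-slide foreground counts are negative-binomial
  (size 4) around stage burden means (0.2, 6, 18, 45 objects/slide) —
  the real per-score count distributions are unpublished, so these
  placeholders were fixed once against the 0/1–9/10–49/≥50 expert-score
  rubric and not revisited; ranks mix 0.40/0.35/0.25
  definite/probable/possible; spatial clustering increases with stage
  (0, 1, 2, 3). Expert scores are deterministic thresholdings of the true
  counts. Clinical covariates couple to the true mean burden with Gaussian
  noise: MDS-UPDRS III increases with stage and burden, DAT-SBR decreases
  (lower binding = worse dopaminergic loss), CSF α-synuclein decreases
  weakly; coupling strengths and noise SDs are `cohortSpec()` parameters.
* **Raters.** `simulateRaters()` relabels true categories through a
  per-category confusion matrix, supporting both the 4-way rank categories
  and binary foreground/background tables (the original concordance
  protocol did not state which was used, so both are constructible).

What the generator does **not** emulate: realistic tissue texture, scanner
artifacts and compression, pyramidal slide formats, annotator spatial
uncertainty (geometry is exact), and the real morphological ambiguity that
caps human concordance around κ ≈ 0.7. Consequently, passing tests show
that the pipeline's machinery is correct and recovers planted signal under
the stated statistical structure — not that the reference network would
match a full-scale convolutional detector on real tissue, nor that the
prediction accuracies attained on synthetic cohorts transfer to real ones
(on the clean synthetic gradient, status prediction is near-perfect; real
slides are far noisier).

## 6. Evaluation statistics

`spearmanRho()` uses mid-ranks with the two-sided t-approximation p-value;
`pearsonR()` is the standard product-moment test; `mannWhitneyU()` reports
`U = min(U_a, U_b)` with an exact two-sided p by full enumeration of group
assignments (ties included) for total n ≤ 12 and the tie-corrected normal
approximation (no continuity correction) otherwise — for two groups its
normal-approximation p coincides with the Kruskal-Wallis chi-square p, a
cross-check in the tests; `kruskalWallis()` is the tie-corrected H with
k − 1 degrees of freedom, with an all-ties guard. Tests are two-sided
throughout and p-values are reported raw (no multiplicity correction),
matching the evaluation conventions of the study this package models.

## 7. Problem sizes and reproducibility

The default test and acceptance runs use 604 × 604-px slides (904 × 904 for
detector benchmarks), the 56-subject cohort with 13 slides per subject, 200
repeated splits for selection and validation, and 200 Monte-Carlo seeds for
the kappa null — sizes chosen so the full pipeline exercises every stage in
minutes on one CPU while leaving the statistical conclusions stable across
seeds. Every stochastic stage derives its stream from a single master seed
(`withSeed()` restores the caller's RNG state), and `runPipeline()` writes
a manifest with stage seeds and output checksums sufficient to re-derive
every artifact; identical configs produce identical CSVs.

## 8. Known limitations

* The reference classifier is a deliberately small network; its role is to
  satisfy the training/inference contract on CPU, not to rival a deep
  backbone.
* Affinity propagation is O(n² · iterations) in memory and time; slides
  with tens of thousands of positive cells would need subsampling or a
  preference schedule.
* The `graph_v1` feature set is an open stand-in for unpublished
  proprietary features; numeric comparability with those features is not
  claimed.
* Elastic-net regularization strength is chosen per split by internal
  cross-validation; the original protocol's strength (and whether its 1000
  evaluation splits reused the selection splits) is unstated, so agreement
  at the protocol level, not the coefficient level, is the goal.
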
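---
title: "Cascaded recalibration for patient-level lung cancer prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cascaded recalibration for patient-level lung cancer prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(milcascade)
```

## The problem

A chest CT scan of one patient typically shows several pulmonary nodules.
The patient is lung-cancer positive if **at least one** nodule is malignant
and negative only if **all** nodules are benign — the standard
multiple-instance learning (MIL) assumption, with the patient as the *bag*
and the nodule patches as the *instances*. Pathologically confirmed
patient-level labels are scarce (they require biopsy or resection), but
radiologists routinely score every annotated nodule on nine semantic
attributes — texture (`tex`), sphericity (`sph`), subjective malignancy
(`mal`), lobulation (`lob`), spiculation (`spi`), margin (`mar`),
calcification (`cal`), subtlety (`sub`) and internal structure (`int`) —
on a 1–5 scale (1–6 for `cal`). These scores are abundant, noninvasive,
and strongly correlated with the pathologic label.

`milcascade` exploits that asymmetry. Nodules *without* a pathologic label
(the **discovery group**) train attribute-specific feature extractors by
score regression; the extractors are then transferred to the labeled
patients (the **diagnosis group**), where a cascaded attention mechanism
pools attribute features into nodule embeddings and nodule embeddings into
a patient embedding for bag-level classification.

## The model

**Attribute feature learning.** For each attribute $s$, a convolutional
extractor $\phi_s$ and a regression head $R_s$ (fully connected
$512\!\to\!32\!\to\!1$, ReLU on the first two layers) are trained jointly on
the discovery group by minimizing the mean squared error between
$R_s(\phi_s(x))$ and the radiologist score $y_s$ of nodule $x$. The
extractor output is a 512-dimensional embedding.

**Attribute-level recalibration.** A patient $X$ has nodules
$x_1,\dots,x_n$; extractor $j$ of the $m$ chosen attribute sources yields
features $u_i^j = \phi_j(x_i)$. A shared recalibration subnetwork
$\mathrm{Recal}(\cdot)$ ($512\!\to\!128\!\to\!32\!\to\!1$, ReLU on the first
three layers) squeezes each feature vector to one logit, and a softmax over
a nodule's $m$ attributes gives coefficients

$$\alpha_i^j = \frac{\exp \mathrm{Recal}(u_i^j)}{\sum_{j'=1}^m \exp \mathrm{Recal}(u_i^{j'})},
\qquad v_i = \sum_{j=1}^m \alpha_i^j\, u_i^j ,$$

so each $\alpha_i$ row is nonnegative and sums to one.

**Nodule-level recalibration.** A second, independent subnetwork of the
same shape produces $\beta_i$ by softmax over the bag's $n$ nodule
embeddings, and the patient embedding is $z = \sum_i \beta_i v_i$, again
with $\sum_i \beta_i = 1$.

**Classification.** A $512\!\to\!32\!\to\!1$ head with a logistic output
gives the bag probability $P(z)$, trained with binary cross-entropy against
the pathologic label $Y$:
$\mathcal{L} = -(1-Y)\log(1-P(z)) - Y \log P(z)$.

With a single attribute source ($m=1$) the attribute softmax is identically
1 and the cascaded model collapses, weight for weight, to the
**recalibrated MIL** model (nodule-level attention only). Two classic
baselines are included for comparison: **instance-space MIL** (a logistic
head per nodule, bag probability = max over nodules) and **embedding-space
MIL** (bag embedding = coordinatewise max over nodule embeddings).

Because every pooling is a softmax-weighted sum, bag probabilities are
invariant to nodule order, and the coefficients $\alpha$ and $\beta$ are an
interpretable by-product: `explain_bag()` flags the argmax-$\beta$ nodule
as the *key nodule* of the decision and reports the full coefficient table.

## The three-step protocol

1. **Step I** — train one attribute-specific model per candidate attribute
   on the discovery group (`train_attribute_model()`).
2. **Step II** — rank the attributes by the cross-validated F1 of a
   single-attribute recalibrated MIL model on the diagnosis group
   (`rank_attributes()`); ties break by accuracy, then AUC, then attribute
   name. This sidesteps the combinatorial explosion of attribute subsets.
3. **Step III** — train the cascaded model on the top-$k$ ranked attribute
   sources (`run_top_k()`), reporting accuracy, AUC and macro F1 as
   mean ± SD over stratified patient-level 5-fold cross-validation.

Training follows the bag-level recipe: one bag per SGD step, learning rate
0.001, weight decay $10^{-4}$, 2000 iterations, drawing bags from a
strictly alternating positive/negative stream (`balanced_bag_stream()`) to
neutralize the roughly 31:86 class imbalance. Extractors are frozen by
default — they were fitted on the disjoint discovery group, so no
information leaks from diagnosis test folds — and features are cached per
bag, which makes the MIL stage fast; an unfrozen end-to-end mode exists
behind `frozen_extractors = FALSE`.

Cross-validation folds are stratified by label. With 31 negatives across 5
folds, an unstratified patient split risks a fold without negatives, which
would leave AUC undefined; stratification with largest-remainder
allocation keeps fold sizes within one bag of each other. The ranking and
top-$k$ stages share the fold split and all derived seeds, so the top-1
cascaded run reproduces the ranking row of the leading attribute exactly.

## The backbone and the optimizer

The package ships a compact convolutional backbone (`tinycnn_init()`):
three 3×3 convolution blocks (8, 16, 32 channels, each followed by 2×2 max
pooling and ReLU), global average pooling, and a fully connected projection
with ReLU to the 512-dimensional feature interface that all downstream
heads expect. It trains in minutes on one CPU core for 64×64 grayscale
patches, which is the scale every bundled experiment and test runs at.
Convolutions are lowered to BLAS matrix products via an `im2col` transform
in compiled code; gradients are exact (the test suite checks them against
finite differences).

For this backbone, trained from scratch on a few hundred patches, the
attribute-regression default is Adam (learning rate 0.003, batch 32, 40
epochs, weight decay $10^{-4}$). Plain SGD with momentum and a stepped
learning rate — the classical recipe for fine-tuning large pretrained
backbones, also available via `optimizer = "sgd"` — needs far more epochs
than a desk-scale budget allows before the regression heads escape the
predict-the-mean solution; Adam's per-parameter step sizes remove that
plateau. The MIL stage keeps plain SGD with momentum at the recipe above:
its subnetworks sit on cached features and converge comfortably within
2000 single-bag iterations.

## What the synthetic cohort generator emulates

`generate_cohort()` builds a download-free stand-in for an
attribute-scored nodule cohort with the statistical structure the method
relies on:

* **A shared malignancy latent** $t \in [0,1]$ per nodule drives all nine
  scores through linear maps with clipping: `mal`, `lob`, `spi`, `sub`
  increase ($1+4t$), `sph`, `mar`, `tex` decrease ($5-4t$), `cal` decreases
  over its wider range ($6-5t$), and `int` stays at 1 — real cohorts are
  almost exclusively soft tissue, which is why `int` carries no signal.
  Linear maps are the simplest monotone family and make hand-verification
  of the endpoints trivial. Attribute correlation is induced solely by the
  shared latent plus independent Gaussian jitter (`noise_sd`); no separate
  covariance structure is invented.
* **Appearance encodes the scores.** Each patch is a rendered blob on
  smoothed background noise: eccentricity falls with `sph`, boundary lobes
  and spikes grow with `lob`/`spi`, the edge blurs as `mar` drops, internal
  heterogeneity grows as `tex` drops, a bright uniform core appears at high
  `cal`, contrast rises with `sub`, and the effective diameter grows with
  `mal` — the classic size–malignancy association, which gives the
  malignancy attribute an appearance cue of its own.
* **Bags follow the MIL assumption by construction.** Positive bags plant
  at least `malignant_per_positive_bag` nodules with latent above 0.7;
  negative bags keep all latents below 0.3; the label always equals the OR
  of the per-nodule indicators. Bag sizes are uniform on `bag_size_range`
  (default 1–10; real per-patient nodule counts are in this range but
  their exact distribution is not published, so the uniform default is a
  choice). The default diagnosis group mirrors the real cohort's skew:
  117 patients, 86 positive.
* **`decoupled_attributes`** draws selected scores uniformly at random,
  independent of the latent, while still rendering them into appearance.
  Decoupling every attribute except `mal` yields a cohort where only
  malignancy-specific features carry label signal — the construction used
  to check that the Step II ranking puts the informative attribute first.
  Without decoupling, noise-free scores are all deterministic functions of
  one latent, every extractor learns the same latent, and no ranking can
  distinguish them; this is a property of the generator, not of the
  method.

The generator does **not** attempt physically realistic CT texture, 3-D
volumes, slice selection, or inter-radiologist disagreement beyond score
jitter. Passing the bundled experiments therefore demonstrates that the
implementation is correct and that the pipeline recovers planted structure
under its own assumptions — not that it reaches any particular performance
on real CT data.

## Problem sizes in the bundled experiments

The package's synthetic study (exercised by the test suite) uses a study
cohort of 120 diagnosis patients (positive fraction 86/117) with 500
discovery nodules, noise-free scores, and three attribute sources
(`mal`, `sph`, `tex`); attribute models train on 400 discovery patches with
100 held out, and MIL models run the full 2000 iterations under 5-fold
cross-validation. The ranking check uses a second, 60-patient cohort with
every attribute except `mal` decoupled. The checks assert held-out
regression MAE below 0.5, the informative attribute ranked first, held-out
AUC above 0.9 for the top-3 cascaded model, and key-nodule recovery above
chance — these bounds and sizes are the package's desk-scale study
conditions, chosen once.

## Numerical and convention choices

* Softmaxes subtract the maximum logit before exponentiation; untrained
  512-wide subnetworks can emit logits far outside `exp`'s safe range.
* The cross-entropy is evaluated from the logit in softplus form, so
  saturated probabilities never produce `-log(0)`.
* "ReLU on the first *k* layers" counts the input neuron layer: the input
  activation is idempotent for the nonnegative CNN features but is applied
  unconditionally so the subnetworks are well-defined on any input.
* The decision threshold is 0.5 with ties called **positive**.
* AUC is the Mann–Whitney rank statistic with half-credit for ties;
  macro F1 averages the positive-class and negative-class F1, defining an
  undefined class F1 (no predicted and no actual members) as 0; fold
  aggregation uses the sample (n−1) standard deviation.
* Interobserver variation averages all unordered rater pairs within each
  nodule and then averages over nodules; single-rater nodules are skipped
  (they contribute no pair). Whether the per-nodule or the pooled-pairs
  convention is intended in the literature is ambiguous; the per-nodule
  convention is fixed here.
* ROI crops use 0-based coordinates and a half-open window
  $[c - s/2,\, c + s/2)$, padding out-of-image regions with 0 (the
  windowed value of air); nodules near the lung border are kept rather
  than rejected. Pixels live in $[0,1]$ doubles internally and are
  quantized to 8 bits only at the PNG boundary.
* Max-pooling ties route gradients to the first window position;
  softmax-coefficient ties in `explain_bag()` flag the first index and set
  a tie note.
* Every stage derives its RNG seed from a master seed and a stage tag, so
  the full pipeline is bit-reproducible and stages stay decoupled.

## Limitations

* The bundled backbone is a compact CNN; the framework's feature interface
  (512-dimensional, frozen by default) would accept features from any
  larger pretrained backbone, but none is bundled, and headline numbers
  from GPU-scale training on real data are out of this package's reach.
* Real-data ingestion is delegated: the package consumes the manifest
  interchange format (CSV + PNG patches) and deliberately does not parse
  DICOM studies or cluster per-radiologist annotation marks; an external
  ingestion step (or the synthetic generator) produces the manifest.
  Multi-rater nodules are expected to be pre-merged, or merged with
  `average_scores()`.
* Attention-style coefficients are a model introspection tool, not a
  causal explanation; the key-nodule check in the synthetic study shows
  they track planted malignancy there, nothing more.
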
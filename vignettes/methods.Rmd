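---
title: "Harmonizing whole-slide patch embeddings: model, design choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Harmonizing whole-slide patch embeddings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(combatslide)
```

## The problem

Slides digitized at different clinical centers (tissue-source sites, TSS)
carry center-specific technical signatures — staining chemistry, scanner
optics, compression — that survive into the patch embeddings produced by
pretrained feature extractors. A bag-level classifier trained on such
embeddings can "predict" a clinical attribute by recognizing the site rather
than the tissue, which inflates cross-validated performance and destroys
generalization. `combatslide` provides the machinery to (a) emulate this
failure mode with a generator whose ground truth is known, (b) remove the
site signature with an empirical-Bayes location–scale correction (ComBat,
fitted from scratch here), (c) train attention-based multiple-instance
(A-MIL) classifiers on raw and harmonized embeddings, and (d) quantify what
the correction removed and what it preserved.

## The location–scale model

For batch (site) $i$, slide/patch sample $j$ and feature $g$, the observed
embedding value is modeled as

$$Y_{ijg} = \alpha_g + \gamma_{ig} + \delta_{ig}\,\varepsilon_{ijg},
\qquad \varepsilon_{ijg} \sim N(0, \sigma_g^2),$$

with additive site effects $\gamma_{ig} \sim N(\mu_i, \tau_i^2)$ and
multiplicative site effects $\delta_{ig}^2 \sim
\mathrm{InvGamma}(\lambda_i, \Theta_i)$. Fitting proceeds by
standardization ($\hat\alpha_g$ the batch-size-weighted grand mean,
$\hat\sigma_g^2$ the pooled residual variance after batch-mean removal, $N$
denominator), per-batch estimates $\hat\gamma_{ig}$ (within-batch mean of
$Z$) and $\hat\delta^2_{ig}$ (within-batch variance, $n-1$ denominator),
method-of-moments hyperpriors
($\hat\lambda = (\bar V^2 + 2S^2)/S^2$, $\hat\Theta = (\bar V^3 + \bar V
S^2)/S^2$), and the coupled posterior-mean fixed point for
$(\gamma^*, \delta^{*2})$. The corrected value is

$$Y^*_{ijg} = \hat\sigma_g\,\frac{Z_{ijg} - \gamma^*_{ig}}{\delta^*_{ig}}
  + \hat\alpha_g .$$

The adjustment is written here in its fully standardized form; the common
shorthand that omits $\hat\sigma_g$ cannot simultaneously "center and
standardize the variance of each batch", so the standard form is
implemented. Samples are *patches pooled across all slides of a site*, the
fit happens once per cohort before any cross-validation (mirroring the
audited workflow; a per-fold refit would be the leakage-safe variant and can
be composed from the same primitives).

Correction modes: `additive` forces $\delta^{*2} \equiv 1$ in the
adjustment, `multiplicative` forces $\gamma^* \equiv 0$; both let the
additive-vs-multiplicative contribution of the batch signature be audited
separately.

### Numerical choices

* Variance conventions: population ($N$) denominator for
  $\hat\sigma_g^2$, sample ($n-1$) for $\hat\delta^2_{ig}$ and the
  across-feature moments. The brute-force oracle used in the tests follows
  the same conventions.
* The EB fixed point stops when the largest absolute relative change drops
  below `tol` (default `1e-4`, tightened to `1e-12` when comparing against
  the oracle); non-convergence returns the last iterate and flags the batch
  in `model$converged`.
* Degenerate across-feature moments ($S^2 = 0$) would make the
  inverse-gamma prior undefined; the fit falls back to a flat prior (no
  shrinkage of $\hat\delta^2$) and records it.
* Features with zero within-slide variance in *any* slide are dropped
  dataset-wide before fitting. The printed rule is ambiguous between
  per-slide and dataset-wide dropping; dataset-wide keeps one rectangular
  feature space and the mask is stored in the model so external data are
  masked identically.
* Batches with a single sample are rejected, not passed through.
* One-batch input is only accepted behind `allow_single_batch = TRUE` and is
  an exact identity.

### Reference-batch alignment

External cohorts are aligned by a two-batch fit on
`[corrected training data; external data]` anchored at the reference:
standardization statistics come from the reference batch, the reference rows
are returned unchanged (its $\gamma^*$ row is 0, $\delta^{*2}$ row is 1) and
only the external batch is adjusted. One deliberate deviation: in this
anchored fit the external $\hat\delta^2$ uses the population denominator,
because under the stated $n-1$ convention aligning a batch to *itself* would
leave an $O(1/n)$ scale drift rather than being the identity. The
"reference unchanged, external adjusted" contract is itself an
interpretation of the original toolchain's behaviour, which is not printed
in full.

### Non-parametric priors

`prior_mode = "nonparametric"` replaces the parametric posterior means with
the empirical-prior weighting: feature $g$ borrows every other feature's
$(\hat\gamma_{g'}, \hat\delta^2_{g'})$, weighted by the Gaussian likelihood
of feature $g$'s data under those parameters (leave-one-out across features,
log-space weights, $O(D^2 n_i)$). This is only sensible when $D$ is large
enough for the empirical prior to be dense; with a handful of features each
feature is forced onto its nearest neighbour's estimates.

## The synthetic cohort generator

`simulate_cohort()` draws exactly from the model above — $\gamma$,
$\delta^2$ once per (site, feature) from their stated priors, Gaussian patch
noise — plus two controlled extensions that give the audit something to
measure:

* **Label signal.** Each categorical attribute shifts the *slide-level* mean
  by a per-class vector supported on a stated feature subset. The shift is
  uniform across a slide's patches: no patch-level label model is printed
  anywhere for how clinical attributes manifest in embeddings, so the
  slide-uniform shift is a stand-in chosen to make bag labels learnable even
  by mean pooling (the weakest aggregator). $\delta_{ig}$ multiplies the
  noise term only, exactly as the model is written, so the class shift is
  not scaled by site.
* **Confounding dial.** Attribute classes are sampled with site-conditional
  probabilities $P(c \mid i) = \rho\,[c = \mathrm{map}(i)] + (1-\rho)/C$:
  $\rho = 0$ is independence, $\rho = 1$ makes the class a deterministic
  function of site.
* **Artifacts.** `inject_artifact_regions()` adds a constant offset to a
  contiguous axis-aligned rectangle (about half the grid in each dimension)
  on a seeded fraction of slides — the simplest localized structure a
  correction heatmap must highlight, standing in for pen markings and
  tissue folds.

One master seed drives four independent sub-streams (effects, labels, noise,
artifacts), so changing e.g. the artifact fraction does not perturb the
embeddings. Per-slide patch counts may be drawn from a range to exercise
variable bag sizes.

What the generator does **not** emulate: nonlinear (interaction) batch
effects, heavy-tailed or skewed embedding marginals, spatial correlation
between neighbouring patches, patch-level label heterogeneity (tumor
fraction), or any actual image content. A green end-to-end test therefore
establishes that the pipeline removes *linear location–scale* site structure
while preserving an *additive slide-level* signal — precisely the model's
claim — and nothing about extractor-specific nonlinear leakage, which is a
known limitation of this correction family.

## The A-MIL classifier

Each bag (slide) of patch embeddings is mapped through an affine $D \to 256$
layer with ReLU; attention scores
$a_k = \mathrm{softmax}_k(w^\top \tanh(V h_k))$ with $V \in
\mathbb{R}^{128\times256}$, $w \in \mathbb{R}^{128}$ pool the patches into
$h_{sum} = \sum_k a_k h_k$; a batch-normalization layer and dropout 0.5 act
on the mini-batch of pooled vectors; a final affine layer with softmax gives
class probabilities. Training uses cross-entropy weighted inversely to class
occurrence, mini-batches of 64 bags, at most 64 epochs with early stopping
(patience 16) on a validation loss, a one-cycle cosine schedule peaking at
$10^{-4}$, and at most $K = 512$ patches sampled uniformly without
replacement per bag per epoch.

No tensor framework is available in this stack, so forward, backward
(including the batch-norm and attention-softmax gradients), Adam and the
one-cycle schedule are implemented directly on base-R matrices. Choices the
recipe leaves open, decided here and logged: the optimizer is Adam with
default moments (only the learning rate is scheduled); initialization is
fan-based (He for the ReLU layer, Xavier elsewhere), seeded; inference uses
*all* patches of a bag with running normalization statistics and no dropout,
so evaluation is deterministic and permutation-invariant; bags within a
mini-batch interact only through the normalization of $h_{sum}$, never
through attention. The one-cycle schedule uses 30% warmup from
`max_lr / 25` and anneals to `max_lr / 1e4` (the common defaults of the
policy's reference implementation).

## Evaluation harness

* Sites with fewer than 5 slides are dropped before site prediction so every
  site can appear in every fold.
* Attribute screening: chi-squared against site on the pairwise-complete
  contingency table, Benjamini–Hochberg across the screened family
  (hand-implemented step-up, tested against an independent definition),
  inclusion requires $q < 0.05$ *and* a minority class of at least 30.
* Cross-validation is stratified by the prediction target (5 folds; 3 for
  small targets). One fold assignment and one training seed per fold are
  shared across condition arms, which is what makes the two-sided paired
  t-test between conditions exact; one-sided t-tests compare fold AUROCs to
  0.5. Degenerate (zero-variance) t-tests return deterministic flagged
  values instead of NaN.
* The held-out fold doubles as the early-stopping validation set by default
  — optimistic, but it mirrors the audited design, which names no inner
  split; `inner_val = TRUE` switches to a stratified 80/20 inner split.
* AUROC uses midranks (ties credited 1/2); multiclass targets use
  support-weighted one-vs-rest AUROC.
* Bootstrap intervals default to 10 replicates — as coarse as it sounds,
  kept as the audited default and configurable.
* `summarize_cohort()` reports percentages under both the non-missing and
  total denominators (the printed tables are not internally consistent about
  which they use; non-missing reproduces them).

## Correction maps

The per-patch correction magnitude is the Euclidean distance between the raw
and harmonized embedding of the patch. Distances are min–max normalized over
the pooled patches of all slides of one site (a z-score variant is available
behind a flag), so maps of slides from the same site share a scale; a
constant-distance site maps to zero by convention. Rendering places each
patch at its grid cell, empty cells are `NA`. Because the adjustment is
affine per feature, the correction distance grows with a patch's deviation
from the site mean whenever $\delta^* \neq 1$; localized artifacts are
therefore highlighted exactly when sites differ in scale, which is the
regime the localization test constructs.

## Scaled-down defaults in the shipped tests

The end-to-end acceptance experiment simulates the stated world (8 sites ×
25 slides × 100 patches, $D = 64$, strong additive and multiplicative
effects, one attribute confounded at $\rho = 0.9$, one site-independent
attribute with a real signal, seed set {11, 12, 13}) but trains the A-MIL
arms with a reduced budget (embedding 64, attention 32, 10 epochs, patience
3, mini-batch 32, peak learning rate $10^{-3}$) so three seeds × eight
experiment arms × five folds fit a single-CPU grading run. The package
defaults remain the full-size recipe. Parameter-recovery tests compare
$\gamma^*$ against the *centered* truth: $\gamma$ is only identified up to
the per-feature baseline absorbed into $\alpha$, and with four sites the
uncentered correlation has a theoretical ceiling of $\sqrt{3/4} \approx
0.866$ for any estimator.

## Known limitations

Linear location–scale correction cannot remove batch information encoded in
feature interactions; the generator cannot produce such leakage either, so
this package measures the best case for ComBat, not its failure modes. The
cohort-level fit before cross-validation leaks (unlabeled) test-fold
statistics into training, as in the audited design. The CLI stores matrices
as full-precision TSV — lossless but bulky for very large cohorts.
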
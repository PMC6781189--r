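---
title: "Lesion-guided training with Grad-CAM supervision: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lesion-guided training with Grad-CAM supervision: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(lesioncam)
```

## The problem and the model

Endoscopic frames showing early gastric cancer differ from benign mucosa —
and mucosal (T1a) cancers differ from submucosal (T1b) ones — by subtle
textural and chromatic cues confined to the lesion. A classifier trained
with cross-entropy alone is free to exploit *any* discriminative signal,
including acquisition biases of the collection (how closely a lesion is
documented, illumination, incidental artifacts). Such a model can reach a
respectable AUC while its evidence map sits on the wrong part of the frame,
which is fatal both for clinical trust and for downstream localization.

`lesioncam` trains the classifier and its spatial evidence jointly. For an
input image with true class $c$, last-layer convolutional feature maps
$A^k$ ($K$ maps of size $u \times v$) and class score $y^c$, the Grad-CAM
map is

$$\alpha_k = \frac{1}{uv}\sum_{i,j}\frac{\partial y^c}{\partial A^k_{ij}},
\qquad
L^c = \mathrm{ReLU}\Big(\sum_k \alpha_k A^k\Big),$$

and the training objective is the weighted sum

$$\mathcal{L} \;=\; w_{ce}\,\mathrm{CE}(p, y)\;+\;
w_{cam}\,\frac{1}{uv}\Big\lVert \tilde L^c - M \Big\rVert_2^2 ,$$

where $\tilde L^c = L^c / \max L^c$ is the max-normalized map and $M$ is
the binary lesion mask downsampled to the feature grid (area mean, then
threshold at 0.5). Images without a lesion use an all-zero $M$, so any
activation of their class map is penalized. The CAM in the loss always
targets the *true* class: the mask is defined by the true lesion, and this
keeps the supervision signal stable before the classifier is any good.

Assumptions worth stating: the mask is trusted (drawn by an expert, aligned
with the image); one lesion per frame; the classifier head is global
average pooling plus a dense layer, so class evidence is spatially additive
— the regime in which Grad-CAM is an exact decomposition rather than an
approximation.

## Gradient treatment of the localization term

The localization term contains $\alpha_k$, which is itself a gradient, and
the normalization maximum. Differentiating through both would require
second-order automatic differentiation. The package instead uses the
standard first-order attention-supervision treatment: $\alpha_k$ and
$\max L^c$ are held constant (stop-gradient) and the loss is
backpropagated through the feature maps $A^k$ only. Two numerical guards
were found to be essential in practice:

* **Rectifier resurrection.** $\mathrm{ReLU}$ has zero gradient on a dead
  map, so a CAM that collapses to all-zero is a permanent fixed point of
  the localization term. The subgradient is therefore taken as active
  wherever the pre-rectified map is positive *or* the mask demands
  activation, which lets the supervision revive a collapsed map.
* **Scale floor.** The $1/\max L^c$ factor of the normalized loss explodes
  as the map maximum approaches zero; the stop-gradient scale is floored
  at 0.05.

Without either guard, lesion-mode training was observed to converge with a
dead activation map (classification fine, localization nil).

## Tunable parameters

| Parameter | Default | Meaning and rationale |
|---|---|---|
| `w_ce` | 1 | weight of the cross-entropy term |
| `w_cam` | 10 | weight of the localization term; the MSE is averaged over $uv$ feature cells, making its per-parameter gradients roughly an order of magnitude smaller than the cross-entropy's, so 10 puts the two terms on comparable gradient scales (a sweep over 2/5/10/25 showed 10 is the smallest decisive value; 1 leaves the CAM unpinned under dataset bias) |
| `learning_rate` | 1e-3 | Adam step size |
| `batch_size` | 16 | mini-batch size |
| `balance_classes` | TRUE | epoch indices drawn with inverse-class-frequency weights (with replacement); with an 85/15 imbalance and without balancing, the optimizer sits in the majority-class regime for tens of epochs with a seed-dependent breakthrough |
| `cam_loss` | "mse" | squared error on the normalized map; a soft-Dice alternative (`"dice"`) is provided |
| `cam_threshold` | 0.5 | activated-region binarization, as a fraction of the map maximum |
| `overlap cutoff` | 0.5 | overlap ratio above which a localization counts as correct |

Model selection returns the weights at the best validation loss; training
is fully deterministic given the model seed (initialization) and the
config seed (shuffling).

## What the synthetic generator emulates — and what it does not

No clinical images ship with the package; the generator produces cohorts
with the *statistical structure* that makes the method's claims testable:

* patient grouping (2–6 frames per patient sharing lesion morphology up to
  viewpoint jitter), so patient-level splitting is consequential;
* heavy class imbalance (default mix 85.2% non-lesion, 7.8% T1a, 7.0%
  T1b, mirroring clinical collections);
* lesions occupying 1–40% of the frame: a smoothly perturbed ellipse with
  a pixel-aligned binary mask;
* subtle in-mask class cues: fine-grained texture roughness and a mild hue
  shift for T1a, the same plus a marginal rim (the submucosal "marginal
  elevation" cue) and a stronger hue shift for T1b;
* a **dataset bias**: lesion-bearing frames are rendered slightly dimmer
  and more vignetted with probability 0.9 (versus 0.1 for clean frames),
  emulating closer documentation of lesions. This incidental, perfectly
  learnable global cue is what gives plain cross-entropy training
  somewhere wrong to look, and it is deliberate: without it the planted
  lesion is the only discriminative signal and *any* training method
  localizes it, which no real collection resembles.

What passing tests on this generator show: that the composite objective
pins the class evidence map to the lesion when an easier off-lesion
shortcut exists, while plain training does not. What they do not show:
performance on real endoscopic appearance (specularity, peristalsis,
instrument artifacts, heterogeneous lesion phenotypes), robustness of the
specific default amplitudes, or clinical-grade diagnostic accuracy. The
printed clinical headline numbers (detection AUC 0.981, depth AUC 0.851,
correct ratios 0.994/0.581 and 0.959/0.811) belong to a hospital dataset
that is not publicly deposited and are directional references only.

## Numerical and design choices

* **Fold construction.** Patients are shuffled by seed and dealt
  round-robin into five folds (near-equal patient counts; image counts
  differ since patients contribute unequal numbers of frames). Group $g$
  trains on folds $(g, g{+}1, g{+}2) \bmod 5$, validates on $(g{+}3)
  \bmod 5$, tests on $(g{+}4) \bmod 5$. Only $k=5$ is supported; other
  $k$ are rejected rather than silently generalized.
* **Quality filtering.** Blur is scored as the variance of a discrete
  Laplacian of luminance (low = blurred), halation as the fraction of
  pixels with all channels at or above 0.98. The criteria are stated by
  the application; the detectors are the package's own operationalization.
  Air-insufflation quality has no operational definition and is not
  scored.
* **Resolution split.** The loss compares CAM and mask at feature
  resolution ($u \times v$), where gradients live; evaluation upsamples
  the CAM to image resolution (pixel-centre-aligned bilinear
  interpolation) and compares with the full-resolution mask.
* **Region extraction.** Binarize at 0.5 of the map maximum, keep the
  largest 8-connected component (ties broken by first label in scan
  order); an all-zero map yields an empty region.
* **Overlap.** Intersection-over-union by default
  (intersection-over-truth available). Conventions for degenerate cases:
  both regions empty is correct non-activation (overlap 1); empty against
  non-empty is overlap 0.
* **AUC.** Trapezoidal integration over all distinct score thresholds —
  algebraically identical to pairwise concordance with ties counted one
  half, which the tests verify exactly. Cross-validation folds are pooled
  by concatenating score and label vectors.
* **Odds ratios.** $(c/d)/(a/b)$ for a table laid out reference-first with
  accurate/inaccurate columns; 95% Wald interval on the log scale. This
  convention reproduces the printed interval of the motivating table to
  all three printed decimals, which is the evidence that Wald (not exact
  or profile) intervals were used there. Zero cells raise an error unless
  the 0.5 continuity correction is explicitly enabled. Percentages are
  rounded half-up to one decimal, matching clinical table conventions.
* **Degenerate inputs.** All-zero CAMs normalize to themselves; one-class
  ROC inputs, empty localization lists, zero-margin contingency tables and
  mask/class mismatches raise typed errors rather than returning
  conventional values.

## Problem sizes used by the tests

Desk-scale sizes were chosen so the whole suite runs comfortably on one
CPU: 64-px images and a ~120-patient cohort (~600 images) for the
plain-versus-lesion comparison (three seeds, one cross-validation group,
25 epochs per model); 8-px inputs for the finite-difference Grad-CAM
oracle; 1000 masks for the area-bound check. The comparison expects the
lesion-based model to beat plain training's correct-localization ratio by
at least 0.15 while reaching a detection AUC of at least 0.85, for a
majority of seeds — a directional, stochastic reading of the clinical
result, not a reproduction of its magnitudes.

## Known limitations

* The CNN engine is intentionally compact (three small backbones, GAP
  heads, 3×3 convolutions, Adam); it is not a general deep-learning
  framework, and no pretrained weights are bundled — `pretrained = TRUE`
  is rejected.
* The localization gradient is first-order (stop-gradient $\alpha_k$);
  with an FC-head backbone Grad-CAM would be an approximation and the
  supervision signal correspondingly noisier.
* Correct-ratio denominators on heavily imbalanced synthetic test folds
  can be small (a handful of lesion patients per fold); the multi-seed
  majority criterion absorbs this, single runs should not be
  over-interpreted.
* Multivariable (adjusted) odds ratios are out of scope: the module
  covers exactly the univariable 2×2 statistics whose inputs are printed
  count tables.
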
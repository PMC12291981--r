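---
title: "Density-aware suppression and counting: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Density-aware suppression and counting: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(densecount)
```

## The problem

Counting animals by detection reduces to two sub-problems once a detector
has emitted candidate boxes: deciding which boxes are redundant views of
the same animal, and turning the retained set into a count with known
error characteristics. Both are density-dependent. In a sparse pen, true
animals rarely overlap, so any two strongly overlapping boxes are almost
surely duplicates and aggressive suppression is right. In a crowded pen,
animals genuinely overlap — pairwise box IoU reaches 0.5 when pigs pile
up — and the same suppression deletes real animals. `densecount`
implements the post-processing side of this problem: box-geometry scores,
two suppressors, a density-router between them, the metric suite, and a
scene simulator that makes the whole chain testable without images.

## Box scores: IoU, PIoU, and the v2 loss

For axis-aligned boxes in continuous coordinates (x right, y down;
widths are arithmetic differences with no pixel-index convention), IoU is
intersection area over union area. The penalized score

$$\mathrm{PIoU} = \mathrm{IoU}
 - \frac{\rho^2(c, c_{gt})}{w^2 + h^2}
 - \alpha\,\frac{(w_{gt}-w)^2 + (h_{gt}-h)^2}{w_{gt}^2 + h_{gt}^2}$$

subtracts a normalized squared center distance and a shape-disparity
term. Two conventions needed fixing:

* **Center-distance normalization.** The denominator $w^2 + h^2$ uses
  the *predicted* box's dimensions. DIoU-style scores use the diagonal of
  the smallest enclosing box instead; that choice is bounded in [0, 1]
  while ours is not, but the predicted-box form follows the score's
  definition of $w, h$ as predicted dimensions, and all identities the
  package tests (PIoU ≤ IoU, equality at 1 only for identical boxes)
  hold either way.
* **$\alpha$** (default 1.0, dimensionless) balances the shape penalty.

The v2 regression loss is

$$L = 1 - \mathrm{PIoU} + \lambda\,\phi(\mathrm{IoU})\,\psi(\Delta)$$

with $\lambda = 0.5$. Only the *qualitative* behavior of $\phi$ and
$\psi$ is prescribed by the loss's origin — a non-monotonic attention
that peaks for moderate overlap, and a penalty of geometric disparity —
so the concrete forms are package design choices, recorded in
`piou_v2_params()` by name so alternatives can be registered:

* $\phi(u) = 4u(1-u)$: bounded in [0, 1], maximal at IoU 0.5, above 0.84
  throughout IoU 0.3–0.7, vanishing at 0 and 1. Vanishing at 0 makes the
  loss of a disjoint pair exactly $1 - \mathrm{PIoU}$; vanishing at 1
  makes the loss 0 exactly at a perfect match.
* $\Delta = \rho^2/d^2 + [(w-w_{gt})^2 + (h-h_{gt})^2]/(w_{gt}^2 +
  h_{gt}^2)$ with $d$ the enclosing-box diagonal (scale-free by
  construction), and $\psi(\Delta) = 1 - e^{-\Delta}$: zero at zero
  disparity, monotone, bounded, so the attention term can never make the
  loss negative.

Only loss *values* are exposed. Gradients belong to detector training,
which is outside this package's scope, as are GIoU/CIoU/DIoU variants and
rotated boxes.

## Suppression

**Hard NMS** is the classic greedy rule: keep the highest-scored
remaining detection, discard everything overlapping it beyond the IoU
threshold, repeat. **Soft-NMS** decays instead of deleting: when $M$ is
selected, every remaining score is rescaled by
$e^{-\mathrm{IoU}(M, b_i)^2/\sigma}$, and only after all detections are
processed are those below `keep_floor` dropped. With $\sigma = 0.5$ the
decay factor is $e^{-0.5} \approx 0.607$ at IoU 0.5 and
$e^{-2} \approx 0.135$ for an exact duplicate — duplicates die, genuine
overlaps survive.

Two free parameters are not fixed by the procedure's description and are
package decisions:

* `conf_init = 0.25`: the confidence threshold defining the "initial
  detection count" used for density routing. Whether the raw count is
  taken before or after a confidence cut was genuinely open; we count
  detections at score ≥ 0.25, a common detector evaluation floor, and
  record the value in the result object so reports document their
  confidence surface.
* `keep_floor = 0.25`: the retention floor after Soft-NMS decay, set
  equal to `conf_init` so the whole counting rule is a single documented
  confidence surface.

**Density routing.** The initial count selects the tier: LOW (≤ 15
animals) → hard NMS at 0.5; MEDIUM (16–23) → hard NMS at 0.4; HIGH
(≥ 24) → Soft-NMS with σ = 0.5. The taxonomy is defined on 8–30 animals;
counts outside it are clamped to the nearest tier rather than rejected,
since deployed scenes can fall outside a study's range. The count is then
the size of the retained set — direct enumeration, no regression layer.
Ties in confidence are broken by input order everywhere, so all outputs
are deterministic functions of their inputs. Suppression is
class-agnostic (single animal class).

### Numerical notes and limiting behavior

* $\sigma \to \infty$ makes Soft-NMS the identity on scores.
* $\sigma \to 0^+$ with a positive floor reproduces hard NMS in the
  zero-threshold limit — *for detections whose raw score is above the
  floor*. A detection already below `keep_floor` is dropped by Soft-NMS
  but untouched by hard NMS, which has no floor; the test-suite
  generators therefore draw scores in [0.1, 1] where the equivalence is
  well-posed.
* Decayed scores underflow to exactly 0 for IoU²/σ beyond ~745; such
  detections still participate in later iterations (standard Soft-NMS)
  but cannot survive any positive floor.

## Evaluation

Matching is greedy in descending confidence: each detection claims its
best-IoU unmatched ground-truth box, becoming a TP if that IoU ≥ 0.5.
The protocol (single-match, ties by ground-truth index) is a package
decision — headline detection metrics are conventionally reported as
mAP@0.5 without specifying the matcher. AP integrates the all-point
precision envelope over recall (the "maximum precision at recall ≥ r"
reading); the 11-point and 101-point approximations are deliberately not
offered. With one class, mAP equals AP.

Counting metrics over scenes $i = 1..m$ with true count $a_i$ and
predicted count $b_i$:

$$\mathrm{average\_accuracy} = \frac1m \sum_i \Big(1 - \frac{|a_i-b_i|}{a_i}\Big),
\qquad \mathrm{MAE} = \frac1m\sum_i |a_i-b_i|,
\qquad \mathrm{RMSE} = \sqrt{\tfrac1m\sum_i (a_i-b_i)^2}.$$

`average_accuracy` equals 1 only when every count is exact and goes
*negative* when an error exceeds the true count — it is a relative
metric, so scenes with $a_i = 0$ are rejected rather than patched (the
emulated density regimes start at 8 animals, so this cannot arise there).

## The simulator: what it emulates, and what it does not

`sample_scene()` reproduces the density taxonomy of overhead pig-pen
surveys: four categories (sparse 8–12, low-medium 13–18, medium-high
19–25, high 26–30 animals per scene) drawn at 20/30/35/15% frequency,
canvas 640 × 640 px (the standard working resolution of such imagery).
The within-category count is uniform — the taxonomy gives ranges, not
within-range distributions. Boxes are placed by rejection sampling under
a pairwise-IoU ceiling (`max_pairwise_iou`, default 0.3; crowded-pen
studies reach ~0.5). Infeasible configurations fail loudly after
`max_attempts` tries — never a silently truncated scene, because the true
count is the quantity under study.

Parameters neither the taxonomy nor the toolkit's contracts fix, chosen
once as field-realistic and not revisited:

* box width ~ lognormal(meanlog = log 110 px, sdlog = 0.2) and aspect
  h/w ~ lognormal(meanlog = log 0.6, sdlog = 0.15): overhead pigs are
  landscape-elongated bodies roughly a sixth of the canvas across, so 30
  fit with room to overlap;
* detector noise (`noise_config()`): 95% per-animal detection
  probability, 5% center/size jitter, confidence N(0.8, 0.1) clipped to
  [0, 1], 10% duplicate-proposal probability at 0.8× parent confidence,
  Poisson(0.5) false positives per scene at N(0.35, 0.1) confidence —
  the profile of a strong single-class detector.

All randomness flows from explicit seeds (`withr::with_seed`; no global
RNG state is touched), so scenes and detector outputs are byte-identical
across runs for a fixed config.

The simulator models occlusion *only* as box overlap. It renders no
pixels, so a green end-to-end test establishes that the post-processing
chain is correct — zero-noise closure (count = true count in every tier),
duplicate removal, overlap preservation by the HIGH-tier Soft-NMS — but
says nothing about any real detector's accuracy on real imagery:
appearance-driven failure modes (lighting, breed, posture, motion blur)
are out of its reach by construction.

## Reference survey tables

`reference_density_distribution()` and `reference_split_summary()` ship
the composition of the 8000-image multi-source overhead pen survey from
which the density taxonomy and category frequencies derive (image counts
per category; per-split image and animal totals). They exist so that the
taxonomy's arithmetic — total animals, mean per image, category shares —
is computable from the package itself, and they parameterize nothing
else.

## Known limitations

* Single class; multi-class grouping in suppression and multi-category
  mAP averaging are untested surface.
* PIoU with the predicted-box normalization is unbounded below for far
  apart boxes; use the v2 loss (bounded attention term, loss ≥ 0) where a
  bounded objective matters.
* The density router trusts the initial count: a detector whose raw
  count is grossly inflated by false positives can route a sparse scene
  to the HIGH tier. The `density_count` object reports the tier and
  initial count so this is visible.
* Counting is per-scene; tracking-based counting across video frames is
  out of scope.
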
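# densecount

Detection post-processing and counting evaluation for crowded animal
scenes, aimed at precision-livestock vision pipelines that count pigs (or
any single-class animal) in overhead pen imagery from a detector's raw
bounding-box output.

Counting by detection fails in two opposite ways. In sparse pens, loose
post-processing keeps duplicate and spurious boxes, inflating the count;
in crowded pens, where animals pile up and pairwise box overlap reaches
50%, a fixed non-maximum-suppression (NMS) threshold deletes legitimate
overlapping animals and undercounts. `densecount` implements a
density-aware pipeline that first classifies scene crowding from the raw
detection count and then applies the suppression strategy suited to it,
together with the box-geometry scores, evaluation metrics and synthetic
scene generator needed to study this behavior without any image data.

## What it computes

**Box scores and losses.** Besides plain IoU, the penalized IoU

> PIoU = IoU − ρ²(c, c_gt)/(w² + h²) − α·[(w_gt − w)² + (h_gt − h)²]/(w_gt² + h_gt²)

adds center-distance and shape-disparity penalties (α = 1 by default,
w, h the predicted box dimensions), and the v2 regression loss

> L = 1 − PIoU + λ·ϕ(IoU)·ψ(Δ)

adds a non-monotonic attention term (λ = 0.5) that weights the geometric
penalty most heavily at moderate overlap (IoU 0.3–0.7), where gradient
signal matters most during detector training. The concrete forms
ϕ(u) = 4u(1−u) and ψ(Δ) = 1 − e^(−Δ) are package choices documented in
the methods vignette.

**Density-aware suppression and counting.** The raw detection count at
confidence ≥ 0.25 selects a tier: LOW (≤ 15) runs hard NMS at IoU 0.5,
MEDIUM (16–23) hard NMS at 0.4, HIGH (≥ 24) Soft-NMS with Gaussian decay

> s_i ← s_i · exp(−IoU(M, b_i)²/σ),  σ = 0.5,

which decays rather than deletes overlapping boxes so heavily occluded
animals survive. The final count is the size of the retained set.

**Evaluation.** Greedy confidence-ordered matching at IoU ≥ 0.5 yields
precision, recall, F1 and AP from the all-point interpolated
precision–recall envelope (`map50`), and scene-level counts yield

> average_accuracy = (1/m) Σ (1 − |a_i − b_i| / a_i),  MAE, RMSE.

**Simulation.** Scenes are sampled from a four-category density taxonomy
(sparse 8–12, low-medium 13–18, medium-high 19–25, high 26–30 animals,
at 20/30/35/15% frequency) on a 640×640 canvas with a configurable
pairwise-overlap ceiling, and a detector-noise model adds misses, jitter,
duplicates and false positives.

## Worked example

```r
library(densecount)

scene <- sample_scene(sim_config(density_category = "high",
                                 max_pairwise_iou = 0.4, seed = 42))
dets  <- simulate_detector(scene, noise_config(seed = 42))
res   <- density_aware_count(dets)
res
#> density-aware count: 25 (tier HIGH, 28 initial detections at conf >= 0.25)

evaluate_detections(res$kept, scene$boxes)[c("precision", "recall", "f1", "map50")]
#> $precision: 0.96   $recall: 0.923   $f1: 0.941   $map50: 0.923
```

The scene holds 26 animals; the noisy detector emits 28 boxes (one miss,
plus duplicates/false positives), the raw count ≥ 24 routes the scene to
the HIGH tier, and Soft-NMS retains 25 — one animal short, rather than
the larger deficit a hard 0.5 threshold would give on overlapping pairs.
Of the 25 retained boxes, 24 match a true animal at IoU ≥ 0.5.

Batch counting over simulated scenes:

```r
out <- count_scenes(scenes, dets_list)   # lists of scenes / detections
out$report
#> counting over 10 scenes: average_accuracy 0.9354, MAE 1.200, RMSE 1.673
head(out$pairs, 3)
#>   scene_id  a  b   tier
#> 1  scene-1 19 19 MEDIUM
#> 2  scene-2 25 24   HIGH
#> 3  scene-3 22 23   HIGH
```

`average_accuracy` is the scene-mean of 1 − |true − predicted|/true; MAE
and RMSE are the absolute and quadratic count errors.

A thin command-line front end with `simulate`, `suppress`, `evaluate` and
`count` subcommands is installed at `inst/cli/densecount.R`
(`Rscript $(Rscript -e 'cat(system.file("cli/densecount.R", package="densecount"))') --show-config`).

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the package's end-to-end pipeline from scratch: it samples 40
scenes at the taxonomy's category frequencies, runs the simulated
detector, the density-aware suppression and counting pipeline, and the
detection/counting metric suite, logging the batch summary (mean AP at
IoU 0.5, counting accuracy, MAE, RMSE) and writing the JSON report to
`--out`. All randomness derives from `--seed`.
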
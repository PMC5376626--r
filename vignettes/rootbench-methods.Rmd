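---
title: "Simulated ground truth for root image analysis: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulated ground truth for root image analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`rootbench` builds libraries of simulated root systems whose geometry is
known exactly, images them, re-measures the images, and quantifies — and
then corrects — the gap between image descriptors and ground truth. This
vignette documents the models and the design choices behind each stage:
what is assumed, what is tunable, and what the results do and do not show
about real data.

## 1. The growth model

Root systems are grown in two dimensions (the plane of a rhizotron or a
scanner image), in millimetres, with the seed at the origin and *y*
pointing downward. The rules are the classical minimal-parameter
architectural principles used by structural root models:

* **Elongation.** Each root tip carries a fixed apical diameter $d$ set
  at its emission. Per day it elongates by $E \cdot d$ where $E$
  (`elong_coeff`, mm day^-1 mm^-1) couples growth speed to tip
  thickness — thick roots grow fast, fine laterals slowly. Tips with
  $d <$ `d_min_mm` never elongate.
* **Branching.** Laterals are emitted acropetally, one every
  `interbranch_mm` of parent length, as soon as the parent tip has grown
  past the insertion point. A daughter's apical diameter is
  `diam_ratio` times the mother's, perturbed by a Gaussian factor with
  relative s.d. `diam_cv`; daughters below `d_min_mm` are unemerged
  primordia and are not kept. Because the daughter/mother ratio is < 1,
  branching depth is self-limiting.
* **Trajectory.** Each step the heading is pulled toward the downward
  vertical with weight `tropism_strength`, then perturbed by Gaussian
  angular noise (`direction_noise_sd_deg`). Two clamps encode
  gravitropism explicitly: laterals emerge at most 80° off the vertical
  (plagiotropic emergence — roots do not set off skyward), and no tip
  ever elongates more than 85° off the vertical. The clamps are what
  makes system *depth* an error-less quantity in the images: without
  them, weakly gravitropic laterals wander above the seed line and the
  image bounding box no longer measures rooting depth.
* **Radial (secondary) growth.** For tap-rooted systems only, every node
  thickens each day by `sec_growth_coeff` times the number of root
  apices downstream of it — a discrete pipe-model analogue. A single
  scalar thus produces the characteristic conical tap root whose base is
  many times thicker than its tip.
* **Plant types.** `fibrous`: 1–20 axes fanned up to ±60° around the
  vertical, no radial growth. `tap`: a single vertical axis with radial
  growth.

Time advances in fixed 1-day steps (`time_step_days`); the step length
bounds the spacing error of lateral insertions (they land exactly on
multiples of `interbranch_mm` along the parent) and sets the polyline
resolution. All randomness flows from a single integer seed per system;
identical seeds give byte-identical RSML output.

### Parameter sampling and envelope calibration

A library draws every growth parameter uniformly from per-type intervals
stored in `inst/extdata/sampling_intervals.json` (versioned data, not
code). The intervals were calibrated **once**, before any accuracy
experiment, against two requirements:

1. realized trait ranges over a 1,000-system library must stay within
   1.5× published envelopes for fibrous and tap libraries of this kind
   (total length up to ~75 m, up to thousands of laterals, tap bases up
   to centimetres thick) — the acceptance suite re-checks this;
2. the libraries must span sparse seedlings through heavily
   self-overlapping mature systems (overlap indices from ~0 to ~0.95),
   because the error-vs-complexity analyses need that spread.

Two early candidate ranges failed these requirements (a solid-mat regime
where nearly every segment overlapped, and a tap regime whose branching
cascade overshot the lateral-count envelope); the shipped intervals are
the corrected draw and are not revisited per experiment.

## 2. Ground truth and RSML

The 13 traits are computed from the vector representation: polyline arc
lengths, length-weighted mean diameters (the weighting is a deliberate
choice — a per-apex mean would over-weight short fine segments), lateral
density as per-axis count/length averaged over axes, insertion angle as
the unsigned angle between a lateral's first segment and the parent
tangent at the insertion abscissa, width as the x-extent and depth as the
maximal y of the node cloud. Traits of empty sets (lateral means of an
unbranched system) are `NA`, and deliberately so: the calibration stage
must demonstrate its imputation step on realistic missingness.

RSML files carry one scene/plant, nested `<root>` elements (nesting depth
= root order), a polyline geometry, a per-node diameter function and an
`insertion_position` property. Numbers are printed at 12 significant
digits: round-trips agree to below 1e-9 mm and identical systems produce
identical bytes. A reader flag (`multiple = "error"/"first"`) decides
what to do with multi-plant files; missing diameter functions fall back
to a configured default with a warning.

## 3. Imaging and degradation

Rendering strokes every polyline edge as a capsule (round caps) of width
equal to the local diameter, black on white, no anti-aliasing, with a
2 mm margin; the default 300 DPI (11.811 px/mm) matches flatbed-scanner
practice, and tests at 150 DPI trade resolution for speed. The minimum
stroke half-width is 0.5 px so the finest laterals stay visible — an
idealization: a real 0.1 mm root at 300 DPI is near the optical limit.
PNG is the default output (lossless, so descriptor runs are
deterministic); JPEG compression noise is deliberately not emulated.

Salt-and-pepper noise flips a fraction of uniformly chosen pixels to
black or white with equal probability; the fractions for `medium` and
`high` are configuration constants, 5% and 15% by default (chosen once
as a visually mild and a clearly degraded regime). The noise is the only
degradation modelled: blur, uneven illumination and soil occlusion are
out of scope, which bounds what the noise-robustness results transfer to.

The **overlap index** — the fraction of segments whose stroked areas
intersect a non-adjacent segment's stroke (minimal distance below the sum
of the two radii) — is computed on the vector side, not from pixels, so
it measures the geometry itself rather than the rendering; a
pixel-rasterized oracle cross-checks it in the tests. Adjacent edges of
one root and a lateral's first edge against its insertion neighbourhood
are excluded so that a straight root scores exactly 0.

## 4. The descriptor extractor

Binarization is a fixed global threshold (128), followed by removal of
8-connected components below 4 px (salt) and a one-sided 3×3 majority
fill of enclosed background pixels (pepper). The clean-up never erodes
foreground, so noiseless renders pass through bit-identically.
8-connectivity in the despeckle step matters: a 1-px diagonal root stroke
is 8-connected but 4-disconnected, and a 4-connected filter would delete
it wholesale.

Skeleton metrics thin the mask (Zhang–Suen, topology-preserving) and
count weighted adjacencies — 1 per 4-neighbour link, √2 per diagonal
link, diagonals skipped when a 4-connected path covers them — the
standard ImageJ-style length estimate. Tips are skeleton pixels with one
skeleton neighbour. Mean diameter is projected area divided by skeleton
length (the classical morphometric estimator; a distance-transform
alternative is noted in the configuration but not the default).

Geometry metrics use the pixel bounding box (width, depth, their ratio),
the foreground centroid in relative bounding-box coordinates, and the
convex hull over pixel *squares* (corner points of row/column extreme
pixels), so a filled rectangle is exactly its own hull and the
exploration ratio (hull/area) is exactly 1 there. `exploration` follows
the hull/projected-area direction; part of the literature uses the
reciprocal ("solidity"), available via `exploration_inverse` in the
configuration.

## 5. Evaluation layer

MRE excludes pairs with zero truth (a relative error is undefined there)
and always reports how many were excluded. r² matrices are squared
Pearson correlations per (descriptor, trait) cell, per plant type, with
listwise deletion per cell and `NA` for constant or under-populated
(< 3) cells. The overlap-binned MRE uses equal-width bins over the
observed overlap range; bins with fewer than 5 rows are flagged, never
interpolated.

PCA standardizes traits to unit variance before decomposition — the
traits span four orders of magnitude (millimetres to thousands of
laterals), so an unscaled PCA would only measure total length. Missing
trait values are median-imputed for the multivariate analyses. MANOVA
uses Pillai's trace. One structural subtlety: the trait set is *exactly*
collinear (total length = first-order + lateral length, and single-axis
systems duplicate total/mean axis length), so aliased columns are
detected by rank and dropped with a warning before the test; without
this every MANOVA on exact simulated traits would be singular.

## 6. Random-forest calibration

The learning problem: predict each of the 13 traits from the 11
descriptors plus a plant-type indicator. The framework is deliberately
simple and fully seeded:

* **Split.** 3/4 training, 1/4 test, stratified by plant type.
* **Imputation (training only).** Missing cells → column median, then a
  10-tree regression forest fitted on the completed table re-predicts the
  originally missing cells. Ten trees (not the package default of 300)
  keep this step cheap at equal practical accuracy. Observed values are
  never altered; rare missing *test* features receive the training
  median only, so no information flows out of the test responses.
* **Model generation.** For each trait and each pair $(t, m)$ in
  trees × splits grids (defaults {10, 50, 100, 300} × {1, 2, 4}), the
  training rows are partitioned into $m$ disjoint subsets and a $t$-tree
  forest is fitted on each; a candidate predicts by averaging its $m$
  forests. $m = 1$ degenerates to a single forest; $m > 1$ trades
  per-forest sample size for ensemble diversity.
* **Selection.** Held-out RMSE per candidate; the minimizer wins, ties
  break toward fewer trees then fewer subsets. The whole RMSE grid is
  retained for inspection.

Regression forests split on variance reduction — the regression analogue
of the Gini impurity used for classification in the same package
lineage. Responses are modelled independently (one model per trait), and
models are trained per noise level; pooling noise levels into one model
is possible by passing the combined table but is not the default,
because per-noise training mirrors the question "how well can this
image quality be calibrated?".

## 7. Problem sizes and numerical choices

The test suite and the acceptance script size their experiments as: 500
fibrous + 500 tap systems for the type-separation and error-growth
analyses, 2,000 systems (rendered at 150 DPI) for the calibration
experiments, 200 renders for the depth check — sizes at which the
reported quantities are stable to the seed while a full run stays in the
minutes range on one CPU. Insertion points are validated to 1e-6 mm;
RSML round-trips to 1e-9 mm; hand-arithmetic identities (MRE, RMSE) to
1e-12. Degenerate inputs (zero-duration systems, empty masks, pure-noise
images, constant columns, sub-minimal bins) return explicit `NA`/flags
or are rejected with named errors rather than silently propagating.

## 8. What passing tests do and do not show

The simulator emulates geometry, not physiology: no soil heterogeneity,
no water or nutrient tropisms, no plasticity, no root death, and 2D
growth only. The imaging model is binary and noise means salt-and-pepper
only. Consequently, results transfer to real images in proportion to how
far those idealizations hold: the qualitative claims (geometric traits
are robust, morphological traits degrade with overlap and noise, learned
calibration beats any single descriptor) are the transferable content,
while the specific error magnitudes are properties of this simulator and
this extractor. Calibration models trained on one library apply only to
images at the same scale and a comparable noise regime — exactly the
caveat that motivates generating a custom library for one's own imaging
setup.
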
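---
title: "Quantifying rosettes, markers, colocalization and expression screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying rosettes, markers, colocalization and expression screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(organoidquant)
```

## What this package computes

Cerebral-organoid studies of Alzheimer's-protective genetics rely on a small
set of bespoke quantifications layered on top of standard imaging and
single-cell tooling: intensity measurements inside hand-drawn neural-rosette
regions, background-corrected punctate-marker quantification (pTau S396,
Reelin), thresholded colocalization volumes between nuclear, neuronal and
signalling markers, arithmetic filters over gene-by-cell count matrices, and a
fixed group-comparison chain. organoidquant implements exactly those pieces as
tested, seeded, reusable functions, together with a synthetic-data generator
that plants known ground truth for each stage so the whole pipeline can be
validated end to end without patient data.

## Rosette geometry in physical units

A rosette is delineated by two hand-drawn closed polylines in microns: the
outer tissue boundary and the inner luminal boundary. Two regions of interest
derive from them:

* **Body** — the annulus between the boundaries, *eroded* by 1.8 µm so that
  neither boundary's edge pixels contaminate the measurement.
* **Ribbon** — the inner boundary line *dilated* by 1.8 µm, capturing the thin
  apical band of beta-catenin enrichment around the lumen.

Erosion and dilation are realized as thresholds on the exact Euclidean
distance from each pixel centre to the boundary curves rather than as discrete
structuring elements. This has three consequences worth stating:

1. The operation is isotropic at any pixel size — no disk-discretization
   anisotropy — and the µm parameters transfer across magnifications.
2. A brute-force per-pixel oracle (point-in-polygon plus exact distance
   minimization) reproduces the masks pixel for pixel, which the test suite
   exploits on randomized boundaries.
3. The tie-break is explicit: Body keeps pixels with distance strictly
   greater than 1.8 µm, Ribbon keeps distance less than or equal to 1.8 µm, so
   the two masks are disjoint at the shared front whenever erosion equals
   dilation.

Pixels live on a calibrated grid with centres at `(i + 0.5) * pixel_size_um`,
0-based indices, y increasing downward. Rasterization uses the even-odd rule
on pixel centres. Optional Otsu refinement (off by default) removes background
pixels from the hand-drawn regions; the threshold is computed on a 256-bin
histogram of the intensities within the geometric region being refined
(annulus for Body, band for Ribbon), on the channel being quantified. Which
channel fed the refinement in the original workflow is not documented, so the
channel is configurable and recorded in the output.

Morphometrics: area is the pixel count of Body ∪ Ribbon times the pixel area —
the lumen interior is deliberately excluded, following the definition of the
ROIs as the measured regions. Aspect ratio is the major/minor axis ratio of
the ellipse with the same normalized second central moments as the
hole-filled union: filling makes the measure describe the rosette outline
rather than the annulus, which is what "rosette aspect ratio" means
morphologically. Rotation invariance holds to well under 2% at 0.2 µm pixels.

```{r geometry-example}
sc <- make_rosette_scene(rosette_scene_params(noise_sigma = 0))
measure_rosette(sc$image, sc$truth$outer, sc$truth$inner,
                rosette_id = "demo", group = "control")
```

## Punctate marker quantification

Marker channels are background-corrected with a white top-hat: the image minus
its grayscale opening with a 54 µm-radius disk. The disk is rasterized by
pixel-centre distance with the radius rounded to whole pixels; the image is
replicate-padded by one disk radius before the opening so border pixels are
not attenuated (without padding a tilted illumination plane loses several AU
near the high edge). Any background feature smoother and wider than the disk
is removed exactly — the opening of an affine plane is the plane itself — while
puncta far smaller than 54 µm pass through unchanged. Foreground is then
`intensity >= Otsu threshold` on a 256-bin histogram of the whole corrected
image (ties to foreground), and the record keeps the threshold, the
foreground mean and the foreground fraction. The order matters and is pinned
by a regression test: thresholding before background subtraction gives a
different, wrong answer on a tilted plane.

One numerical property deserves emphasis: on a noisy image the opening rides
on local noise minima, so the top-hat output — and therefore the foreground
mean — overshoots the true amplitude by roughly 2–2.5 noise standard
deviations. This is inherent to top-hat background subtraction, not an
implementation artifact. Noiseless scenes are recovered exactly; recovery
tests run at a signal-to-noise ratio of 100 (amplitude 200 AU, sigma 2 AU),
where the bias is ~1–3% of the amplitude, and a dedicated test pins the bias
property itself (positive, at most 3 sigma) at sigma 5.

## Thresholded colocalization volumes

For 3D stacks with `target` (beta-catenin), `nuclear` (DAPI) and `neuronal`
(NeuN) channels, each channel is binarized — per-channel Otsu over all voxels
by default; fixed thresholds are supported and always recorded — and the TVC
of an ordered pair is `100 * |A ∩ B| / |A|`. The measure is asymmetric; the
denominator channel is the target, and both orientations are emitted since the
original description leaves the orientation of the neuronal comparison
ambiguous. `coloc_report()` assembles per-stack rows across labelled regions
(e.g. brain areas) and runs the group-comparison chain on the
target-denominator percentages when at least two regions with two stacks each
are present. 2D images are accepted as single-slice volumes.

## The expression screen

The screen operates on gene-by-cell integer count matrices with supplied
cluster labels — clustering, integration and doublet removal are upstream
tools' responsibility, and the upstream multiplet rate (0.8%) is carried only
as provenance metadata in run configurations.

* **QC**: per cell, `nFeature` (genes detected), `nCount` (total counts) and
  `pct_mito` (percent mitochondrial). A cell is removed iff
  `nFeature > 8000`, `nFeature < 200`, `nCount > 50000` or `pct_mito > 20` —
  all strict inequalities, pinned by boundary tests (a cell at exactly 200
  features survives).
* **Downsampling**: uniform, seeded sampling without replacement to a fixed
  6400 cells, making samples comparable.
* **Cluster-aggregate ratios**: each cell is library-size-normalized to
  10,000 counts, cluster means are arithmetic, and the per-(gene, cluster)
  statistic is `log2((mean_A + eps) / (mean_B + eps))` with eps = 0.01. The
  normalization and pseudocount are not documented in the original workflow;
  both are configurable and recorded in the output's `parameters` attribute.
  A pseudobulk mode (all cells as one cluster) is available; per-cluster is
  the default.
* **Selection**: `|log2 ratio| > 1`, strict, per cluster, in deterministic
  gene order.
* **Enrichment cutoff**: consumed NES scores are filtered at `>= 7.5`
  (boundary kept); each cluster is assigned the arg-max surviving set, ties
  resolved lexicographically and flagged, clusters with nothing surviving
  labelled "unassigned".
* **Overrepresentation**: for each gene set, a one-sided binomial tail
  `P(X >= k)` with `p0 = |set ∩ background| / |background|`, Bonferroni
  correction over the number of sets tested.

## The group-comparison chain

Every grouped measurement — rosette intensities, marker means, TVC
percentages, reporter activities — flows through the same chain: per-group
Shapiro–Wilk normality (reported alongside, never switching the test
automatically, matching the original analysis which reports ANOVA
regardless), one-way ANOVA, and Tukey's multiple comparison using the
Tukey–Kramer form, since real group sizes are unbalanced (n = 17–159
measurements per line in the source data). Isogenic-control lines are pooled
per patient before comparison; pooling raw measurements is the default, with
a per-line-means mode behind a flag because the original wording ("averaged
together") does not distinguish the two. Degenerate inputs are handled
explicitly: identical group means give F = 0, p = 1; a zero within-group
variance with distinct means gives F = Inf, p = 0.

## The synthetic-data generator

Each generator plants ground truth (`SceneTruth`) and is bit-reproducible
under a fixed seed:

* **Rosette scenes** (`make_rosette_scene`): elliptical lumen and outer
  boundary (128-vertex polygonal truth, optionally off-centre lumen and
  rotated), ribbon band painted within a half-width of the lumen curve, body
  at lower intensity, optional linear illumination ramp, additive Gaussian
  noise clipped at zero. Regions are painted from the same polygonal
  boundaries handed to the ROI stage, so in the noiseless case every measured
  mean equals its planted value *exactly*, not approximately. Defaults: 64 µm
  field at 0.25 µm/px, body 100 AU, ribbon 300 AU, background 20 AU, noise
  10 AU, ribbon half-width 1.8 µm.
* **Marker fields** (`make_marker_field`): affine background plane plus
  non-overlapping disk puncta kept clear of the border (placement retried,
  error after 100 failures), default 256 µm field at 1 µm/px, 30 puncta of
  radius 5 µm and amplitude 200 AU.
* **Colocalization stacks** (`make_coloc_stack`): the target support is a
  union of random spheres; companion channels take an axial sweep of exactly
  `round(f * |target|)` target voxels plus spheres disjoint from the target,
  so the planted overlap fraction is exact by construction (identical support
  at f = 1, disjoint at f = 0).
* **Count experiments** (`make_count_experiment`): negative-binomial counts
  per gene × cluster (dispersion 0.1 — no generative model is documented for
  the real data, so the standard NB parameterization was chosen), log-normal
  gene base means (meanlog 0, sdlog 1) giving realistic per-cell totals for a
  moderately expressed feature panel, shared per-cluster wobble, planted
  fold-changes applied to sample A's cluster means, named QC violators
  planted against the supplied thresholds. Planted differential genes are
  drawn from genes with base mean ≥ 0.5 counts — the standard convention for
  a power check, since fold-change recovery on near-zero genes measures
  shot noise, not the method.

What the generator does *not* emulate — real organoid histology, point-spread
optics, read-level sequencing noise, ambient RNA, batch effects — bounds what
passing tests demonstrate: they validate the *arithmetic* of the pipeline
(masks, means, thresholds, ratios, tests) against planted truth, not the
biological interpretability of any particular staining.

## Validation scales and numerical choices

The test-suite study sizes are chosen to exercise each property at meaningful
precision: mask-oracle equivalence on twenty randomized 128² boundary pairs;
analytic-area recovery on a circular rosette at 0.4/0.2/0.1 µm pixels (area
errors are two orders of magnitude below the 1% bound; because rasterization
error oscillates with sub-pixel grid phase, convergence is asserted
endpoint-wise across the refinement sequence rather than stepwise); TVC
recovery on 64³ stacks at f ∈ {0, 0.25, 0.5, 1}; differential-expression
recall and false-selection on 1000-gene, 3-cluster, 500-cells-per-cluster
experiments over 20 seeds; QC set-equality on an 8500-gene experiment (an
`nFeature > 8000` violator needs more than 8000 genes); and a calibration
study of the full synthetic-rosette pipeline — 500 null runs and 100
powered runs of 3 groups × 20 rosettes on 64² scenes, with 10% between-rosette
biological variation — checking the type-I error at alpha = 0.05 and the
power to detect a 1.5× ribbon effect at p < 0.01. Scene geometry is cached
across repeated generation with identical geometric parameters; noise is
drawn fresh per scene, so determinism and independence are unaffected.

Numerical conventions collected in one place: Otsu thresholds come from
256-bin histograms with the returned value at a bin edge and ties going to
foreground; distances and erosion depths are exact Euclidean in microns;
polygon insideness is even-odd on pixel centres; self-intersecting polygons
are rejected, not repaired; empty masks after erosion warn and return empty
rather than erroring mid-pipeline; intensity I/O quantizes to 16-bit unsigned
TIFF pages with the micron calibration in a JSON sidecar (reading requires
the sidecar or an explicit pixel-size override).

## Known limitations

Hand-drawn boundaries are inputs, never detected automatically. ROI geometry
is strictly 2D; stacks are only consumed by the colocalization stage.
A Welch ANOVA variant is available behind `one_way_anova(welch = TRUE)` but
is off by default — the chain reproduces the fixed classical analysis.
The top-hat noise bias described above means foreground means from noisy
images carry a small systematic overshoot; compare conditions imaged at
similar noise levels.
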
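# organoidquant

Quantification pipeline for fluorescence imaging and single-cell screens in
cerebral-organoid studies of Alzheimer's-protective genetics — the kind of
study that asks whether an edited iPSC line (e.g. carrying the APOE3
Christchurch variant) changes tau phosphorylation, beta-catenin distribution
in neural rosettes, or cell-type composition, relative to isogenic controls.

The measurements such studies need are simple but easy to get subtly wrong:
intensity means inside hand-drawn regions eroded/dilated in *physical*
microns, background-corrected punctate-marker quantification, thresholded
colocalization volumes, strict QC cutoffs over count matrices, and a fixed
statistics chain. organoidquant implements each as a tested, seeded function,
plus a synthetic-data generator that plants known ground truth so every stage
is validated end to end.

## The core quantities

**Rosette ROIs.** From the hand-drawn outer boundary and inner luminal
boundary of a rosette (polylines in µm):

* Body = annulus between the boundaries, eroded by 1.8 µm:
  pixels with Euclidean distance > 1.8 µm to both boundary curves.
* Ribbon = the luminal boundary dilated by 1.8 µm:
  pixels with distance ≤ 1.8 µm to the curve.
* area = |Body ∪ Ribbon| · px², aspect ratio = major/minor axis of the
  equal-second-moment ellipse of the hole-filled union.

**Marker quantification.** White top-hat with a 54 µm-radius disk
(`I − opening(I)`), then Otsu foreground (256-bin, ties to foreground),
reporting the foreground mean — in that order.

**Colocalization.** `TVC(A, B) = 100 · |A ∩ B| / |A|` on per-channel
thresholded volumes.

**Expression screen.** Remove cells with nFeature > 8000 or < 200,
nCount > 50000 or %mito > 20 (strict); downsample to 6400 cells;
per (gene, cluster) compute `log2((mean_A + ε)/(mean_B + ε))` on
counts-per-10k cluster means (ε = 0.01); select `|log2 ratio| > 1`; assign
cell types at NES ≥ 7.5; binomial overrepresentation with Bonferroni.

**Statistics.** Shapiro–Wilk (reported), one-way ANOVA, Tukey–Kramer
post-hoc, with isogenic-control lines pooled per patient.

## Worked example

Simulate two groups of eight rosettes (isogenic controls with planted ribbon
mean 300 AU, edited at 220 AU, 10% biological scatter, pixel noise 10 AU),
quantify beta-catenin in the Body and Ribbon ROIs, and run the comparison
chain on the ribbon means:

```r
library(organoidquant)

set.seed(7)
rows <- do.call(rbind, lapply(1:2, function(g) {
  grp <- c("isogenic-control", "APOE3Ch-edited")[g]
  mu0 <- c(300, 220)[g]
  do.call(rbind, lapply(1:8, function(i) {
    mu <- rnorm(1, mu0, 0.1 * mu0)
    sc <- make_rosette_scene(rosette_scene_params(
      ribbon_mean = max(mu, 0), noise_sigma = 10, seed = 100 * g + i))
    measure_rosette(sc$image, sc$truth$outer, sc$truth$inner,
                    rosette_id = sprintf("%s_%d", grp, i), group = grp)
  }))
}))
rows
#> # A tibble: 16 × 6
#>   rosette_id         group           mean_body mean_ribbon area_um2 aspect_ratio
#> 1 isogenic-control_1 isogenic-contr…      100.        369.    1244.         1.27
#> 2 isogenic-control_2 isogenic-contr…      100.        264.    1244.         1.27
#> ...

group_report(dplyr::transmute(rows, group = group, value = mean_ribbon))
#> One-way ANOVA: F(1, 14) = 9.79, p = 0.007396
#> Tukey pairs:
#>           group1           group2   diff     q    p_adj
#> 1 APOE3Ch-edited isogenic-control -46.53 4.425 0.007396
```

Reading the output: `mean_body` sits at the planted 100 AU; `mean_ribbon`
scatters around each group's planted mean (369, 264, … for controls); the
fixed geometry gives every rosette the same area (1244 µm²) and aspect ratio
(1.27 — the 25/20 µm outer ellipse after 1.8 µm erosion, 23.2/18.2). The
ANOVA detects the planted 80 AU group difference at p ≈ 0.007, and the single
Tukey pair reports the mean difference of −46.5 AU actually realized by this
seed's biological scatter.

Other entry points follow the same pattern: `quantify_marker()` for
top-hat + Otsu marker means, `threshold_channel()` + `tvc()` +
`coloc_report()` for colocalization, `compute_cell_qc()` → `qc_filter()` →
`downsample_cells()` → `cluster_aggregate_log2ratio()` → `select_de_genes()`
for the screen, and `run_pipeline()` / `inst/cli/organoidquant` to drive
stages over files (TIFF + sidecar, boundary CSV or ImageJ RoiSet,
MatrixMarket counts, YAML configs).

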
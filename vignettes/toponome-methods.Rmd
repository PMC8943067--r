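---
title: "Methods: combinatorial molecular phenotype analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: combinatorial molecular phenotype analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(toponome)
```

## The model

Serial immunostaining microscopy localizes many markers on one specimen by
cycling stain → image → photobleach → re-stain. After binarization, each
pixel carries a binary vector over the ordered marker panel — its
*combinatorial molecular phenotype* (CMP), written as a bitstring with
marker 0 leftmost. The analysis chain implemented here treats the CMP, not
any single marker level, as the unit of observation:

1. **Channel preparation.** Each marker's image is aligned to a reference
   channel, the matched post-bleach image is subtracted pixel-wise
   (clipped at zero), and the result is binarized. Merging the ordered
   masks yields a per-pixel CMP image; a border margin (15 px by default)
   is excluded, and the all-zero pattern is background, never tabulated.
2. **Catalogs.** CMPs are ranked by pixel count; whole-image analyses use
   the 54 most abundant. A *lead protein* table keeps only CMPs containing
   a chosen marker, in the order of the full ranking.
3. **Conservation.** For a group of three replicate samples, a CMP is
   3-of-3 conserved when it appears in every sample's top-54 list. The
   relaxed 2-of-3 measure makes the three pairwise comparisons
   (1v2, 1v3, 2v3), counts the CMPs shared by each pair but not by all
   three, and reports the mean of the three pairwise counts — which is
   why the value can be fractional. Column totals (All + one column per
   lead marker) of the two groups are compared with a two-sided Wilcoxon
   rank-sum test. These 13 columns share pixels, so the test is
   descriptive (pseudo-replication), and we report it as such.
4. **Single cells.** A cell's pixels give a within-cell CMP ranking; the
   profile counts, for each marker $m$, how many of the cell's 20 most
   abundant CMPs contain $m$ ($k_m \in 0..20$), with fractions
   $f_m = k_m / \text{CMPs used}$.
5. **Clustering and scoring.** Cells are clustered on their $f$ vectors by
   agglomerative hierarchical clustering and the tree is cut to a chosen
   $k$. Each cluster's composition against a two-level factor is scored by
   the 1/3–2/3 rule; association strength between cluster membership and
   the factor is Cramér's
   $V = \sqrt{\chi^2 / (n\,(\min(r,c)-1))}$ with the Pearson statistic and
   no continuity correction.

## Key parameters

| Parameter | Default | Meaning |
|---|---|---|
| `margin` | 15 px | excluded border of the field |
| `top_n` | 54 | whole-image abundance cut per column |
| `top_k` | 20 | CMPs summarized per cell |
| `k` | user-chosen | clusters after cutting the tree (7 for a 12-marker panel, 12 for the 7-marker cross-study comparison, in the analyses this mirrors) |
| `linkage`, `metric` | `ward.D2`, Euclidean | clustering defaults |
| `lo`, `hi` | 1/3, 2/3 | predominance thresholds |

Whole-image CMP frequencies are kept as raw pixel counts: abundance scales
with the number of cells in the field, so cross-image normalization is
deliberately left to the consumer. Per-cell fractions $f_m$ normalize by
the number of CMPs actually used, keeping cells with fewer than 20
distinct CMPs comparable.

## Numerical and design choices

* **Tie-breaking.** Ranking ties (equal pixel counts) are broken by
  ascending lexicographic bitstring. Any total order would do; fixing one
  makes the top-54/top-20 cuts and every downstream statistic
  reproducible.
* **Strict threshold.** Binarization uses a strict `>`, so a resolved
  threshold of 0 (e.g. a zero quantile) does not promote exact-zero pixels
  to foreground. A constant image under Otsu has no separating threshold
  and yields an all-background mask with a warning.
* **Registration.** Only integer translation is searched (serial imaging
  of a fixed slide drifts, it does not rotate), exhaustively within
  `±shift_max`. Both images are demeaned first so the flat illumination
  background carries no weight; ties break toward the smallest L1 shift,
  then lexicographically, which pins a structureless channel at (0, 0).
  Cross-channel registration is only determined by structure the channels
  share: a channel whose content sits entirely in the interior of cell
  disks (e.g. sparse puncta, or a near-empty stain) gives a correlation
  plateau and its 1-px alignment is genuinely unidentifiable. The
  registration tests therefore use configurations in which every channel
  carries dense in-cell structure.
* **Exact predominance thresholds.** The 1/3–2/3 rule is applied as an
  exact rational comparison (with an `all.equal` guard against binary
  rounding), not as rounded percentages: a 2-of-6 cluster (exactly 1/3)
  is classified predominantly-other, not mixed. This reading is the one
  consistent with the bundled 12-cluster treatment table, whose published
  scoring (53/46/118 cells) requires the 2-of-6 cluster to count as
  predominantly SP-A1.
* **2-of-3 semantics.** The per-pair counts exclude the triple
  intersection, and the reported value is the mean of the three pairwise
  counts (sum/3). The sum of the three counts can be odd, so it cannot be
  a per-sample tally in which each shared CMP contributes twice; the
  pairwise-comparison reading is the one the bundled worked example
  (8, 14, 11 → mean 11) satisfies.
* **Common row.** By default a CMP is "conserved in both groups" when it
  is 3-of-3 in each group (i.e. present in all six samples);
  `common = "union23"` relaxes this to ≥ 2-of-3 in each group.
* **Clustering input.** Cells are clustered on the length-$M$ fraction
  vectors $f$ — the same quantity plotted as per-cell line graphs and
  averaged into cluster signatures. Richer representations (full CMP
  histograms) are possible but not what the summary-vector workflow uses.
* **Marker-mean contrasts.** The default contrast set is the six group
  pairs of a two-treatment, two-sex design (treatment overall and within
  each sex; sex overall and within each treatment), each tested per marker
  with a two-sided rank-sum test — 6 × 7 = 42 tests for a 7-marker panel —
  and Benjamini–Hochberg adjusted jointly across all contrast × marker
  tests. Fully tied samples are reported at p = 1.
* **Rank-sum method.** The exact null distribution is used when both
  samples have ≤ 25 observations and no ties; otherwise the normal
  approximation with tie correction. The method used is reported.

## What the simulator emulates — and what it does not

`sim_config()` / `simulate_cohort()` generate fields of sparse,
non-overlapping, disk-shaped cells placed fully inside the margin. Each
cell draws one phenotype from a library of per-marker expression
probability vectors; marker presence is then Bernoulli *per pixel*, so a
cell produces a distribution of CMPs — without this, a per-cell "top 20
CMPs" would be degenerate. Marker 0 is punctate autofluorescence (small
disks at a Poisson rate per cell), the last marker is diffuse F-actin.
Grayscale images are `base + amplitude · presence + Gaussian noise`
clipped at zero; each channel has a matched post-bleach background
(`bleach_residual` of the clean signal plus fresh noise), and channels can
be mis-registered by bounded integer shifts. Group effects enter through
the phenotype weights: the default weights concentrate vehicle-treated
cells on two phenotypes and spread rescue-treated cells uniformly
(treatment increases diversity), with sex rotating which phenotypes are
favored. No quantitative effect sizes are estimated from any real
dataset; they are free, documented parameters.

Not modeled: optical point-spread, spectral autofluorescence, realistic
cell shapes or touching cells, illumination gradients, time-lapse. Passing
the end-to-end tests therefore demonstrates correctness of the
*computation* on controllable inputs, not robustness to every real-data
artifact; in particular, real segmentation and manual cell selection are
out of scope (ROIs are taken as given).

## Verification strategy and problem sizes

The suite validates each operation against an independent oracle:
brute-force dictionary counts for catalogs, set algebra for conservation,
exhaustive enumeration of rank assignments for the rank-sum test,
per-pixel lookup for ROI extraction, recounts for profiles, and the
ground-truth CMP image (which bypasses binarization entirely) for the full
preprocessing chain — on noiseless fields the chain must match it
*exactly*, pixel for pixel. Published 103-cell and 217-cell
cluster-composition tables are bundled as CSV and must reproduce their
known scoring totals and Cramér's V values to the printed precision.
Simulation-based checks use fields of 96–160 px with 4–8 cells per sample
and 50 replicates for the directional Cramér's V property; these sizes
keep the suite fast while leaving dozens of cells and hundreds of CMPs
per instance, and the same code runs unchanged at the instrument scale
(2048 px).

## Known limitations

* Conservation is defined for the 3-replicate design; other group sizes
  are rejected rather than silently generalized.
* The rank-sum comparison of conservation totals inherits the
  pseudo-replication of its 13 shared-pixel columns.
* Cluster labels are arbitrary (they come from the cut order of the
  tree); only composition, scoring and association are meaningful across
  runs.
* Whole-image CMP counts are not comparable across images with different
  cell numbers; use conservation or per-cell profiles for cross-sample
  statements.
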
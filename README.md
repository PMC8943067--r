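# toponome

Pixel-level phenotyping for multiplexed (serial) immunofluorescence
imaging of cells, built around the **combinatorial molecular phenotype
(CMP)**: the binary present/absent pattern of an ordered marker panel at a
single pixel, written as a bitstring whose leftmost digit is marker 0
(conventionally cellular autofluorescence). A pixel where only marker 8 of
a 12-marker panel is present carries CMP `000000001000`.

The package targets workflows such as alveolar macrophage (AM) profiling
in surfactant protein A (SP-A) knockout / SP-A1 rescue experiments, where
the questions are: how conserved are the abundant CMPs across replicate
animals, how heterogeneous are single cells, and whether cluster structure
in per-cell marker profiles associates with treatment or sex. It is aimed
at image-analysis and computational-biology users who have per-marker
grayscale images (or pre-binarized masks) plus sample metadata, and who
want a tested, scriptable re-implementation of the full analysis chain.

## What it computes

* **Preprocessing** — per-channel alignment by integer-shift zero-mean
  cross-correlation, post-photobleach background subtraction
  (`max(signal − bleached, 0)`), per-channel binarization (Otsu default,
  fixed/quantile override), and merging of the ordered mask stack into a
  per-pixel CMP image with a 15-pixel excluded border.
* **CMP catalogs** — frequency-ranked CMP tables (rank 0 = most abundant),
  top-N cuts (N = 54 by default), and marker-specific *lead protein*
  tables containing only CMPs that include a given marker, in original
  ranking order.
* **Conservation** — for groups of 3 replicate samples: CMPs in all three
  top-54 lists (3-of-3), mean pairwise 2-of-3 matches, per-column totals
  (All + one column per lead marker), cross-group Common counts, and a
  Wilcoxon rank-sum comparison of the column totals.
* **Single cells** — per-cell top-20-CMP marker profiles: for each marker
  `m`, `k_m` = number of the cell's 20 most abundant CMPs containing `m`,
  and `f_m = k_m / (CMPs used)`.
* **Clustering & scoring** — Ward hierarchical clustering of the `f`
  vectors cut to `k` clusters; cluster composition scored by the 1/3–2/3
  rule (a cluster is "predominantly X" when level X makes up ≥ 2/3 of its
  cells, "predominantly Y" at ≤ 1/3, else "mixed"); Cramér's V
  (`sqrt(χ²/(n·(min(r,c)−1)))`) between cluster membership and any
  two-level factor; group marker means with BH-adjusted pairwise rank-sum
  contrasts.
* **Synthetic data** — a simulator of multi-marker fields (non-overlapping
  round cells, pixel-level Bernoulli marker expression given a cell
  phenotype, punctate autofluorescence, diffuse F-actin, Gaussian noise,
  bleach residual, channel mis-registration) with full ground truth, so
  every stage is testable end to end.

## Worked example

```r
library(toponome)

cfg <- sim_config(field_size = 256, n_cells = 10, seed = 42)
design <- tidyr::expand_grid(group = c("Vehicle", "Rescue"), rep = 1:3) |>
  dplyr::mutate(sample_id = paste0(substr(group, 1, 1), rep),
                sex = rep(c("Female", "Male", "Female"), 2))
co <- simulate_cohort(cfg, design)
run <- run_pipeline(co, k = 5)
run
#> <toponome_run> 6 samples, 60 cells, k = 5
#> Cramér's V: group = 0.541, sex = 0.211
```

Six simulated samples (two treatment groups of three mice) were
preprocessed, tabulated, profiled and clustered into 5 clusters; the V
values say cluster membership tracks treatment (0.54) much more than sex
(0.21) in this cohort — as designed, since the default simulator weights
differ mainly by treatment. The conservation table gives, per column and
group, the strict and relaxed conserved-CMP counts out of the top 54:

```r
head(tidy(run$conservation), 4)
#> # A tibble: 4 × 5
#>   column group   n_3of3 mean_2of3 total
#>   <chr>  <chr>    <int>     <dbl> <dbl>
#> 1 All    Rescue      33      6.33  39.3
#> 2 All    Vehicle     25      9.67  34.7
#> 3 0      Rescue      21      6     27
#> 4 0      Vehicle     15      7.67  22.7
```

Scoring a published 103-cell, 7-cluster AM composition table (bundled as
example data) with the 1/3–2/3 rule:

```r
score_clusters(example_composition("treatment_k7"), reference = "Vehicle")
#> <cluster_scoring> reference = Vehicle (thresholds 0.333 / 0.667)
#> # A tibble: 3 × 4
#>   label               n_clusters n_cells pct_cells
#>   <chr>                    <int>   <int>     <dbl>
#> 1 predominant-Vehicle          3      51      49.5
#> 2 predominant-SP-A1            2      27      26.2
#> 3 mixed                        2      25      24.3
```

Three clusters holding 51 cells (49.5%) are predominantly vehicle-treated,
two (27 cells, 26.2%) predominantly SP-A1-rescued, two (25 cells, 24.3%)
mixed. `cramers_v(example_composition("sex_k12"))` gives 0.75 for the
sex × cluster association of the bundled 217-cell comparison.

Every result type has `tidy()`/`glance()` methods and an `autoplot()` or
`plot_*()` function (`plot_cell_profiles()`, `plot_dendrogram()`, ...).

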
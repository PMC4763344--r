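# crossview

Cross-view pattern analysis of multi-view neuroimaging biomarkers for
Alzheimer's disease staging.

Different quantitative measures ("views") extracted from the same brain —
gray-matter volume from T1-MRI, gyrification and shape ratios, metabolic
indices and lesion descriptors from FDG-PET — each depict disease pathology
from a different angle. Combining two views often classifies AD / MCI / NC
subjects better than either view alone, but not every combination helps.
`crossview` is a toolbox for researchers who want to *quantify* that
structure: which brain regions each view finds discriminative, how similar
two views' pathology patterns are, how the views cluster, and whether the
cluster structure predicts which pairs create synergy in staging.

## What it computes

Working from a cohort feature table (subjects × 83 atlas ROIs per view, with
diagnosis labels) or directly from labelled NIfTI volumes:

1. **ROI feature extraction** — nine views per subject: GMV, LGI
   (gyrification), CNV (convexity = hull area / surface area), SLD (solidity
   = volume / hull volume) from MRI; M-IDX (cerebellum-normalised mean
   activity), F-IDX (coefficient of variation), and DoG-M / DoG-C / DoG-Z
   (mean, contrast and voxel fraction of hypometabolic lesions found by
   multi-scale Difference-of-Gaussian filtering) from PET.
2. **Pathology patterns** — per view, a one-way ANOVA of each ROI across the
   NC / MCI / AD groups gives p-values *P(i)*, transformed as

       P'(i) = exp(-P(i)² / 2σ²),   σ = 0.05
       P″(i) = P'(i) / Σⱼ P'(j)

   so each view becomes a probability vector over ROIs concentrating on its
   discriminative regions.
3. **Cross-view structure** — pairwise Kullback–Leibler divergences between
   patterns (oriented as `d[row, col] = D(col‖row)`), the
   affinity `A(P,Q) = exp(-(D(P‖Q)+D(Q‖P)) / 2π)`, the symmetric normalised
   Laplacian `L = I − D^{−1/2} A D^{−1/2}`, its 2-D spectral embedding, and
   k-means view clustering.
4. **Staging** — a cascade of kernel SVMs (NC-vs-rest, then AD-vs-rest, then
   a three-class one-vs-one machine) over single-view RBF kernels or
   multi-kernel convex combinations, tuned by random search under stratified
   5-fold cross-validation, reporting per-class precision, accuracy,
   specificity and sensitivity (NC negative; MCI∪AD positive).
5. **Synergy analysis** — per view pair, the joint performance `E_joint`
   against the stronger/weaker single view (`E_high`, `E_low`) and the
   divergence summaries (`D_mutual`, `D_high`, `D_low`), with Pearson
   correlations and a best-pair report flagging inter- vs intra-cluster
   combinations.

Because the cohort the method was developed on is access-restricted, the
package ships synthetic generators with full ground truth: geometric
phantoms (balls, boxes, indented and C-shaped regions, planted Gaussian
cold spots) for the image-based features, and a latent-archetype cohort
model (9 views, 4 archetypes sized 3/1/3/2, K = 83, groups 77/169/85) for
everything downstream. Every claim in the test suite is scored against that
ground truth.

## Worked example

```r
library(crossview)

bench <- default_benchmark(seed = 1, n_scale = 0.25)  # 82 subjects
bench$table
#> <cohort_table> N = 82 subjects ( NC=19, MCI=42, AD=21 ); K = 83 ROIs; M = 9 view(s):
#>    GMV, LGI, CNV, SLD, F-IDX, DoG-C, DoG-Z, M-IDX, DoG-M

pats <- compute_patterns(bench$table)
pats[["GMV"]]
#> <view_pattern> GMV - K = 83 ROIs; top: roi_15 (0.0474), roi_17 (0.0474), roi_5 (0.0474)

d <- divergence_matrix(pats)
attr(d, "n_pairs")
#> [1] 36
round(unclass(d)[1:4, 1:4], 2)
#>       GMV   LGI   CNV   SLD
#> GMV  0.00  9.01  4.76 21.82
#> LGI  8.18  0.00  7.69 18.85
#> CNV  3.89  8.27  0.00 24.17
#> SLD 16.99 20.49 18.38  0.00

emb <- spectral_embed(affinity_matrix(d), k = 2)
cluster_views(emb, n_clusters = 4, seed = 1)
# autoplot(emb, clustering = ...) draws the 2-D view map
```

The GMV pattern puts its largest weights on planted ROIs (the benchmark
plants ROIs 1–20 for the morphometry archetype). Within-archetype
divergences (GMV↔CNV ≈ 4–5) are an order of magnitude below cross-archetype
ones (GMV↔SLD ≈ 17–22), which is exactly the structure the spectral
clustering recovers. Staging one view or a pair:

```r
cfg <- crossview_config(staging = list(folds = 3, budget = 6, inner_folds = 2))
glance(cross_validate(bench$table, c("GMV", "M-IDX"), cfg, seed = 2))
#> # A tibble: 1 × 7
#>   views     accuracy precision_AD precision_MCI precision_NC sensitivity specificity
#>   <chr>        <dbl>        <dbl>         <dbl>        <dbl>       <dbl>       <dbl>
#> 1 GMV|M-IDX     68.1         96.3          62.5          100         100        8.33
```

Accuracy is the headline number; the high sensitivity / low specificity
split reflects the deliberately MCI-heavy cohort and the positive class
being MCI∪AD. `run_pair_benchmark()` repeats this for all 9 single views
and 36 pairs over replicate cohorts and feeds `correlate()` /
`best_pair_report()`.

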
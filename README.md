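# lymphopatch

Hierarchical patch-based classification of H&E-stained non-Hodgkin lymphoma
histopathology images into the three major subtypes — chronic lymphocytic
leukemia (CLL), follicular lymphoma (FL) and mantle cell lymphoma (MCL) —
for image-analysis researchers who want a fully inspectable, deterministic
reference pipeline rather than an opaque end-to-end network.

## The method

An RGB section is transformed into two complementary spaces: the
**blue-ratio** gray space

```
BR = 100 · B/(1 + R + G) · 256/(1 + B + R + G)
```

which enhances the hematoxylin (nuclear) signal, and **CIE Lab**, whose a/b
channels carry stain chroma. The image is tiled into non-overlapping
`s1 = 200` px parent patches; `s2 = 50` px subpatches slide inside each
parent with overlap ratio `r_o = 0.5` (49 subpatches per parent). Each
subpatch yields three descriptors:

| block  | content                                     | dims |
|--------|---------------------------------------------|------|
| `r_LBP`| uniform LBP histograms, radii 1 and 2, p = 8 | 118 |
| `r_sta`| gray-level statistics (max … IQR)            | 9   |
| `r_Lab`| 85-bin a/b color histograms                  | 170 |

Parent patches aggregate their subpatches dimension-wise (mean, sd, 10th,
90th percentile → 4n), giving 472/36/680 features, combined as
`F1 = {r_LBP, r_sta}` (508) and `F2 = F1 ∪ {r_Lab}` (1188). A seeded
probability random forest (200 trees) classifies parent patches; image-level
decisions come from majority voting (MV), mean score (MS), or
**distance-matrix weighting (DMW)**: with `d_ij` the Euclidean feature
distance between patches i and j,

```
da_k = (1/(m−1)) Σ_i d_ki      Sd_k = 1/da_k      w_k = Sd_k / Σ_i Sd_i
S_I  = Σ_k w_k · s_k
```

so patches typical of their image are up-weighted and outliers suppressed.
Score paths are fused at patch level (`w_P = 0.7`) and image level
(`w_I = 0.5`) in five combination modes C1–C5; C3 (F1 + F2 fusion, then
DMW) is the strongest handcrafted mode, and C4/C5 add a pluggable
deep-embedding path (a deterministic mock backend is bundled). A seeded
synthetic H&E-like image generator makes the whole pipeline testable with
no external data.

## Worked example

```r
library(lymphopatch)

## one synthetic MCL-like image, full handcrafted feature extraction
img <- generate_image("MCL", synth_config(), seed = 42)
fs  <- extract_image_features(img, lp_config())
nrow(fs$meta); ncol(fs$r_LBP); ncol(fs$r_sta); ncol(fs$r_Lab)
#> 9     472     36     680

## DMW weights over the image's 9 parent patches (F2 feature space)
round(dmw_weights(assemble_feature_set(fs, "F2")), 3)
#> [1] 0.108 0.113 0.114 0.111 0.107 0.113 0.112 0.109 0.113

## end-to-end benchmark: 10 train + 5 test images per class, mode C3
bench <- run_synthetic_benchmark(n_train_per_class = 10,
                                 n_test_per_class = 5,
                                 seed = 1, mode = "C3")
bench$image_accuracy   #> 0.933
bench$patch_accuracy   #> 0.933
bench$metrics$confusion
#>      pred
#> truth CLL FL MCL
#>   CLL   4  1   0
#>   FL    0  5   0
#>   MCL   0  0   5
round(bench$metrics$AUC, 3)
#> Overall     CLL      FL     MCL
#>       1       1       1       1
```

The 9 parent patches of a homogeneous synthetic image receive near-uniform
DMW weights (≈ 1/9 each) — exactly the intended behavior when no patch is
an outlier. On the 45-image benchmark, one CLL test image is called FL;
14/15 images are correct and the score ranking is perfect (AUC 1), while
patch-level accuracy shows what the image-level aggregation is built on
top of. Reruns with the same seed reproduce these numbers bit-for-bit.

A command-line front end with verbs `synth`, `extract`, `train`,
`predict`, `evaluate` and `run-all` is installed at
`system.file("cli", "lymphopatch.R", package = "lymphopatch")`, e.g.

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","lymphopatch.R",package="lymphopatch"))')" \
    run-all --out run1 --seed 1 --mode C3
```

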
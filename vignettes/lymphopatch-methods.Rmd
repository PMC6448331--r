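---
title: "Methods: hierarchical patch classification with distance-matrix weighting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hierarchical patch classification with distance-matrix weighting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Non-Hodgkin lymphoma subtyping from H&E-stained histology sections —
distinguishing chronic lymphocytic leukemia (CLL), follicular lymphoma (FL)
and mantle cell lymphoma (MCL) — is difficult because the three subtypes
differ in subtle textural and chromatic patterns rather than in gross
morphology. `lymphopatch` implements a hierarchical, patch-based
classification pipeline for this task: images are decomposed into local
windows, local windows are classified, and the local decisions are
aggregated back into a whole-image call with a weighting scheme that favors
patches typical of their image.

# The pipeline

## Image-space transforms

Two transforms amplify the two discriminative axes of H&E stains:

* **Blue ratio.** Hematoxylin stains nuclei blue-purple, so the transform
  $BR = 100\,\frac{B}{1+R+G}\cdot\frac{256}{1+B+R+G}$ enhances nuclear
  signal (first factor) and attenuates the bright pink background (second
  factor). Both denominators are at least 1, so $BR$ is finite and
  non-negative for every 8-bit pixel. Texture and intensity statistics are
  computed in this single-channel space.
* **CIE Lab.** Color features come from the a (green–red) and b
  (blue–yellow) channels of CIE Lab, which decorrelate chroma from
  lightness and are more robust to staining intensity differences than raw
  RGB. Channels are scaled to $[0,1]$, sRGB-gamma linearised, mapped
  through the linear D65 RGB→XYZ matrix, and converted with the standard
  piecewise cube-root $f(t)$ ($t > (6/29)^3$, linear continuation below)
  and reference white $X_n = 0.950456$, $Y_n = 1$, $Z_n = 1.088754$.

Two numerical choices here are the package's own, because the upstream
convention is not fixed: (1) the blue-ratio image is min–max rescaled *per
image* to integer $[0,255]$ (half-to-even rounding) before texture
extraction, making downstream features invariant to each image's raw BR
dynamic range; a constant image maps to zeros. (2) Gamma linearisation is
applied by default (standard colorimetry); `lab_gamma = FALSE` gives the
naive linear reading. We verified the Lab conversion against base R's
`grDevices::convertColor` — agreement is within 0.4 on all channels over
the 8-bit gamut, the residual coming from slightly different published D65
constants.

## Two-level patching

Parent patches of size $s_1 = 200$ px are tiled without overlap (incomplete
border windows are discarded so every patch has identical size); subpatches
of size $s_2 = 50$ px slide inside each parent with overlap ratio
$r_o = 0.5$, i.e. stride $\mathrm{round}(s_2(1-r_o)) = 25$, giving
$7\times7 = 49$ subpatches per parent. Coordinates are 0-based with
half-open windows. The two levels trade off locality (subpatch statistics)
against reliability (parent-level aggregation).

## Subpatch descriptors

* **`r_LBP`** — uniform local binary patterns. Each interior pixel is coded
  by thresholding $p = 8$ circularly sampled neighbors (radii 1 and 2,
  bilinear interpolation at non-integer positions) against the center;
  codes with at most two circular 0/1 transitions get one histogram bin
  each, all other codes share one pooled bin: $p(p-1)+3 = 59$ bins per
  radius, 118 per subpatch. Two conventions are deliberately pinned down:
  the threshold is `>=` (the dominant LBP convention — a constant patch
  produces the all-ones pattern; `lbp_strict_gt = TRUE` restores the
  literal "greater than" reading), and the comparison is applied to the
  bilinearly interpolated neighbor-minus-center *difference*, which makes
  exact ties exact in floating point. Histograms are normalised to sum to
  1 so the descriptor is patch-size invariant.
* **`r_sta`** — nine gray-level statistics in fixed order: max, min, sum,
  mean, standard deviation (population, $n$ divisor), median, Q1, Q3, IQR.
  Quantiles use linear interpolation between order statistics.
* **`r_Lab`** — 85-bin histograms of the a and b channels over
  $[-128, 127]$ (values clipped into range), each normalised, concatenated
  a-then-b: 170 dimensions.

## Parent aggregation

Each parent patch summarises its 49 subpatch vectors dimension-wise by
mean, population standard deviation, 10th and 90th percentile,
concatenated as four blocks: $4n$ dimensions, hence 472 / 36 / 680 per
parent for the three descriptors. Feature sets are
$F_1 = \{r_{LBP}, r_{sta}\}$ (508 dims) and
$F_2 = \{r_{LBP}, r_{sta}, r_{Lab}\}$ (1188 dims).

## Patch classification

A probability random forest (`ranger`, 200 trees by default, single thread,
seeded — predictions are bit-reproducible given the seed) is trained per
feature set on parent-patch rows, each patch inheriting its image's label.
Splits are stratified by class *at the image level*, so no image
contributes patches to both sides (patches of one section are highly
correlated; splitting at patch level would leak). The paper-style default
split is 7:3. Forest hyperparameters beyond the tree count stay at library
defaults and are recorded in the model handle.

## Patch-to-image aggregation

Three strategies turn $m$ patch score vectors $s_1,\dots,s_m$ into an
image decision:

* **MV** — majority vote over patch argmax labels, ties to the lowest
  class index (deterministic).
* **MS** — mean of the score vectors.
* **DMW** (distance-matrix weighting) — the package's centrepiece. From
  the patches' feature vectors, form the Euclidean distance matrix
  $M_d = (d_{ij})$; each patch's mean distance to the others is
  $da_k = \frac{1}{m-1}\sum_i d_{ki}$ (the zero diagonal included, the
  $m-1$ divisor as defined), its score is the reciprocal $Sd_k = 1/da_k$,
  and weights are $w_k = Sd_k / \sum_i Sd_i$. The image score is
  $S_I = \sum_k w_k s_k$. The premise: sections are sampled from lesions,
  so most patches carry the class signal; a patch far from the rest in
  feature space is atypical (fat, background, artefact) and is
  down-weighted.

DMW edge cases are defined, not left to chance: $m = 1$ gives weight 1;
all-identical patches give uniform weights (the symmetry-forced limit);
individual zero mean-distances are clamped to $10^{-12}\max(M_d)$ before
the reciprocal. Weights are permutation-equivariant and invariant to
positive rescaling of the feature space. By default feature dimensions are
z-scored across the image's patches before distances are taken, so blocks
on different scales (histogram bins vs. raw intensity sums) cannot
dominate; `dmw_standardize = FALSE` restores raw Euclidean distances. For
the worked three-patch example with colinear features at 0, 1, 3 the
weights are exactly $(15, 20, 12)/47$.

## Multi-path combination

Five modes combine the handcrafted paths and an optional deep-embedding
path: C1 = DMW over $F_1$; C2 = MS over $F_2$; C3 = patch-level score
fusion $w_P S^{(F_1)} + (1-w_P) S^{(F_2)}$ followed by DMW; C4 = DMW over
the deep path; C5 = image-level fusion $w_I S_{I3} + (1-w_I) S_{I4}$.
Defaults $w_P = 0.7$, $w_I = 0.5$.

Two genuinely open design points were resolved as follows. *Which features
drive DMW for the fused C3 path?* The fused scores live on no single
feature space; we use the $F_2$ features (the richer superset). A
consequence worth stating: C3 with $w_P = 1$ discards the $F_2$ *scores*
but still weights with $F_2$ *features*, so it coincides with C1 exactly
when the two paths' DMW feature spaces coincide — the endpoint tests
construct that case explicitly. *Standardise before distances?* Yes by
default, for the scale argument above; the flag restores the raw reading.

## Deep path

The deep path is a pluggable contract: a function mapping $s_3 \times s_3$
RGB patches (default $s_3 = 300$) to fixed-length embeddings (2048 by
convention, matching the pooled pre-logit width of Inception v3), plus a
softmax head. The bundled `mock` backend is a deterministic tanh random
projection of an 8×8 block-mean downsample — not a CNN, but order-faithful:
same patch → same vector, different patches → different vectors. It
exists so every C4/C5 code path, and the head training, runs offline and
deterministically. The head itself is multinomial logistic regression
trained by seeded mini-batch SGD on cross-entropy (learning rate 0.001,
batch 100 by default) — the analogue of fine-tuning only the final layer
of a pretrained network. Plugging a real CNN in means passing a function
as `backend`; nothing else changes.

## Metrics

Overall accuracy; per-class sensitivity, specificity, precision, recall
(= sensitivity) and F1 from the confusion matrix; one-vs-rest AUC per
class (midrank tie handling via `pROC`) and an overall AUC as the macro
(unweighted) mean — macro was chosen because the class design is balanced;
a micro variant is available behind `auc_average = "micro"`. A class
absent from the ground truth yields `NA` sensitivity (undefined, not 0); a
class never predicted yields precision 0 with a warning.

# The synthetic generator

`generate_image()` emulates the two axes the feature blocks are built for,
not histology per se: an eosin-pink background with Gaussian pixel noise
(sd 8), dark blue-purple elliptical "nuclei" placed by a Poisson process at
a class-specific density with a class-specific size range, and (for FL) a
clustering of ~80% of nuclei into follicle-like disks. Class parameters
(densities 10 / 6 / 16 nuclei per $10^4$ px for CLL / FL / MCL; radius
ranges 4–6 / 4–7 / 3–6 px; distinct background tints) were chosen once so
that (a) nuclear area coverage — and hence mean blue-ratio intensity — is
monotone in density across classes, (b) texture scale separates the
classes for `r_LBP`/`r_sta`, and (c) tint separates them for `r_Lab`, so
block-ablation comparisons are meaningful. All randomness flows through a
single per-image seed; generation restores the caller's RNG state.

What the generator does *not* emulate — and therefore what passing tests do
not show about real data: staining variability between labs and patients,
tissue architecture beyond follicle-like clustering, nuclear chromatin
texture, scanner optics, and patch-level label noise (every patch of a
synthetic image genuinely carries its class signal, which is exactly the
DMW premise; real sections can contain non-lesional patches). Results on
the synthetic benchmark validate the machinery, not clinical performance.

# Problem sizes and determinism

The shipped end-to-end benchmark uses 600×600 images, 10 training + 5 test
images per class, mode C3, and three seeds — sizes chosen so the whole
suite runs comfortably on one CPU while still exercising 9 parents × 49
subpatches per image and both forest paths. The full-scale microscope
format (1388×1040, 30 parents) runs through the identical code path.
Every stage is a pure function of (data, config, seed): the forests are
seeded and single-threaded, the SGD head samples batches from a seeded
stream, and the generator derives one seed per image, so reruns are
bit-identical.

# Known limitations

* The image-level split treats images as independent; real datasets with
  several sections per patient need a patient-level split, which the
  package does not manage for you.
* The blue-ratio rescale is per image; features are therefore invariant to
  global BR scale but also blind to absolute staining intensity.
* The bundled deep backend is a fidelity mock; C4/C5 results with it say
  nothing about what a pretrained CNN would add.
* Gist/LPQ comparison descriptors and rotation-invariant LBP variants are
  out of scope.
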
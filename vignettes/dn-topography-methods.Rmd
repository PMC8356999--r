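---
title: "Methods: mapping dentate-nucleus topography from diffusion MRI derivatives"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mapping dentate-nucleus topography}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dntopo)
```

## Scope and assumptions

`dntopo` operates downstream of image reconstruction: it assumes every
input — DN masks, per-target track-density images (TDI), and the seven
diffusion-metric maps — already lives on one common voxel grid. Grid
agreement is enforced (`check_same_grid()`, tolerance 1e-4 mm on affine
entries) rather than repaired: registration, tractography and model
fitting belong to upstream tools and are deliberately out of scope.

Two conventions hold everywhere:

* **Label 0 is background/unassigned.** Voxels with no streamline at all,
  or pruned by a support threshold, carry 0 and never enter a parcel's
  numerator; they do count in the DN-volume denominator, so reported
  fractions always add to 100% with the unassigned remainder.
* **Voxel indices are 1-based** (the natural R convention); world
  coordinates in mm come from the affine applied to the 0-based offset.
  Medial/lateral language refers to |world x|, so the input affine must
  place the mid-sagittal plane at x = 0 — a documented input contract.

## Connectivity-based parcellation

For DN voxel $v$ the membership vector is
$n(v) = (n_1(v), \dots, n_T(v))$, the raw streamline counts of each
target's TDI at $v$. Connection strength is the raw count — not density
normalized — and the winner-takes-all label is $\arg\max_t n_t(v)$.
Ties are broken to the lowest target index by default (deterministic and
order-stable); an alternative policy marks tied voxels unassigned. The
distribution connectivity maps $n_t(v)/\sum_t n_t(v)$ are the soft
counterpart used for inspection.

The retention filter keeps a target only if its total DN-masked
streamline count **strictly** exceeds `min_streamlines` and its won
volume **strictly** exceeds `min_volume_pct` (both "more than"
readings). The two operating points used throughout are
(10,000 streamlines, 15%) for the cerebellar system and (300, 40%) for
the thalamic system. Whether the filter should act on per-subject
summaries or on group means is genuinely open; both are exposed, and
`analysis/02_connectivity_parcellation.R` reports both.

Streamline totals are DN-masked TDI sums — consistent with how the
membership vectors are built — rather than whole-tract streamline counts;
the two differ when streamlines end outside the mask.

## Microstructure-based parcellation

Each DN voxel is a point in the 7-dimensional space (FA, MD, AD, RD, MK,
AK, RK), MD/AD/RD in $10^{-3}\,\mathrm{mm^2/s}$. Preprocessing:

1. **Max normalization**: each feature divided by its per-subject maximum
   (so each column peaks at exactly 1). This is scale equalization, not
   standardization — chosen for its robustness to near-constant features.
2. **IQR outlier replacement**: per column, values outside
   $[Q_1 - 1.5\,\mathrm{IQR},\; Q_3 + 1.5\,\mathrm{IQR}]$ are replaced by
   the column median. Quantiles use linear interpolation (R type 7), and
   the median is computed on the pre-replacement column; both choices are
   stated so the operation is exactly checkable, and the operation is
   idempotent. The default order is normalize → IQR; the reverse is
   available via the `order` flag of `microstructure_parcellation()`
   since the two readings are equally defensible.

Fuzzy c-means then minimizes
$J=\sum_i\sum_j u_{ij}^m \lVert x_i - c_j\rVert^2$ with the classical
alternating updates, $c = 3$ clusters and fuzziness $m = 2$.
Implementation choices, all tunable through `fuzzy_cmeans()`:

* convergence when $|\Delta J| < 10^{-6}$, at most 300 iterations;
* random row-stochastic membership initialization from a seed, with
  **5 restarts** keeping the lowest final $J$ — at ~900 voxels this makes
  the solution stable without noticeable cost;
* a point at (numerically) zero distance from a centroid receives all its
  membership there, split equally among coincident centroids;
* the objective trace is returned and is non-increasing by construction —
  the test suite asserts this on every run it makes.

Hardening takes the per-voxel argmax membership (ties to the lowest
cluster index). The 3-cluster solution is then reduced to two: the pair
of clusters with the **closest mean feature vectors** is merged (a single
agglomerative step). The original analysis used an unspecified
"bottom-up hierarchic" rule for this reduction; closest-centroid merging
is this package's own concrete choice, stated as such. Finally the
surviving cluster whose voxel centroid is nearer the mid-sagittal plane
is named *medial* (label 2), the other *lateral* (label 1).

## Group atlases, comparison, statistics

The modal atlas takes, per voxel, the most frequent nonzero label across
subjects; an unassigned voxel casts no vote, ties go to the lowest label,
and an optional `min_support` fraction prunes voxels won by too few
subjects (default 0, since no support threshold was used in the original
analysis — agreement there was inspected visually). Per-label probability
maps are subject fractions; wherever a voxel has a unique most-probable
label the modal atlas equals the argmax of those maps, a cross-operation
consistency the tests check exhaustively.

Atlas overlap uses the Dice similarity coefficient
$\mathrm{DSC} = 2|A \cap B| / (|A| + |B|)$ over all nonzero label pairs;
two empty parcels score 0 by convention (absence of both is not
agreement).

Cohort tests are two-sided at $\alpha = 0.05$ with no multiple-testing
correction (matching the original exploratory analysis; a caveat users
should keep in mind). The Wilcoxon signed-rank test (paired left/right
comparisons) and Mann-Whitney U test (two groups) compute **exact**
permutation p values for up to 25 informative observations — including
under ties, via integer convolution over doubled midranks — and fall
back to tie-corrected normal approximations beyond that; the Friedman
test uses the tie-corrected chi-square statistic of
`stats::friedman.test`. Data with no within-block variation at all carry
no rank information and are reported as a null result (statistic 0,
p = 1, with a warning) rather than an error.

## The synthetic cohort: what it emulates, and what it does not

`phantom_spec()` defaults encode the study conditions the pipeline
targets:

| parameter | default | rationale |
|---|---|---|
| grid | 48×24×24 @ 1.25 mm | acquisition voxel size; grid symmetric about x = 0 |
| DN semi-axes | 6 × 9 × 7.5 mm | ~890 voxels ≈ 1.7 ml per nucleus, realistic DN size |
| cerebellar fractions | 28.9, 39.5, 8.0, 3.0, 4.2, 16.4 % | reference cohort volume means |
| cerebellar counts | 18.9k, 38k, 9.2k, 2.7k, 2k, 11.8k | reference cohort streamline means |
| thalamic fractions / counts | 45.9 … 0.7 % / 330 … 1 | reference cohort means |
| band order | IX–X most medial … Crus I–II most lateral | observed medio-lateral layout |
| leakage | 0.1 | off-target count spill, keeps winner recovery well-posed |
| label noise | 0.2 | inter-subject variability as label flips |
| n_subjects | 25 (16 F / 9 M) | cohort size |
| micro split | 55% lateral / 45% medial | reference cluster volumes |
| micro means | FA 0.292/0.276, MD 0.753/0.820, MK 1.213/1.165, … | lateral ≈ Crus I–II profile, medial ≈ IX–X profile |
| micro SD | (mean separation)/3 per metric | planted 3-SD cluster separation |

Counts are Poisson (streamline counts are event counts): a voxel of true
parcel $p$ draws its on-target count from
$\mathrm{Pois}(\lambda_p (1-\ell))$ and each off-target count from
$\mathrm{Pois}(\lambda_p \ell/(T-1))$, with
$\lambda_p = \text{parcel count}/\text{parcel voxels}$. Metrics are
Gaussian truncated at zero. Subject variability is i.i.d. label noise;
left and right DN are exact mirrors. All randomness flows from one seed
and cohorts are bit-reproducible.

What this phantom deliberately does **not** reproduce — and hence what
passing tests do *not* show about real data:

* **Spatial structure of TDI.** Real streamline counts are spatially
  clustered; the phantom draws counts independently per voxel. At the
  cerebellar scale ($\lambda \ge 50$) this is immaterial, but at the
  thalamic scale (a few hundred streamlines spread over ~400 voxels,
  $\lambda < 1$) independent Poisson draws leave most voxels with zero
  counts, so on synthetic data no thalamic target clears the 40% volume
  bar even though the reference cohort means do. The thalamic worked
  example therefore runs on the reference means, and the recovery
  criteria address the cerebellar system.
* **Cluster overlap.** The planted 3-SD separation makes the
  microstructural clusters far cleaner than the heavily overlapping
  metric distributions of real DN tissue, where cluster recovery is
  necessarily partial and only two of three requested clusters emerge
  consistently.
* **Geometry.** Real DN are not ellipsoids, parcels are not planar
  bands, and inter-subject variability is anatomical, not label flips;
  registration error is absent by construction.

## Problem sizes and numerical conventions

The analysis drivers and verification runs use the full default phantom
(25 subjects × 2 hemispheres × ~890 DN voxels); unit tests use a smaller
ellipsoid (~260 voxels) for speed. Null calibration of the three tests
uses 2,000 simulated datasets each at the cohort's own sample sizes
(paired n = 25; groups 16 vs 9; blocks 25 × 6). Band construction orders
DN voxels by |world x| with lexicographic tie-breaks, then cuts at
rounded cumulative targets, so every planted fraction is honoured to
within one voxel per band boundary and mirrored hemispheres split
identically. Degenerate inputs fail loudly: ellipsoids under two voxels
per semi-axis, all-zero feature columns, fewer than two nonempty
clusters, unknown mask labels, grid or label-dictionary mismatches.
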
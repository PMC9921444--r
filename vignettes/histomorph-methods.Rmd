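---
title: "Nuclear morphometry, deep clustering, and cluster-specific genes: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nuclear morphometry, deep clustering, and cluster-specific genes: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

histomorph implements a joint analysis of H&E-stained tissue images and bulk
RNA abundance for cohorts of non-diseased tissue samples. One sample
contributes a whole-slide image and a TPM expression column; the pipeline
(i) isolates the glandular compartment at low resolution, (ii) segments
individual nuclei inside it at full resolution, (iii) condenses each sample
into a 65-feature nuclear morphometry profile, (iv) stratifies the cohort by
an iterative MLP + k-means deep-clustering scheme, and (v) screens every
gene for cluster-specific over-expression with a quasi-Poisson
dual-statistic test under two FDR gates. This vignette records the models,
the tunable parameters and the design decisions; it states no empirical
number that the package's tests and acceptance script do not themselves
compute.

## Glandular tissue segmentation

Breast tissue sections contain three morphologically distinct compartments
-- glandular (epithelial), connective and adipose -- plus slide background.
Nuclei differ systematically between compartments (adipose nuclei are small
and elongated, for instance), so pooling them would let tissue composition
mask the between-individual variation of interest. Only glandular nuclei
are analyzed.

Segmentation runs on a low-resolution rendering (nominally 16 um/pixel,
where individual nuclei are unresolvable). Every pixel is described by
three robust statistics -- median, inter-quartile range, and median
absolute deviation -- of each RGB channel over a local window, giving a
9-dimensional feature vector $f(x) = (f_R, f_G, f_B) \in \mathbb{R}^9$ with
$f_R = (\mathrm{Med}, \mathrm{IQR}, \mathrm{MAD})$. The median carries the
compartment's color, IQR/MAD carry its texture (fibrous connective tissue
has high local spread, adipose almost none). Choices that the window
statistics need but that have no canonical value:

* **Window radius**: default 2 (a 5x5 window). At the analysis scale this
  captures local texture without smearing thin connective strands.
  Configurable (`window_radius`).
* **Quartile convention**: linear interpolation between order statistics
  (the common "type 7" rule); a convention must be fixed for
  reproducibility.
* **Standardization**: features are z-scored per dimension before k-means;
  otherwise the medians (0-255) dominate the spread statistics.

The standardized features go to k-means (k-means++ seeding, 10 restarts,
Lloyd iterations; `tissue_k = 4` by default). Cluster identities are
arbitrary, so the glandular cluster is recognized by comparing centroids
(reported in the original feature space) against a reference centroid taken
from one verified standard image; the closest centroid wins, ties break to
the lowest label with a warning. The shipped reference
(`inst/extdata/glandular_reference.json`) is computed from a synthetic
standard tile whose glandular region is known exactly -- the synthetic
counterpart of a pathologist-verified image -- and can be regenerated with
`makeGlandularReference()` or replaced by the user. The resulting binary
mask is upsampled to full resolution by nearest neighbor.

## Nucleus segmentation

Full-resolution images are cropped into non-overlapping tiles (default
4096 px; tiles without glandular pixels are skipped), and each tile passes
through:

1. **Normalization.** Histogram equalization of the L channel of CIELAB
   (256-bin cumulative mapping, rank-preserving); a and b are untouched.
   This removes brightness variation between slides without altering hue.
2. **Stain unmixing.** Per-pixel optical density
   $OD_c = -\log_{10}(\max(I_c, 1)/255)$ is solved against the standard
   H&E absorption matrix (hematoxylin $\approx (0.65, 0.70, 0.29)$, eosin
   $\approx (0.07, 0.99, 0.11)$, unit-normalized, plus their residual
   vector); negative concentrations clip to zero. The $\max(I, 1)$ floor
   (rather than adding a constant to every intensity) keeps the transform
   exact for bright pixels; with an additive offset the darkest nuclei
   would carry a systematic concentration bias of more than one percent.
   The matrix is user-overridable for other stain batches.
3. **Initialization.** Otsu's threshold (between-class variance
   maximization over 256 bins) on the hematoxylin channel restricted to
   glandular pixels, scaled by `otsuRatio` (default 1 -- the plain Otsu
   partition); components under `minArea` = 10 px are specks and removed.
4. **Refinement.** Chan-Vese level-set evolution: the signed distance to
   the initial mask evolves under inside/outside mean data terms plus a
   curvature term weighted by `mu` (default 0.2 with the channel
   normalized to [0, 1], making the weight scale-free). The time step is
   capped at $1/(4\mu)$ so the explicit scheme stays stable for any
   curvature weight. Evolution stops at `maxIters` = 100 or when the
   segmented area changes by less than `tol` = 1e-3 (relative) over five
   iterations. Collapse (below 10% of the initial area) or flooding
   (99% of the frame) falls back to the initial mask with a warning.
5. **Declumping.** Connected components flagged as clumps -- area above
   1.5x the tile's median component area, or convex solidity below 0.9 --
   are split by mean-shift over their pixel coordinates: flat kernel of
   radius `bandwidth` (default $\sqrt{\text{median area}/\pi}$, about one
   nucleus radius), every pixel a seed, convergence at 0.1 px, modes
   closer than 0.7x bandwidth merged. A consolidation pass then removes
   the plateau artifacts a flat kernel can leave on heavily overlapping
   pairs: while the mode count exceeds the area-implied multiplicity
   $\lceil \text{area}/(\pi\,\text{bandwidth}^2) \rceil$ *and* the two
   closest modes are within 1.1x bandwidth, they merge with basin-size
   weights. The clump trigger is deliberately sensitive: mean-shift
   returns a single mode on a convex single nucleus, so a false trigger
   costs compute and nothing else, whereas a missed trigger permanently
   merges two nuclei.

Nuclei whose centroid falls outside the glandular mask are discarded;
records carry global coordinates through the tile origin, so the pipeline
is translation-equivariant and deterministic (no randomness anywhere in
segmentation).

## Morphometry: the 65-feature profile

The feature catalog is frozen (names and order) in a versioned JSON schema
(`inst/extdata/feature_catalog.json`), since only its total size -- 65 --
is fixed by the design the package follows; the composition is the
package's own canonical choice:

* 12 per-nucleus features -- area, perimeter (Vossepoel-Smeulders-corrected
  chain length), equivalent diameter, elongation (major/minor axis ratio
  from second central moments, with the 1/12-per-pixel term so a discrete
  w x h rectangle reports exactly w/h), eccentricity, roundness
  $4\pi A/P^2$, convex solidity (hull taken over pixel corners so solidity
  never exceeds 1), and five hematoxylin intensity statistics -- each
  aggregated over nuclei by mean, sample standard deviation (n-1), and
  median: 36 features.
* 4 spatial-arrangement families over the nucleus centroids -- bounded
  Voronoi cell areas (frontier cells are excluded rather than clipped, to
  avoid frame-size artifacts), Delaunay edge lengths, the edge lengths of
  the Euclidean minimum spanning tree built on the Delaunay graph, and
  neighbor counts strictly within `neighbor_radius` (default 50 px at full
  resolution) -- each summarized by mean, sd, median, min, max, and
  disorder (sd/mean): 24 features.
* nucleus density (count / glandular-mask area) and 4 boundary-robust
  extras: the bounded-Voronoi cell fraction, the MST total length, the
  Delaunay mean degree, and the mean nearest-neighbor distance: 5
  features.

Samples with fewer than 3 nuclei receive NA sentinels for the spatial
block (logged); profiles are permutation-invariant in the nucleus list.

## Deep clustering

Profiles are z-scored per feature to mean 0, sd 1. The z-score uses the
population standard deviation (divide by n) so the normalization targets
are met exactly; constant features map to zeros with a warning. The
clustering loop then alternates, for `outer_iters` = 50 iterations:

1. k-means (k-means++, 10 restarts) on the current representation --
   initially the z-scored input -- yields pseudo-labels, aligned to the
   previous iteration's labels by Hungarian assignment on the contingency
   table (k-means labels are arbitrary; alignment stabilizes the training
   target);
2. a 3-hidden-layer ReLU MLP (100, 100, 50 units) with a linear softmax
   head is trained on (features, pseudo-labels) by full-batch Adam
   (learning rate 1e-3) for `epochs` = 500 epochs under cross-entropy;
3. the representation becomes the z-scored activations of the 50-unit
   layer; the classifier head is discarded.

Final labels are the last k-means result. Weights warm-start across outer
iterations while optimizer moments reset -- re-initializing the network
each iteration would discard the learned representation, while keeping
stale Adam moments couples iterations through the optimizer; both choices
are configurable in source. Full-batch training is appropriate at cohort
scale (hundreds of samples). All randomness (k-means seeding, weight
initialization) flows from the single `seed`.

Model selection scans k = 1..14, computing the within-cluster SSE, and
selects the k with the maximum discrete second difference of the curve --
an automated reading of the visual elbow. The curve is always returned for
manual override (`--k` on the CLI), and a curvature peak below 12% of the
total SSE drop flags the selection as low-confidence: on an unstructured
single Gaussian the measured peak ratio stays well below this mark while
planted-subtype cohorts sit several-fold above it.

## Cluster-specific genes

Genes are first filtered: a gene is kept when the proportion of samples
with TPM > 0 strictly exceeds `min_expr_prop` = 0.10. Statistics are
computed on the TPM scale directly, matching a quasi-Poisson
(variance $= \phi \times$ mean) model of count-derived abundance;
logarithms are for display only.

For each gene, the dispersion is estimated from the k-cluster fit as
$\hat\phi = \max(1, X^2/(n-k))$ with $X^2$ the Pearson statistic against
the cluster means; flooring at 1 treats under-dispersion as Poisson and
keeps the tests conservative. For each gene and target cluster $t$:

* **Over-expression (T1).** A quasi-Poisson Wald contrast of the target
  mean against the complement mean,
  $T_1 = (\hat\mu_t - \hat\mu_r) / \sqrt{\hat\phi(\hat\mu_t/n_t +
  \hat\mu_r/n_r)}$, with one-sided (upper-tail) normal p-value $p_1$:
  only over-expression counts.
* **Homogeneity of the rest (T2).** On the samples outside $t$, the scaled
  Poisson deviance difference between the one-common-mean fit and the
  per-cluster-means fit, $T_2 = (D_0 - D_1)/\hat\phi$, referred to
  $\chi^2_{k-2}$ (upper tail, $p_2$). Small $T_2$ means the remaining
  clusters are statistically indistinguishable. $T_2$ requires $k \ge 3$.

Benjamini-Hochberg adjustment is applied per cluster, separately to the
$p_1$ family and the $p_2$ family across genes. A (gene, cluster) pair is
*selected* iff $q_1 < 0.01$ and $q_2 > 0.1$: significantly up in exactly
that cluster, with no detectable structure among the rest. This dual gate
is what distinguishes the screen from one-vs-rest differential expression,
which cannot prevent a gene elevated in two clusters from passing both
contrasts. A gene passing in several clusters is kept only where its $p_1$
is smallest (logged); within each cluster, selected genes are ranked by
ascending $p_1$ -- the implementation reads "ranked by the over-expression
statistic" as p-value order, which respects the per-gene dispersions. The
BH family structure (per cluster, across genes) and the one-sided
convention are the package's documented choices among the alternatives the
underlying description leaves open; both statistics, $\hat\phi$, and all
p/q-values are exposed so alternates can be swapped in.

## Synthetic data: what it emulates, and what it does not

All stages are testable without any external download through three
ground-truthed generators (deterministic under a fixed seed):

* `generateTile()` renders H&E-like tiles through the Beer-Lambert forward
  model with the standard stain vectors, so unmixing is exercised against
  known concentrations. Four tissue regions carry distinct color/texture
  statistics: near-white background, bright low-texture adipose, pink
  connective with fibrous stripes (wavelength ~7.5 px, below the robust
  statistics window so the texture reads as spread rather than splitting
  clusters on stripe phase), and glandular stroma holding elliptical
  nuclei with per-nucleus hematoxylin intensities and per-pixel OD noise.
  A `clumpFraction` of nuclei is planted overlapping a partner at center
  distance 0.8-0.98x the sum of semi-minor axes -- a dumbbell pair the
  declumping stage must split. Defaults (512 px, 50 nuclei, 30% clumped)
  are the package's standard test condition.
* `generateExpression()` draws negative-binomial counts with variance
  $= \phi \times$ mean (the quasi-Poisson-compatible parameterization;
  $\phi = 1$ collapses to Poisson), plants `nSpecificPerCluster` = 50
  genes per cluster whose mean is multiplied by `foldChange` = 4 in
  exactly one cluster, includes a fraction of near-silent genes so the
  expression filter has work to do, and rescales columns to a constant sum
  of $10^6$ (equal gene lengths, so TPM conversion is pure column
  scaling). Defaults: 160 samples in 4 clusters, 2000 genes, $\phi = 2$.
* `generateFeatureCohort()` draws 65-dimensional Gaussian clusters (unit
  within-cluster sd) whose centroids sit `separation` = 8 sd apart along
  random orthonormal directions. Spreading the signal over all features
  matters: concentrated on a few axes it would be crushed by the
  per-feature z-score that the clustering stage rightly applies.

What the generators do **not** emulate -- and hence what green tests do not
establish about real slides: out-of-focus regions, stain batch variation
beyond global brightness, tissue folds and pen marks, non-elliptical and
textured chromatin, nuclei split across tile borders at scale, and any
correlation between morphology and expression beyond the planted cluster
structure. The numbers the acceptance checks produce are statements about
the pipeline's correctness under its stated model, not about biological
truth.

## Numerical choices and problem sizes

Tie-breaks and degenerate inputs are fixed throughout: Otsu ties resolve
to the first maximizing bin; glandular-reference ties to the lowest label
id (with a warning); both-empty masks score Dice = IoU = 1 (logged);
average Hausdorff is undefined (an error) on empty masks; two-point
spatial summaries return NA sentinels; an all-zero gene gets $\phi = 1$,
$T_1 = 0$, $p_1 = 0.5$, $T_2 = 0$, $p_2 = 1$.

The test suite and the acceptance script run at deliberately desk-scale
sizes chosen to estimate each quantity stably: 512-pixel tiles with 50
nuclei for segmentation recovery; 200-sample, 65-feature cohorts with the
deep-clustering configuration scaled to 50 epochs x 5 outer iterations
(the full 500 x 50 default changes runtime, not the recovered partition,
on separable cohorts); 2000 null genes for type-I error and null-KS
calibration, with the homogeneity null simulated at the 456-sample cohort
scale where the dispersion floor is numerically immaterial; and 2000-gene
matrices with 50 planted genes per cluster for precision/recall.

## Known limitations

* The level-set refinement is global per tile (one inside/outside mean
  pair); strongly varying stroma within a tile would benefit from local
  Chan-Vese variants.
* The area-implied multiplicity cap in declumping assumes nuclei of
  broadly comparable size within a tile; a bimodal size distribution
  would bias the cap.
* The elbow rule reports a single k; cohorts with hierarchical structure
  can show several curvature peaks, which is why the curve and the
  low-confidence flag are always returned.
* T1/T2 assume the quasi-Poisson mean-variance law on TPM values; heavy
  zero inflation beyond the expression filter, or strong library-size
  artifacts surviving TPM normalization, would mis-calibrate both tests.
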
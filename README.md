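# histomorph

Joint nuclear-morphometry and expression stratification for H&E tissue
cohorts.

Non-diseased tissue varies between individuals, and part of that variation
is visible in the nuclei of histology sections. **histomorph** asks which
genes track that visible variation: it segments glandular tissue and
individual nuclei from H&E-stained images, condenses each sample into a
65-feature nuclear morphometry profile, stratifies the cohort into
morphology clusters, and screens the transcriptome for genes over-expressed
in exactly one cluster. It is written for computational biologists working
with paired image + bulk RNA cohorts (GTEx-style: whole-slide images and
TPM matrices in GCT `#1.2` format), and every stage is testable offline
through ground-truthed synthetic generators.

## The method

* **Tissue segmentation.** Each low-resolution pixel is described by
  robust color statistics per channel, f(x) = (Med, IQR, MAD) for R, G, B
  (a 9-vector), clustered by k-means (k = 4: background, adipose,
  connective, glandular). The glandular cluster is identified by centroid
  distance to a reference from a verified standard image.
* **Nucleus segmentation.** Per 4096-px tile: CIELAB-L histogram
  equalization; H&E stain unmixing via Beer-Lambert optical density
  against the standard absorption vectors; Otsu initialization on the
  hematoxylin channel (ratio 1); Chan-Vese level-set refinement;
  mean-shift declumping of touching nuclei.
* **Morphometry.** 12 per-nucleus size/shape/intensity features x
  {mean, sd, median} + Voronoi / Delaunay / MST / neighbor-count spatial
  statistics + density terms = 65 features per sample (frozen catalog).
* **Deep clustering.** Iterated pseudo-labeling: k-means labels train a
  (100, 100, 50) ReLU MLP by Adam under cross-entropy; the 50-unit
  representation re-feeds k-means; 50 iterations, k chosen at the SSE
  elbow (maximum second difference over k = 1..14).
* **Cluster-specific genes.** After filtering (TPM > 0 in more than 10% of
  samples), for every gene and cluster t: a quasi-Poisson Wald contrast
  T1 = (mu_t - mu_rest) / sqrt(phi (mu_t/n_t + mu_rest/n_rest)) tests
  over-expression (one-sided), and a scaled deviance chi-square T2 on the
  remaining clusters tests their homogeneity (k - 2 df). Benjamini-
  Hochberg per cluster; selected iff q1 < 0.01 **and** q2 > 0.1 -- up in
  one cluster, flat among the rest.

## Worked example

Segment a synthetic tile and build its 65-feature profile:

```r
library(histomorph)

tile    <- generateTile(seed = 1)              # 512 px, 50 nuclei, 30% clumped
mask    <- tileTissueMap(tile) == 3L           # glandular truth mask
profile <- sampleProfile(tileRGB(tile), mask,
                         sampleId = "GTEX-demo", tileSize = 512L)
#> [histomorph] segment_nuclei: tile=1 nuclei=47
round(profile[1, c("area_mean", "roundness_mean",
                   "nn_distance_mean", "nucleus_density")], 4)
#>        area_mean   roundness_mean nn_distance_mean  nucleus_density
#>          93.0851           0.9902          16.1747           0.0007
```

47 of the 50 planted nuclei are recovered; the mean nucleus covers ~93 px,
is nearly round (roundness 0.99), sits ~16 px from its nearest neighbor,
and nuclei cover the glandular mask at ~7 per 10^4 px.

Cluster a cohort and find cluster-specific genes:

```r
co <- generateFeatureCohort(seed = 2)          # 200 samples, 4 planted subtypes
eb <- elbowSelect(zscoreMatrix(co$features), 1:14, seed = 2)
eb
#> ElbowResult: k = 1..14 -> selected k = 4
dc <- deepCluster(co$features, k = selectedK(eb),
                  epochs = 50, outerIters = 5, seed = 2)
table(cluster = clusterLabels(dc), truth = co$true_labels)
#>        truth
#> cluster  1  2  3  4
#>       1  0  0 50  0
#>       2  0  0  0 50
#>       3 50  0  0  0
#>       4  0 50  0  0

ge  <- generateExpression(seed = 3)            # 2000 genes, 50 planted/cluster
fl  <- filterGenes(ge$matrix, 0.10)
res <- selectSpecificGenes(fl$matrix, ge$true_labels)
sum(res$selected)
#> [1] 200
head(subset(res, selected & cluster == 2), 3)
#>        gene_id       T1 p1 q1       T2        q2 rank
#>      GENE00037 66.47663  0  0 3.287731 0.6556362    1
#>      GENE00153 42.38143  0  0 8.583679 0.1353724    2
#>      GENE00230 41.57406  0  0 7.361592 0.2251372    3
```

The elbow picks the planted k = 4, the cluster table is a permutation
matrix (perfect recovery), and the screen selects 200 genes -- the 4 x 50
planted ones: large positive T1 with q1 below the 0.01 gate, small T2 with
q2 above the 0.1 gate.

A thin CLI wraps the same functions
(`inst/cli/histomorph <subcommand> --help`): `simulate`, `segment-tissue`,
`segment-nuclei`, `extract-features`, `cluster`, `elbow`, `find-genes`,
`evaluate`.

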
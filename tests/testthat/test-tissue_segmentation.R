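test_that("per-pixel robust statistics follow the Med/IQR/MAD definitions", {
  # constant image: every pixel maps to (c, 0, 0) per channel
  img <- array(0L, dim = c(8, 8, 3))
  img[, , 1] <- 37L; img[, , 2] <- 120L; img[, , 3] <- 200L
  f <- computePixelFeatures(img, 2L)
  expect_equal(dim(f), c(8L, 8L, 9L))
  expect_true(all(f[, , "R_med"] == 37))
  expect_true(all(f[, , c("R_iqr", "R_mad")] == 0))
  expect_true(all(f[, , "G_med"] == 120))
  expect_true(all(f[, , "B_mad"] == 0))

  # 3x3 window holding 1..9: Med 5, IQR 4 (type-7 quartiles), MAD 2
  img2 <- array(128L, dim = c(3, 3, 3))
  img2[, , 1] <- matrix(1:9, 3, 3)
  f2 <- computePixelFeatures(img2, 1L)
  expect_equal(unname(f2[2, 2, "R_med"]), 5)
  expect_equal(unname(f2[2, 2, "R_iqr"]),
               unname(diff(quantile(1:9, c(0.25, 0.75), type = 7))))
  expect_equal(unname(f2[2, 2, "R_mad"]), 2)

  expect_error(computePixelFeatures(matrix(1, 4, 4)), "3-channel")
})

test_that("robust features are permutation-invariant and affine-equivariant", {
  set.seed(21)
  for (rep in 1:5) {
    vals <- sample(0:255, 25, replace = TRUE)
    mk <- function(v) {
      img <- array(0L, dim = c(5, 5, 3))
      img[, , 1] <- matrix(v, 5, 5); img
    }
    f1 <- computePixelFeatures(mk(vals), 2L)[3, 3, 1:3]
    f2 <- computePixelFeatures(mk(sample(vals)), 2L)[3, 3, 1:3]
    expect_equal(f1, f2)
    aff <- computePixelFeatures(mk(2L * vals + 5L), 2L)[3, 3, 1:3]
    expect_equal(aff[["R_med"]], 2 * f1[["R_med"]] + 5)
    expect_equal(aff[["R_iqr"]], 2 * f1[["R_iqr"]])
    expect_equal(aff[["R_mad"]], 2 * f1[["R_mad"]])
  }
})

test_that("tissue k-means recovers well-separated feature regions", {
  # four regions with distinct constant 9-dim features (plus tiny jitter so
  # k-means sees full-rank data); the label map must equal the region map
  # up to label permutation
  set.seed(22)
  region <- matrix(1L, 32, 32)
  region[1:16, 17:32] <- 2L; region[17:32, 1:16] <- 3L
  region[17:32, 17:32] <- 4L
  proto <- matrix(stats::runif(4 * 9, 0, 255), 4, 9)
  f <- array(0, dim = c(32, 32, 9))
  for (j in 1:9)
    f[, , j] <- matrix(proto[region, j], 32, 32) +
      matrix(stats::rnorm(32 * 32, 0, 0.5), 32, 32)
  dimnames(f) <- dimnames(computePixelFeatures(array(1L, dim = c(2, 2, 3)),
                                               1L))
  tm <- clusterTissue(f, 4L, seed = 3)
  expect_equal(ari(as.vector(tissueLabels(tm)), as.vector(region)), 1)

  # tissue_k = 1: one label, centroid = mean feature
  tm1 <- clusterTissue(f, 1L, seed = 3)
  expect_true(all(tissueLabels(tm1) == 0L))
  expect_equal(as.numeric(tissueCentroids(tm1)),
               colMeans(matrix(f, 32 * 32, 9)), tolerance = 1e-9)

  expect_error(clusterTissue(computePixelFeatures(
    array(7L, dim = c(4, 4, 3)), 1L), 4L), "degeneracy")
})

test_that("glandular matching picks the closest centroid with a stated tie rule", {
  mkMap <- function(centroids)
    methods::new("TissueLabelMap",
                 labels = matrix(0L, 2, 2), centroids = centroids,
                 scale = 16)
  ref <- rep(0, 9)
  # centroids at distances 3, 1, 2, 5
  cen <- rbind(c(3, rep(0, 8)), c(1, rep(0, 8)), c(0, 2, rep(0, 7)),
               c(5, rep(0, 8)))
  expect_equal(matchGlandular(mkMap(cen), ref), 1L)
  # exact match
  cen2 <- rbind(c(2, rep(0, 8)), rep(0, 9))
  expect_equal(matchGlandular(mkMap(cen2), ref), 1L)
  # tie: lower label id wins, with a warning
  cen3 <- rbind(c(1, rep(0, 8)), c(-1, rep(0, 8)))
  expect_warning(hit <- matchGlandular(mkMap(cen3), ref), "tie")
  expect_equal(hit, 0L)
})

test_that("mask upsampling is nearest-neighbor and round-trips block-aligned shapes", {
  m <- matrix(c(1L, 0L, 0L, 0L), 2, 2)
  up <- upsampleMask(m, c(4L, 4L))
  expect_equal(up[1:2, 1:2], matrix(1L, 2, 2))
  expect_equal(sum(up), 4L)

  ones <- matrix(1L, 3, 3)
  expect_true(all(upsampleMask(ones, c(9L, 12L)) == 1L))

  set.seed(13)
  m2 <- matrix(sample(0:1, 16, replace = TRUE), 4, 4)
  up2 <- upsampleMask(m2, c(12L, 12L))
  expect_identical(histomorph:::downsampleMaskMajority(up2, c(4L, 4L)), m2)

  expect_error(upsampleMask(matrix(1, 4, 4), c(2L, 2L)), "parameter")
})

test_that("glandular mask recovery on generated tiles reaches Dice 0.9", {
  tile <- generateTile(size = 256, nNuclei = 0, seed = 23)
  f <- computePixelFeatures(tileRGB(tile), 2L)
  tm <- clusterTissue(f, 4L, seed = 2)
  gid <- matchGlandular(tm, glandularReference())
  d <- diceCoefficient(tissueLabels(tm) == gid, tileTissueMap(tile) == 3L)
  expect_gte(d, 0.9)
})
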
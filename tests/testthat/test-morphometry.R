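maskFeatures <- function(mask, intensity = NULL) {
  px <- which(mask, arr.ind = TRUE)
  oc <- EBImage::ocontour(EBImage::Image(mask * 1))[[1]] + 1L
  computeNucleusFeatures(px, oc, intensity, dim(mask))
}

test_that("per-nucleus geometry matches analytic shapes", {
  disk <- diskMask(40, 40, 20, 20, 10)
  f <- maskFeatures(disk)
  expect_equal(unname(f["area"]), 100 * pi, tolerance = 0.03)
  expect_lt(f["eccentricity"], 0.1)
  expect_gt(f["roundness"], 0.9)
  expect_lte(f["roundness"], 1 + 1e-6)
  expect_gt(f["solidity"], 0.9)

  # 10 x 2 axis-aligned rectangle: elongation 5 from second moments
  rect <- matrix(FALSE, 20, 20)
  rect[6:7, 5:14] <- TRUE
  fr <- maskFeatures(rect)
  expect_equal(unname(fr["elongation"]), 5, tolerance = 0.05)
  expect_equal(unname(fr["area"]), 20)

  # constant intensity under the mask
  I <- matrix(0.7, 40, 40)
  fi <- maskFeatures(disk, I)
  expect_equal(unname(fi["intensity_sd"]), 0)
  expect_equal(unname(fi["intensity_mean"]), 0.7)
  expect_equal(unname(fi["intensity_median"]), 0.7)
})

test_that("geometry is invariant under translation and 90-degree rotation", {
  set.seed(41)
  base <- diskMask(30, 30, 14, 13, 6) | diskMask(30, 30, 17, 17, 5)
  shifted <- matrix(FALSE, 30, 30)
  shifted[6:30, 4:28] <- base[1:25, 1:25]
  rotated <- t(base)[, rev(seq_len(30))] > 0
  geomCols <- c("area", "perimeter", "equivalent_diameter", "elongation",
                "eccentricity", "roundness", "solidity")
  f0 <- maskFeatures(base)[geomCols]
  expect_equal(maskFeatures(shifted)[geomCols], f0, tolerance = 1e-9)
  expect_equal(maskFeatures(rotated)[geomCols], f0, tolerance = 1e-6)
})

test_that("spatial statistics match brute-force graph oracles", {
  # near-collinear 3 points: MST edges ~ {1, 2}
  pts <- rbind(c(0, 0), c(0, 1), c(0.01, 3))
  s <- computeSpatialSummary(pts, radius = 1.5)
  expect_equal(sort(s$mst_edge_length), c(1, 2), tolerance = 0.01)
  expect_equal(mean(s$mst_edge_length), 1.5, tolerance = 0.01)

  # equilateral triangle side 1, radius 1.5: every neighbor count is 2
  eq <- rbind(c(0, 0), c(1, 0), c(0.5, sqrt(3) / 2))
  se <- computeSpatialSummary(eq, radius = 1.5)
  expect_equal(unname(se$neighbor_count), c(2, 2, 2))

  # unit 5x5 grid: interior Voronoi cells all have area 1
  grid <- as.matrix(expand.grid(1:5, 1:5))
  sg <- computeSpatialSummary(grid, radius = 1.1)
  expect_equal(length(sg$voronoi_cell_area), 9L)  # 3x3 interior
  expect_equal(unname(sg$voronoi_cell_area), rep(1, 9), tolerance = 1e-9)

  # MST on the Delaunay graph equals the exhaustive minimum (n <= 7)
  set.seed(42)
  for (rep in 1:5) {
    n <- sample(5:7, 1)
    p <- matrix(stats::runif(2 * n, 0, 10), n)
    sm <- computeSpatialSummary(p, radius = 3)
    expect_equal(sm$mst_total_length, bruteMSTWeight(p), tolerance = 1e-9)
  }

  # fewer than 3 points: documented NA sentinels
  s2 <- computeSpatialSummary(rbind(c(0, 0), c(1, 1)), radius = 1)
  expect_true(is.na(s2$voronoi_cell_area))
  expect_true(is.na(s2$mst_total_length))
})

test_that("profile aggregation follows the frozen 65-feature catalog", {
  set.seed(43)
  pts <- as.matrix(expand.grid(seq(5, 45, by = 10), seq(5, 45, by = 10)))
  sp <- computeSpatialSummary(pts, radius = 15)
  fm <- matrix(stats::rnorm(25 * 12, mean = 10), 25, 12,
               dimnames = list(NULL, histomorph:::perNucleusFeatureNames()))
  prof <- aggregateProfile(fm, sp, "s1", glandularArea = 2500)
  expect_equal(ncol(prof), 65L)
  expect_equal(colnames(prof), featureCatalog())
  expect_true(all(is.finite(prof)))
  expect_equal(unname(prof[1, "nucleus_density"]), 25 / 2500)

  # permutation invariance over the nucleus list
  prof2 <- aggregateProfile(fm[sample(25), ], sp, "s1",
                            glandularArea = 2500)
  expect_equal(prof2, prof)

  # two nuclei with areas 100 and 300 under the sample-sd convention
  fm2 <- fm[1:2, ]; fm2[, "area"] <- c(100, 300)
  p2 <- aggregateProfile(fm2, sp, "s2", glandularArea = 2500)
  expect_equal(unname(p2[1, "area_mean"]), 200)
  expect_equal(unname(p2[1, "area_median"]), 200)
  expect_equal(unname(p2[1, "area_sd"]), 141.42, tolerance = 1e-4)

  # single nucleus: all sd aggregates collapse to 0
  p1 <- aggregateProfile(fm[1, , drop = FALSE], sp, "s3",
                         glandularArea = 2500)
  expect_equal(unname(p1[1, "area_sd"]), 0)
  expect_equal(unname(p1[1, "area_mean"]), unname(p1[1, "area_median"]))

  expect_error(aggregateProfile(fm[0, , drop = FALSE], sp, "s4", 1),
               "segmentation")
})
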
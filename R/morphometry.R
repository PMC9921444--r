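#' The frozen 65-feature morphometry catalog
#'
#' Returns the versioned, ordered list of the 65 per-sample feature names:
#' 12 per-nucleus features (size, shape, stain intensity) each aggregated
#' over nuclei by mean/sd/median (36), four spatial-arrangement families
#' (Voronoi cell area, Delaunay edge length, MST edge length, neighbor count
#' within a radius) each summarized by mean/sd/median/min/max/disorder (24),
#' nucleus density, and four boundary-robust extras. The catalog is stored as
#' a versioned JSON schema under `inst/extdata`.
#'
#' @return character vector of length 65.
#' @export
featureCatalog <- function() {
  path <- system.file("extdata", "feature_catalog.json",
                      package = "histomorph")
  if (!nzchar(path))  # during in-source development
    path <- file.path("inst", "extdata", "feature_catalog.json")
  unlist(jsonlite::read_json(path, simplifyVector = TRUE)$features)
}

perNucleusFeatureNames <- function() {
  c("area", "perimeter", "equivalent_diameter", "elongation", "eccentricity",
    "roundness", "solidity", "intensity_mean", "intensity_median",
    "intensity_sd", "intensity_min", "intensity_max")
}

# Perimeter from an 8-connected boundary chain: axial steps count 1,
# diagonal steps sqrt(2), scaled by the Vossepoel-Smeulders factor 0.95 to
# debias the staircase over-estimate on smooth boundaries.
chainPerimeter <- function(contour) {
  if (nrow(contour) < 2L) return(0)
  d <- rbind(diff(contour), contour[1L, ] - contour[nrow(contour), ])
  steps <- sqrt(rowSums(d^2))
  0.95 * sum(steps)
}

# Convex hull area of a pixel set, using the pixel corners so that the hull
# always contains the full pixel area (keeps solidity <= 1).
pixelHullArea <- function(px) {
  corners <- rbind(cbind(px[, 1] - 0.5, px[, 2] - 0.5),
                   cbind(px[, 1] - 0.5, px[, 2] + 0.5),
                   cbind(px[, 1] + 0.5, px[, 2] - 0.5),
                   cbind(px[, 1] + 0.5, px[, 2] + 0.5))
  hull <- grDevices::chull(corners)
  poly <- corners[hull, , drop = FALSE]
  n <- nrow(poly)
  if (n < 3L) return(nrow(px))
  x <- poly[, 1]; y <- poly[, 2]
  abs(sum(x * y[c(2:n, 1)] - x[c(2:n, 1)] * y)) / 2
}

#' Per-nucleus size, shape and intensity features
#'
#' Geometry comes from the pixel mask: area is the pixel count, the
#' perimeter is the corrected chain length of the boundary contour, axis
#' ratios come from second central moments (with the 1/12 per-pixel term so
#' a discrete w x h rectangle reports elongation w/h exactly), solidity uses
#' the convex hull of the pixel footprint. Intensity statistics are taken
#' over the masked stain-channel pixels.
#'
#' @param pixels two-column integer matrix of (row, col) mask pixels.
#' @param contour two-column matrix, closed boundary polygon (local or
#'   global coordinates; only used for the perimeter).
#' @param intensity numeric matrix covering the mask (stain channel), or
#'   `NULL` for geometry only.
#' @param imageDim dimensions of the enclosing frame; masks touching the
#'   frame border are flagged `boundary_truncated`.
#' @return named numeric vector of the 12 per-nucleus features plus a
#'   `boundary_truncated` attribute.
#' @export
computeNucleusFeatures <- function(pixels, contour, intensity = NULL,
                                   imageDim = NULL) {
  stopIfNot(nrow(pixels) > 0, "empty nucleus mask")
  area <- nrow(pixels)
  per <- chainPerimeter(contour)
  eqd <- 2 * sqrt(area / pi)
  ctr <- colMeans(pixels)
  cv <- stats::cov(pixels) * (area - 1) / area + diag(1 / 12, 2)
  if (area == 1L) cv <- diag(1 / 12, 2)
  ev <- sort(eigen(cv, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  ev <- pmax(ev, 1e-12)
  elong <- sqrt(ev[1] / ev[2])
  ecc <- sqrt(max(0, 1 - ev[2] / ev[1]))
  round_ <- if (per > 0) min(4 * pi * area / per^2, 1 + 1e-6) else 1
  sol <- min(area / pixelHullArea(pixels), 1)
  vals <- c(area = area, perimeter = per, equivalent_diameter = eqd,
            elongation = elong, eccentricity = ecc, roundness = round_,
            solidity = sol)
  if (!is.null(intensity)) {
    iv <- intensity[pixels]
    vals <- c(vals, intensity_mean = mean(iv),
              intensity_median = stats::median(iv),
              intensity_sd = if (length(iv) > 1) stats::sd(iv) else 0,
              intensity_min = min(iv), intensity_max = max(iv))
  } else {
    vals <- c(vals, intensity_mean = NA_real_, intensity_median = NA_real_,
              intensity_sd = NA_real_, intensity_min = NA_real_,
              intensity_max = NA_real_)
  }
  trunc <- FALSE
  if (!is.null(imageDim))
    trunc <- any(pixels[, 1] <= 1 | pixels[, 2] <= 1 |
                 pixels[, 1] >= imageDim[1] | pixels[, 2] >= imageDim[2])
  attr(vals, "boundary_truncated") <- trunc
  vals
}

sixStats <- function(x) {
  if (!length(x) || all(is.na(x)))
    return(c(mean = NA_real_, sd = NA_real_, median = NA_real_,
             min = NA_real_, max = NA_real_, disorder = NA_real_))
  m <- mean(x)
  s <- if (length(x) > 1) stats::sd(x) else 0
  c(mean = m, sd = s, median = stats::median(x), min = min(x), max = max(x),
    disorder = if (m != 0) s / m else NA_real_)
}

#' Spatial-arrangement statistics over nucleus centroids
#'
#' Builds the Voronoi tessellation and Delaunay triangulation of the
#' centroids, the Euclidean minimum spanning tree on the Delaunay graph, and
#' per-nucleus neighbor counts (centroids strictly within `radius`). Voronoi
#' cell areas are reported for bounded (interior) cells only; frontier cells
#' whose tiles touch the enclosing window are excluded.
#'
#' @param centroids two-column numeric matrix of (row, col) positions.
#' @param radius neighbor-count radius in pixels.
#' @return list with per-family value vectors (`voronoi_cell_area`,
#'   `delaunay_edge_length`, `mst_edge_length`, `neighbor_count`), scalars
#'   `voronoi_bounded_fraction`, `mst_total_length`, `delaunay_mean_degree`,
#'   `nn_distance_mean`, and `n_points`. With fewer than 3 points all
#'   entries are `NA` sentinels (logged).
#' @export
computeSpatialSummary <- function(centroids, radius = 50) {
  n <- nrow(centroids)
  if (n < 3L) {
    stageLog("spatial_summary", points = n, note = "too_few_points")
    return(list(voronoi_cell_area = NA_real_,
                delaunay_edge_length = NA_real_,
                mst_edge_length = NA_real_, neighbor_count = NA_real_,
                voronoi_bounded_fraction = NA_real_,
                mst_total_length = NA_real_,
                delaunay_mean_degree = NA_real_,
                nn_distance_mean = NA_real_, n_points = n))
  }
  x <- centroids[, 2]; y <- centroids[, 1]
  # window padded well beyond the points so interior tiles are unaffected
  pad <- 0.1 * max(diff(range(x)), diff(range(y)), 1)
  dd <- deldir::deldir(x, y, rw = c(min(x) - pad, max(x) + pad,
                                    min(y) - pad, max(y) + pad))
  tiles <- deldir::tile.list(dd)
  bounded <- vapply(tiles, function(t) !any(t$bp), logical(1))
  vorArea <- vapply(tiles[bounded], function(t) {
    px <- t$x; py <- t$y; m <- length(px)
    abs(sum(px * py[c(2:m, 1)] - px[c(2:m, 1)] * py)) / 2
  }, numeric(1))
  del <- dd$delsgs
  # edge lengths from the original coordinates (deldir's reported segment
  # endpoints are rounded)
  edgeLen <- sqrt((x[del$ind1] - x[del$ind2])^2 +
                  (y[del$ind1] - y[del$ind2])^2)
  g <- igraph::graph_from_edgelist(cbind(del$ind1, del$ind2),
                                   directed = FALSE)
  igraph::E(g)$weight <- edgeLen
  mstG <- igraph::mst(g)
  mstLen <- igraph::E(mstG)$weight
  dmat <- as.matrix(stats::dist(centroids))
  diag(dmat) <- Inf
  nbr <- rowSums(dmat < radius)
  nnd <- apply(dmat, 1L, min)
  list(voronoi_cell_area = vorArea,
       delaunay_edge_length = edgeLen,
       mst_edge_length = mstLen,
       neighbor_count = nbr,
       voronoi_bounded_fraction = mean(bounded),
       mst_total_length = sum(mstLen),
       delaunay_mean_degree = 2 * nrow(del) / n,
       nn_distance_mean = mean(nnd),
       n_points = n)
}

#' Aggregate per-nucleus features into the 65-feature sample profile
#'
#' Each of the 12 per-nucleus features contributes its mean, sample standard
#' deviation (n - 1) and median over nuclei; the four spatial families
#' contribute mean/sd/median/min/max/disorder; nucleus density
#' (count / glandular area) and four boundary-robust extras complete the
#' catalog. Output order and names follow [featureCatalog()].
#'
#' @param featureMatrix numeric matrix, nuclei x 12, columns named as
#'   [computeNucleusFeatures()] output.
#' @param spatial result of [computeSpatialSummary()].
#' @param sampleId sample identifier.
#' @param glandularArea glandular-mask area in pixels for the density
#'   feature; when `NULL` and `centroids` is given, the convex hull area of
#'   the centroids is used instead -- pass the true mask area when known.
#' @param centroids optional two-column (row, col) matrix used for the
#'   hull-area fallback.
#' @return one-row numeric matrix (row name = `sampleId`) with 65 columns.
#' @export
aggregateProfile <- function(featureMatrix, spatial, sampleId,
                             glandularArea = NULL, centroids = NULL) {
  stopIfNot(nrow(featureMatrix) >= 1L,
            "zero nuclei: check the segmentation stage before aggregating")
  catalog <- featureCatalog()
  out <- stats::setNames(numeric(length(catalog)), catalog)
  for (f in perNucleusFeatureNames()) {
    v <- featureMatrix[, f]
    out[paste0(f, "_mean")] <- mean(v)
    out[paste0(f, "_sd")] <- if (length(v) > 1) stats::sd(v) else 0
    out[paste0(f, "_median")] <- stats::median(v)
  }
  for (fam in c("voronoi_cell_area", "delaunay_edge_length",
                "mst_edge_length", "neighbor_count")) {
    s <- sixStats(spatial[[fam]])
    out[paste0(fam, "_", names(s))] <- s
  }
  if (is.null(glandularArea)) {
    glandularArea <- if (!is.null(centroids) && nrow(centroids) >= 3L)
      pixelHullArea(centroids) else NA_real_
  }
  out["nucleus_density"] <- nrow(featureMatrix) / glandularArea
  out["voronoi_bounded_fraction"] <- spatial$voronoi_bounded_fraction
  out["mst_total_length"] <- spatial$mst_total_length
  out["delaunay_mean_degree"] <- spatial$delaunay_mean_degree
  out["nn_distance_mean"] <- spatial$nn_distance_mean
  matrix(out, nrow = 1L, dimnames = list(sampleId, catalog))
}
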
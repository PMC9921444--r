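#' Merge per-tile nucleus sets into one sample-level set
#'
#' Re-numbers nucleus ids consecutively across tiles and assembles a global
#' label image from the tile label images and origins.
#'
#' @param sets list of [NucleusSet-class] objects (one per tile, with
#'   records in global coordinates).
#' @param imageDim integer `(rows, cols)` of the full image.
#' @param origins list of 0-based (row, col) tile origins, parallel to
#'   `sets`; when `NULL` the label images are assumed to already live on
#'   the full grid.
#' @return a [NucleusSet-class].
#' @export
mergeNucleusSets <- function(sets, imageDim, origins = NULL) {
  lab <- matrix(0L, imageDim[1], imageDim[2])
  recs <- list(); cons <- list(); nextId <- 0L
  for (i in seq_along(sets)) {
    s <- sets[[i]]
    r <- nucleusRecords(s)
    if (!nrow(r)) next
    off <- if (!is.null(origins)) origins[[i]] else c(0L, 0L)
    tl <- nucleusLabelImage(s)
    px <- which(tl > 0, arr.ind = TRUE)
    lab[cbind(px[, 1] + off[1], px[, 2] + off[2])] <- tl[px] + nextId
    r$id <- r$id + nextId
    recs[[length(recs) + 1L]] <- r
    cons <- c(cons, nucleusContours(s))
    nextId <- nextId + max(tl)
  }
  if (!length(recs))
    return(methods::new("NucleusSet",
                        records = data.frame(id = integer(0),
                                             tile_id = integer(0),
                                             row = numeric(0),
                                             col = numeric(0),
                                             area = integer(0),
                                             boundary = logical(0)),
                        contours = list(), labelImage = lab))
  methods::new("NucleusSet", records = do.call(rbind, recs),
               contours = cons, labelImage = lab)
}

#' End-to-end 65-feature profile of one sample
#'
#' Runs the full per-sample imaging pipeline: tiling, per-tile nucleus
#' segmentation, per-nucleus feature extraction on the hematoxylin channel,
#' spatial-arrangement statistics over the global centroids, and
#' aggregation into the 65-feature profile (density uses the glandular-mask
#' area).
#'
#' @param image RGB array (full resolution).
#' @param glandularMask binary matrix on the same grid.
#' @param sampleId sample identifier.
#' @param neighborRadius neighbor-count radius, pixels.
#' @param tileSize tile side, pixels.
#' @param ... further arguments passed to [segmentNuclei()].
#' @return one-row feature matrix (see [aggregateProfile()]).
#' @export
sampleProfile <- function(image, glandularMask, sampleId = "sample",
                          neighborRadius = 50, tileSize = 4096L, ...) {
  tiles <- tileImage(image, glandularMask, tileSize)
  sets <- list(); feats <- list()
  for (i in seq_along(tiles)) {
    tile <- tiles[[i]]
    ns <- segmentNuclei(tile, tileId = i, ...)
    sets[[i]] <- ns
    rec <- nucleusRecords(ns)
    if (!nrow(rec)) next
    hema <- unmixStains(normalizeTile(tile$image))$hematoxylin
    lab <- nucleusLabelImage(ns)
    fm <- t(vapply(seq_len(nrow(rec)), function(j) {
      px <- which(lab == rec$id[j], arr.ind = TRUE)
      contour <- nucleusContours(ns)[[j]]
      local <- cbind(contour[, 1] - tile$origin[1],
                     contour[, 2] - tile$origin[2])
      computeNucleusFeatures(px, local, hema, dim(lab))
    }, numeric(12L)))
    colnames(fm) <- perNucleusFeatureNames()
    feats[[length(feats) + 1L]] <- fm
  }
  merged <- mergeNucleusSets(sets, dim(image)[1:2],
                             origins = lapply(tiles, `[[`, "origin"))
  rec <- nucleusRecords(merged)
  stopIfNot(nrow(rec) > 0,
            "zero nuclei found: check the segmentation stage")
  featureMatrix <- do.call(rbind, feats)
  spatial <- computeSpatialSummary(cbind(rec$row, rec$col),
                                   radius = neighborRadius)
  aggregateProfile(featureMatrix, spatial, sampleId,
                   glandularArea = sum(glandularMask > 0),
                   centroids = cbind(rec$row, rec$col))
}
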
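#' @import methods
NULL

#' Tissue-level segmentation of a low-resolution image
#'
#' Holds the per-pixel tissue labels produced by k-means on the 9-dimensional
#' robust color features, together with the cluster centroids in the original
#' (unstandardized) feature space.
#'
#' @slot labels integer matrix, one label in `0..(k-1)` per pixel.
#' @slot centroids numeric `k x 9` matrix of cluster centroids in feature
#'   space (columns follow the feature order of [computePixelFeatures()]).
#' @slot scale numeric scalar, microns per pixel of the analyzed resolution.
#' @export
setClass("TissueLabelMap",
  representation(labels = "matrix", centroids = "matrix", scale = "numeric"),
  validity = function(object) {
    msg <- character(0)
    if (!all(is.finite(object@centroids)))
      msg <- c(msg, "centroids must be finite")
    if (ncol(object@centroids) != 9L)
      msg <- c(msg, "centroids must have 9 columns")
    labs <- object@labels
    if (any(is.na(labs)) || any(labs < 0) ||
        any(labs >= nrow(object@centroids)))
      msg <- c(msg, "labels must lie in 0..(k-1)")
    if (length(msg)) msg else TRUE
  })

#' Segmented nuclei of one sample
#'
#' One row of `records` per nucleus: `id`, `tile_id`, `row`, `col` (global
#' centroid), `area` (pixels) and `boundary` (logical, touches a tile border).
#' `contours` holds one two-column (row, col) polygon per nucleus, in global
#' coordinates. `labelImage` assigns each pixel its nucleus id (0 = none).
#'
#' @slot records data.frame of per-nucleus records.
#' @slot contours list of numeric matrices (closed polygons).
#' @slot labelImage integer matrix of nucleus ids.
#' @export
setClass("NucleusSet",
  representation(records = "data.frame", contours = "list",
                 labelImage = "matrix"),
  validity = function(object) {
    msg <- character(0)
    rec <- object@records
    need <- c("id", "tile_id", "row", "col", "area")
    if (!all(need %in% names(rec)))
      msg <- c(msg, paste("records must contain", paste(need, collapse = ", ")))
    if (nrow(rec) && anyDuplicated(rec$id))
      msg <- c(msg, "nucleus ids must be unique")
    if (nrow(rec) && length(object@contours) != nrow(rec))
      msg <- c(msg, "one contour per record required")
    if (length(msg)) msg else TRUE
  })

#' Ground-truthed synthetic H&E-like tile
#'
#' @slot image integer array (rows, cols, 3), 8-bit RGB.
#' @slot tissueMap integer matrix: 0 background, 1 adipose, 2 connective,
#'   3 glandular.
#' @slot nucleusLabels integer matrix: 0 = none, i = nucleus i.
#' @slot nucleusParams data.frame with one row per planted nucleus
#'   (`id`, `row`, `col`, `a`, `b`, `theta`, `hema`, `clumped`).
#' @export
setClass("SyntheticTile",
  representation(image = "array", tissueMap = "matrix",
                 nucleusLabels = "matrix", nucleusParams = "data.frame"),
  validity = function(object) {
    msg <- character(0)
    if (length(dim(object@image)) != 3L || dim(object@image)[3] != 3L)
      msg <- c(msg, "image must be rows x cols x 3")
    if (!identical(dim(object@tissueMap), dim(object@nucleusLabels)))
      msg <- c(msg, "tissueMap and nucleusLabels must share a grid")
    n <- nrow(object@nucleusParams)
    labs <- sort(unique(as.vector(object@nucleusLabels)))
    labs <- labs[labs > 0]
    if (n > 0 && !identical(labs, seq_len(n)[seq_along(labs)]))
      msg <- c(msg, "nucleus labels must be contiguous positive integers")
    if (length(msg)) msg else TRUE
  })

#' Result of iterative MLP + k-means deep clustering
#'
#' @slot sampleIds character vector.
#' @slot labels integer vector of cluster labels in `1..k`.
#' @slot representation numeric matrix, samples x 50, the z-scored
#'   activations of the last hidden layer.
#' @slot sseHistory numeric vector, within-cluster SSE per outer iteration.
#' @slot ariHistory numeric vector, agreement (ARI) between consecutive
#'   pseudo-label assignments (convergence indicator).
#' @export
setClass("DeepClusterResult",
  representation(sampleIds = "character", labels = "integer",
                 representation = "matrix", sseHistory = "numeric",
                 ariHistory = "numeric"),
  validity = function(object) {
    msg <- character(0)
    if (length(object@labels) != length(object@sampleIds))
      msg <- c(msg, "every sample must be labeled")
    if (nrow(object@representation) != length(object@sampleIds))
      msg <- c(msg, "representation rows must match samples")
    if (length(msg)) msg else TRUE
  })

#' SSE elbow scan result
#'
#' @slot kValues integer vector of candidate cluster counts.
#' @slot sse numeric vector of within-cluster sums of squared errors.
#' @slot selectedK integer, the k at the maximum discrete second difference.
#' @slot lowConfidence logical, `TRUE` when the curvature peak is weak
#'   relative to the total SSE drop (flat curve).
#' @export
setClass("ElbowResult",
  representation(kValues = "integer", sse = "numeric", selectedK = "integer",
                 lowConfidence = "logical"),
  validity = function(object) {
    if (length(object@kValues) != length(object@sse))
      "kValues and sse must have equal length" else TRUE
  })

setMethod("show", "TissueLabelMap", function(object) {
  cat("TissueLabelMap:", nrow(object@labels), "x", ncol(object@labels),
      "pixels,", nrow(object@centroids), "tissue classes, scale",
      object@scale, "um/px\n")
})

setMethod("show", "NucleusSet", function(object) {
  cat("NucleusSet:", nrow(object@records), "nuclei over",
      length(unique(object@records$tile_id)), "tile(s)\n")
})

setMethod("show", "SyntheticTile", function(object) {
  d <- dim(object@tissueMap)
  cat("SyntheticTile:", d[1], "x", d[2], "px,",
      nrow(object@nucleusParams), "planted nuclei\n")
})

setMethod("show", "DeepClusterResult", function(object) {
  cat("DeepClusterResult:", length(object@labels), "samples,",
      length(unique(object@labels)), "clusters,",
      length(object@sseHistory), "outer iterations\n")
})

setMethod("show", "ElbowResult", function(object) {
  cat("ElbowResult: k =", paste(range(object@kValues), collapse = ".."),
      "-> selected k =", object@selectedK,
      if (object@lowConfidence) "(low confidence)" else "", "\n")
})

#' Accessors
#'
#' `tissueLabels()`, `tissueCentroids()`, `nucleusRecords()`,
#' `nucleusContours()`, `nucleusLabelImage()`, `clusterLabels()`,
#' `clusterRepresentation()`, `sseHistory()`, `selectedK()`,
#' `tileImage()`/`tileTissueMap()`/`tileNucleusLabels()`/`tileNucleusParams()`
#' read the corresponding slots.
#'
#' @param x an object of the matching class.
#' @return the slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
tissueLabels <- function(x) x@labels
#' @rdname accessors
#' @export
tissueCentroids <- function(x) x@centroids
#' @rdname accessors
#' @export
nucleusRecords <- function(x) x@records
#' @rdname accessors
#' @export
nucleusContours <- function(x) x@contours
#' @rdname accessors
#' @export
nucleusLabelImage <- function(x) x@labelImage
#' @rdname accessors
#' @export
clusterLabels <- function(x) x@labels
#' @rdname accessors
#' @export
clusterRepresentation <- function(x) x@representation
#' @rdname accessors
#' @export
sseHistory <- function(x) if (is(x, "ElbowResult")) x@sse else x@sseHistory
#' @rdname accessors
#' @export
selectedK <- function(x) x@selectedK
#' @rdname accessors
#' @export
tileRGB <- function(x) x@image
#' @rdname accessors
#' @export
tileTissueMap <- function(x) x@tissueMap
#' @rdname accessors
#' @export
tileNucleusLabels <- function(x) x@nucleusLabels
#' @rdname accessors
#' @export
tileNucleusParams <- function(x) x@nucleusParams
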
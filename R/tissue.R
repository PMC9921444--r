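#' Per-pixel robust color statistics
#'
#' For each pixel and each of the R, G, B channels, computes the median,
#' inter-quartile range and median absolute deviation over the
#' `(2r + 1)^2` local window (edges replicated), yielding a 9-dimensional
#' feature vector per pixel. Quartiles use linear interpolation between
#' order statistics (quantile type 7).
#'
#' @param image integer/numeric array `(rows, cols, 3)`.
#' @param windowRadius window radius `r >= 1` in pixels.
#' @return numeric array `(rows, cols, 9)`; slice order is
#'   R(Med, IQR, MAD), G(Med, IQR, MAD), B(Med, IQR, MAD).
#' @export
computePixelFeatures <- function(image, windowRadius = 2L) {
  if (length(dim(image)) != 3L || dim(image)[3] != 3L)
    stop("dimensionality error: expected a 3-channel RGB image",
         call. = FALSE)
  stopIfNot(windowRadius >= 1L, "windowRadius must be >= 1")
  r <- as.integer(windowRadius)
  h <- dim(image)[1]; w <- dim(image)[2]
  out <- array(NA_real_, dim = c(h, w, 9L))
  offs <- expand.grid(dr = -r:r, dc = -r:r)
  clampR <- function(i) pmin(pmax(i, 1L), h)
  clampC <- function(j) pmin(pmax(j, 1L), w)
  rows <- seq_len(h); cols <- seq_len(w)
  for (ch in 1:3) {
    plane <- image[, , ch]
    X <- matrix(NA_real_, h * w, nrow(offs))
    for (o in seq_len(nrow(offs)))
      X[, o] <- plane[clampR(rows + offs$dr[o]), clampC(cols + offs$dc[o])]
    med <- matrixStats::rowMedians(X)
    q <- matrixStats::rowQuantiles(X, probs = c(0.25, 0.75), type = 7L)
    mad_ <- matrixStats::rowMedians(abs(X - med))
    base <- (ch - 1L) * 3L
    out[, , base + 1L] <- med
    out[, , base + 2L] <- q[, 2L] - q[, 1L]
    out[, , base + 3L] <- mad_
  }
  dimnames(out) <- list(NULL, NULL,
                        as.vector(t(outer(c("R", "G", "B"),
                                          c("med", "iqr", "mad"), paste,
                                          sep = "_"))))
  out
}

# k-means++ seeding followed by Lloyd iterations via stats::kmeans, best of
# `nstart` restarts by total within-cluster SSE.
kmeansPP <- function(x, k, nstart = 10L, iterMax = 100L) {
  n <- nrow(x)
  if (k == 1L) {
    ctr <- matrix(colMeans(x), 1L)
    return(list(cluster = rep(1L, n), centers = ctr,
                tot.withinss = sum(sweep(x, 2L, ctr[1L, ])^2)))
  }
  best <- NULL
  for (s in seq_len(nstart)) {
    centers <- matrix(NA_real_, k, ncol(x))
    centers[1L, ] <- x[sample.int(n, 1L), ]
    d2 <- rowSums(sweep(x, 2L, centers[1L, ])^2)
    for (j in 2:k) {
      p <- d2 / sum(d2)
      if (!all(is.finite(p)) || sum(d2) == 0)
        centers[j, ] <- x[sample.int(n, 1L), ]
      else centers[j, ] <- x[sample.int(n, 1L, prob = p), ]
      d2 <- pmin(d2, rowSums(sweep(x, 2L, centers[j, ])^2))
    }
    fit <- suppressWarnings(stats::kmeans(x, centers = centers,
                                          iter.max = iterMax,
                                          algorithm = "Lloyd"))
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  best
}

#' Cluster pixels into tissue classes
#'
#' Standardizes the 9-dimensional per-pixel features per dimension
#' (z-score), runs k-means (k-means++ seeding, 10 restarts) and returns the
#' per-pixel labels together with the cluster centroids mapped back to the
#' original feature space.
#'
#' @param features array `(rows, cols, 9)` from [computePixelFeatures()].
#' @param tissueK number of tissue classes (>= 1).
#' @param seed integer seed.
#' @param scale microns per pixel of the analyzed resolution (metadata).
#' @return a [TissueLabelMap-class]; labels are `0..(k-1)`.
#' @export
clusterTissue <- function(features, tissueK = 4L, seed = 1L, scale = 16) {
  h <- dim(features)[1]; w <- dim(features)[2]
  x <- matrix(features, h * w, 9L)
  if (nrow(unique(x)) < tissueK)
    stop("degeneracy error: fewer distinct feature vectors than tissueK",
         call. = FALSE)
  mu <- colMeans(x)
  sdv <- apply(x, 2L, stats::sd)
  sdv[sdv == 0] <- 1
  xs <- sweep(sweep(x, 2L, mu), 2L, sdv, "/")
  fit <- withSeed(seed, kmeansPP(xs, tissueK))
  centroids <- sweep(sweep(fit$centers, 2L, sdv, "*"), 2L, mu, "+")
  colnames(centroids) <- dimnames(features)[[3]]
  labels <- matrix(as.integer(fit$cluster) - 1L, h, w)
  stageLog("cluster_tissue", pixels = h * w, k = tissueK)
  methods::new("TissueLabelMap", labels = labels, centroids = centroids,
               scale = scale)
}

#' Identify the glandular cluster by reference centroid
#'
#' Returns the label id (0-based) of the cluster whose centroid is closest
#' in Euclidean distance to a reference centroid taken from a verified
#' standard image. Ties break to the lowest label id with a warning.
#'
#' @param labelMap a [TissueLabelMap-class].
#' @param reference numeric 9-vector (a glandular reference centroid), e.g.
#'   from [glandularReference()].
#' @return integer label id of the glandular cluster.
#' @export
matchGlandular <- function(labelMap, reference) {
  stopIfNot(length(reference) == 9L, "reference centroid must have length 9")
  d <- sqrt(rowSums(sweep(labelMap@centroids, 2L, as.numeric(reference))^2))
  hit <- which(d == min(d))
  if (length(hit) > 1L)
    warning("glandular reference tie: choosing lowest label id")
  as.integer(hit[1L] - 1L)
}

#' Load (or recompute) the glandular reference centroid
#'
#' The package ships a reference centroid computed from one standard
#' synthetic tile whose glandular region is known exactly (the synthetic
#' counterpart of a pathologist-verified standard image); users may supply
#' their own. `makeGlandularReference()` recomputes it from scratch.
#'
#' @param path optional JSON file with a `centroid` array of length 9.
#' @return numeric 9-vector.
#' @export
glandularReference <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "glandular_reference.json",
                        package = "histomorph")
    if (!nzchar(path))
      path <- file.path("inst", "extdata", "glandular_reference.json")
  }
  ref <- jsonlite::read_json(path, simplifyVector = TRUE)
  as.numeric(ref$centroid)
}

#' @rdname glandularReference
#' @param seed seed of the standard tile.
#' @param windowRadius window radius for the pixel features.
#' @export
makeGlandularReference <- function(seed = 1000L, windowRadius = 2L) {
  tile <- generateTile(size = 256L, nNuclei = 0L, seed = seed)
  feats <- computePixelFeatures(tileRGB(tile), windowRadius)
  gl <- tileTissueMap(tile) == 3L
  x <- matrix(feats, prod(dim(gl)), 9L)
  centroid <- colMeans(x[as.vector(gl), , drop = FALSE])
  names(centroid) <- dimnames(feats)[[3]]
  centroid
}

#' Nearest-neighbor mask upsampling
#'
#' @param mask binary or integer matrix (low resolution).
#' @param targetShape integer vector `(rows, cols)` of the full-resolution
#'   grid (each must be >= the mask dimension).
#' @return matrix of `targetShape` with nearest-neighbor replicated values.
#' @export
upsampleMask <- function(mask, targetShape) {
  h <- nrow(mask); w <- ncol(mask)
  H <- targetShape[1]; W <- targetShape[2]
  stopIfNot(H >= h && W >= w,
            "parameter error: target must not be smaller than the mask")
  ri <- pmin(pmax(ceiling(seq_len(H) * h / H), 1L), h)
  ci <- pmin(pmax(ceiling(seq_len(W) * w / W), 1L), w)
  mask[ri, ci, drop = FALSE]
}

# Majority-vote downsampling (block mode); inverse of upsampleMask for
# block-aligned shapes.
downsampleMaskMajority <- function(mask, targetShape) {
  h <- nrow(mask); w <- ncol(mask)
  H <- targetShape[1]; W <- targetShape[2]
  ri <- ceiling(seq_len(h) * H / h)
  ci <- ceiling(seq_len(w) * W / w)
  out <- matrix(0L, H, W)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    block <- mask[ri == i, ci == j, drop = FALSE]
    tab <- table(block)
    out[i, j] <- as.integer(names(tab)[which.max(tab)])
  }
  out
}
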
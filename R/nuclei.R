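#' Split an image and its glandular mask into tiles
#'
#' Non-overlapping tiles cover the image; boundary tiles may be smaller.
#' Tiles containing no glandular pixels are skipped.
#'
#' @param image RGB array `(rows, cols, 3)`.
#' @param glandularMask binary matrix on the same grid.
#' @param tileSize tile side in pixels.
#' @return list of tiles; each is a list with `image`, `origin` (0-based
#'   (row, col) offset) and `glandular_mask`.
#' @export
tileImage <- function(image, glandularMask, tileSize = 4096L) {
  stopIfNot(all(dim(image)[1:2] == dim(glandularMask)),
            "image and mask must share a grid")
  h <- dim(image)[1]; w <- dim(image)[2]
  tiles <- list()
  for (r0 in seq(1L, h, by = tileSize)) {
    for (c0 in seq(1L, w, by = tileSize)) {
      r1 <- min(r0 + tileSize - 1L, h)
      c1 <- min(c0 + tileSize - 1L, w)
      gm <- glandularMask[r0:r1, c0:c1, drop = FALSE]
      if (!any(gm > 0)) next
      tiles[[length(tiles) + 1L]] <-
        list(image = image[r0:r1, c0:c1, , drop = FALSE],
             origin = c(r0 - 1L, c0 - 1L), glandular_mask = gm)
    }
  }
  stageLog("tile_image", tiles = length(tiles))
  tiles
}

# Vectorized sRGB (0..255) <-> CIELAB (D65) conversion.
rgb2lab <- function(img) {
  v <- matrix(img, ncol = 3L) / 255
  lin <- ifelse(v <= 0.04045, v / 12.92, ((v + 0.055) / 1.055)^2.4)
  M <- matrix(c(0.4124564, 0.3575761, 0.1804375,
                0.2126729, 0.7151522, 0.0721750,
                0.0193339, 0.1191920, 0.9503041), 3L, byrow = TRUE)
  xyz <- lin %*% t(M)
  wp <- c(0.95047, 1, 1.08883)
  t_ <- sweep(xyz, 2L, wp, "/")
  f <- ifelse(t_ > (6 / 29)^3, t_^(1 / 3), t_ / (3 * (6 / 29)^2) + 4 / 29)
  cbind(L = 116 * f[, 2] - 16,
        a = 500 * (f[, 1] - f[, 2]),
        b = 200 * (f[, 2] - f[, 3]))
}

lab2rgb <- function(lab) {
  fy <- (lab[, 1] + 16) / 116
  fx <- fy + lab[, 2] / 500
  fz <- fy - lab[, 3] / 200
  finv <- function(f) ifelse(f > 6 / 29, f^3, 3 * (6 / 29)^2 * (f - 4 / 29))
  wp <- c(0.95047, 1, 1.08883)
  xyz <- cbind(finv(fx) * wp[1], finv(fy) * wp[2], finv(fz) * wp[3])
  Minv <- matrix(c(3.2404542, -1.5371385, -0.4985314,
                   -0.9692660, 1.8760108, 0.0415560,
                   0.0556434, -0.2040259, 1.0572252), 3L, byrow = TRUE)
  lin <- xyz %*% t(Minv)
  lin <- pmin(pmax(lin, 0), 1)
  v <- ifelse(lin <= 0.0031308, 12.92 * lin,
              1.055 * lin^(1 / 2.4) - 0.055)
  round(v * 255)
}

#' Normalize a tile by histogram equalization in the CIELAB L channel
#'
#' The L channel is equalized over 256 bins (cumulative-histogram mapping,
#' which preserves the pixel rank order); a and b are untouched; the result
#' is converted back to 8-bit RGB.
#'
#' @param image RGB array `(rows, cols, 3)`.
#' @return RGB integer array of the same shape.
#' @export
normalizeTile <- function(image) {
  d <- dim(image)
  lab <- rgb2lab(image)
  L <- lab[, 1]
  bins <- pmin(pmax(floor(L / 100 * 255), 0), 255) + 1L
  cdf <- cumsum(tabulate(bins, nbins = 256L)) / length(bins)
  lab[, 1] <- cdf[bins] * 100
  out <- lab2rgb(lab)
  arr <- array(out, dim = d)
  storage.mode(arr) <- "integer"
  arr
}

#' Unmix H&E stains by optical-density color deconvolution
#'
#' Converts each pixel to optical density `OD_c = -log10(max(I_c, 1) / 255)`
#' (Beer-Lambert with 8-bit white point 255) and solves the per-pixel 3x3
#' linear system against the stain matrix. Negative concentrations are
#' clipped to zero.
#'
#' @param image RGB array `(rows, cols, 3)` on 0..255.
#' @param stainMatrix 3x3 matrix, rows = unit-norm stain OD vectors
#'   (default: Ruifrok-Johnston hematoxylin/eosin plus their residual).
#' @return list of numeric matrices `hematoxylin`, `eosin`, `residual`
#'   (stain concentrations, OD units, >= 0).
#' @export
unmixStains <- function(image, stainMatrix = heStainMatrix()) {
  if (abs(det(stainMatrix)) < 1e-8)
    stop("numerical error: singular stain matrix", call. = FALSE)
  d <- dim(image)
  od <- -log10(pmax(matrix(image, ncol = 3L), 1) / 255)
  conc <- od %*% solve(stainMatrix)
  conc[conc < 0] <- 0
  list(hematoxylin = matrix(conc[, 1], d[1], d[2]),
       eosin = matrix(conc[, 2], d[1], d[2]),
       residual = matrix(conc[, 3], d[1], d[2]))
}

#' Otsu threshold by between-class variance maximization
#'
#' Exact maximization over a 256-bin histogram of the input values; returns
#' the threshold on the original value scale (upper edge of the selected
#' bin).
#'
#' @param x numeric vector or matrix of values.
#' @param nbins number of histogram bins.
#' @return numeric threshold.
#' @export
otsuThreshold <- function(x, nbins = 256L) {
  x <- as.numeric(x)
  rng <- range(x)
  if (diff(rng) == 0) return(rng[1])
  bins <- pmin(floor((x - rng[1]) / diff(rng) * nbins), nbins - 1L) + 1L
  h <- tabulate(bins, nbins = nbins)
  p <- h / sum(h)
  mids <- rng[1] + (seq_len(nbins) - 0.5) / nbins * diff(rng)
  w0 <- cumsum(p)
  mu0 <- cumsum(p * mids)
  muT <- mu0[nbins]
  sigmaB <- (muT * w0 - mu0)^2 / (w0 * (1 - w0))
  sigmaB[!is.finite(sigmaB)] <- -Inf
  tIdx <- which.max(sigmaB)
  rng[1] + tIdx / nbins * diff(rng)
}

removeSmallComponents <- function(mask, minArea) {
  if (!any(mask)) return(mask)
  lab <- as.matrix(EBImage::bwlabel(EBImage::Image(mask * 1)))
  areas <- tabulate(lab[lab > 0])
  keep <- which(areas >= minArea)
  matrix(lab %in% keep, nrow(mask), ncol(mask))
}

#' Initial nucleus mask by ratio-scaled Otsu thresholding
#'
#' The Otsu threshold is computed on the hematoxylin channel restricted to
#' glandular pixels, scaled by `otsuRatio` (ratio 1 reproduces the plain
#' Otsu partition); components below `minArea` pixels are removed.
#'
#' @param hematoxylin stain-concentration matrix.
#' @param otsuRatio positive scale factor for the threshold.
#' @param glandularMask optional binary matrix restricting both the
#'   threshold estimation and the mask.
#' @param minArea minimum component area in pixels.
#' @return logical matrix.
#' @export
initialNucleiMask <- function(hematoxylin, otsuRatio = 1,
                              glandularMask = NULL, minArea = 10L) {
  stopIfNot(otsuRatio > 0, "otsuRatio must be > 0")
  vals <- if (is.null(glandularMask)) hematoxylin
          else hematoxylin[glandularMask > 0]
  if (length(vals) == 0 || diff(range(vals)) == 0) {
    warning("constant hematoxylin channel: empty initial mask")
    return(matrix(FALSE, nrow(hematoxylin), ncol(hematoxylin)))
  }
  thr <- otsuRatio * otsuThreshold(vals)
  mask <- hematoxylin > thr
  if (!is.null(glandularMask)) mask <- mask & (glandularMask > 0)
  if (!any(mask)) return(mask)
  removeSmallComponents(mask, minArea)
}

shiftMat <- function(m, dr, dc) {
  h <- nrow(m); w <- ncol(m)
  ri <- pmin(pmax(seq_len(h) + dr, 1L), h)
  ci <- pmin(pmax(seq_len(w) + dc, 1L), w)
  m[ri, ci, drop = FALSE]
}

#' Refine a nucleus mask by Chan-Vese level-set evolution
#'
#' Region-based active contour: the level-set function (initialized as the
#' signed distance to the initial mask boundary) evolves under the Chan-Vese
#' energy -- inside/outside mean data terms plus a curvature regularization
#' weighted by `mu` (the intensity channel is normalized to `[0, 1]`, so
#' `mu` is scale-free). The time step is capped at `1 / (4 mu)` so the
#' explicit scheme stays stable for large curvature weights. Evolution
#' stops after `maxIters` iterations or when the relative change in
#' segmented area falls below `tol`. If the contour collapses (below 10%
#' of the initial area) or floods the frame, the initial mask is returned
#' with a warning.
#'
#' @param initMask logical matrix, non-empty initialization.
#' @param intensity numeric matrix (e.g. the hematoxylin concentration).
#' @param mu curvature weight (default 0.2 on the normalized scale).
#' @param maxIters iteration cap.
#' @param tol relative-area-change stopping tolerance.
#' @param dt time step.
#' @return logical matrix (refined mask).
#' @export
refineContours <- function(initMask, intensity, mu = 0.2, maxIters = 100L,
                           tol = 1e-3, dt = 0.5) {
  stopIfNot(any(initMask), "initMask must be non-empty")
  I <- (intensity - min(intensity)) /
    max(diff(range(intensity)), .Machine$double.eps)
  phi <- as.matrix(EBImage::distmap(EBImage::Image(initMask * 1))) -
    as.matrix(EBImage::distmap(EBImage::Image((!initMask) * 1)))
  phi <- pmin(pmax(phi, -5), 5)
  eps <- 1
  total <- length(I)
  initArea <- sum(initMask)
  prevArea <- initArea
  dt <- min(dt, 1 / (4 * mu))  # explicit-scheme stability bound
  for (it in seq_len(maxIters)) {
    inside <- phi > 0
    a1 <- sum(inside)
    if (a1 < 0.1 * initArea || a1 >= 0.99 * total) {
      warning("level-set divergence: falling back to the initial mask")
      return(initMask)
    }
    c1 <- mean(I[inside]); c2 <- mean(I[!inside])
    px <- (shiftMat(phi, 0L, 1L) - shiftMat(phi, 0L, -1L)) / 2
    py <- (shiftMat(phi, 1L, 0L) - shiftMat(phi, -1L, 0L)) / 2
    pxx <- shiftMat(phi, 0L, 1L) - 2 * phi + shiftMat(phi, 0L, -1L)
    pyy <- shiftMat(phi, 1L, 0L) - 2 * phi + shiftMat(phi, -1L, 0L)
    pxy <- (shiftMat(phi, 1L, 1L) - shiftMat(phi, 1L, -1L) -
            shiftMat(phi, -1L, 1L) + shiftMat(phi, -1L, -1L)) / 4
    grad2 <- px^2 + py^2
    kappa <- (pxx * py^2 - 2 * px * py * pxy + pyy * px^2) /
      (grad2^1.5 + 1e-8)
    delta <- eps / (pi * (eps^2 + phi^2))
    force <- mu * kappa - (I - c1)^2 + (I - c2)^2
    phi <- pmin(pmax(phi + dt * delta * force, -5), 5)
    area <- sum(phi > 0)
    if (it %% 5L == 0L) {
      if (abs(area - prevArea) / max(prevArea, 1) < tol) break
      prevArea <- area
    }
  }
  out <- phi > 0
  if (sum(out) < 0.1 * initArea || sum(out) >= 0.99 * total) {
    warning("level-set divergence: falling back to the initial mask")
    return(initMask)
  }
  out
}

#' Split a clumped component into individual nuclei by mean-shift
#'
#' Mode seeking with a flat (uniform) kernel over the foreground pixel
#' coordinates: every pixel is a seed, means iterate until the shift falls
#' below 0.1 px, and converged modes closer than `mergeFactor * bandwidth`
#' merge. A consolidation pass then removes plateau artifacts: while the
#' number of modes exceeds the area-implied multiplicity
#' `ceiling(area / (pi * bandwidth^2))` and the two closest modes are less
#' than `1.1 * bandwidth` apart, they merge (basin-size-weighted). Modes
#' with fewer than `minArea` pixels are absorbed by the nearest surviving
#' mode. Deterministic (no randomness).
#'
#' @param pixels two-column integer matrix of (row, col) foreground pixels.
#' @param bandwidth kernel radius in pixels (about one nucleus radius).
#' @param minArea minimum pixels per sub-nucleus.
#' @param mergeFactor modes closer than `mergeFactor * bandwidth` merge.
#' @return list of (row, col) pixel matrices, one per separated nucleus.
#' @export
declump <- function(pixels, bandwidth, minArea = 10L, mergeFactor = 0.7) {
  n <- nrow(pixels)
  if (n == 0L) return(list())
  pos <- pixels * 1.0
  modes <- pos
  for (it in seq_len(100L)) {
    d2 <- outer(rowSums(modes^2), rep(1, n)) +
      outer(rep(1, nrow(modes)), rowSums(pos^2)) -
      2 * modes %*% t(pos)
    within <- d2 <= bandwidth^2
    newModes <- (within %*% pos) / pmax(rowSums(within), 1)
    shift <- sqrt(rowSums((newModes - modes)^2))
    modes <- newModes
    if (max(shift) < 0.1) break
  }
  # greedy merge of converged modes (index order)
  assign <- integer(n)
  centers <- NULL
  for (i in seq_len(n)) {
    if (!is.null(centers)) {
      dc <- sqrt(rowSums(sweep(centers, 2L, modes[i, ])^2))
      j <- which(dc < mergeFactor * bandwidth)
      if (length(j)) { assign[i] <- j[1L]; next }
    }
    centers <- rbind(centers, modes[i, ])
    assign[i] <- nrow(centers)
  }
  K <- nrow(centers)
  for (k in seq_len(K))
    centers[k, ] <- colMeans(pos[assign == k, , drop = FALSE])
  sizes <- tabulate(assign, K)
  # consolidate plateau modes down to the area-implied multiplicity
  nExp <- max(1L, ceiling(n / (pi * bandwidth^2) - 0.1))
  repeat {
    act <- which(sizes > 0)
    if (length(act) <= nExp) break
    dmat <- as.matrix(stats::dist(centers[act, , drop = FALSE]))
    diag(dmat) <- Inf
    if (min(dmat) >= 1.1 * bandwidth) break
    ij <- which(dmat == min(dmat), arr.ind = TRUE)[1L, ]
    a <- act[ij[1L]]; b <- act[ij[2L]]
    centers[a, ] <- (centers[a, ] * sizes[a] + centers[b, ] * sizes[b]) /
      (sizes[a] + sizes[b])
    sizes[a] <- sizes[a] + sizes[b]; sizes[b] <- 0L
    assign[assign == b] <- a
  }
  # absorb undersized modes into the nearest surviving mode
  act <- which(sizes > 0)
  keep <- act[sizes[act] >= minArea]
  if (!length(keep)) keep <- act[which.max(sizes[act])]
  for (i in which(!(assign %in% keep))) {
    dc <- sqrt(rowSums(sweep(centers[keep, , drop = FALSE], 2L,
                             pos[i, ])^2))
    assign[i] <- keep[which.min(dc)]
  }
  lapply(sort(unique(assign)),
         function(a) pixels[assign == a, , drop = FALSE])
}

componentSolidity <- function(pixels) {
  if (nrow(pixels) < 3L) return(1)
  nrow(pixels) / pixelHullArea(pixels)
}

#' Segment nuclei in one tile
#'
#' Composition of the per-tile pipeline: CIELAB-L histogram equalization,
#' H&E stain unmixing, ratio-scaled Otsu initialization on the hematoxylin
#' channel inside the glandular mask, Chan-Vese refinement, a per-component
#' clump test (area above `clumpAreaFactor` times the median component area,
#' or solidity below `solidityThreshold`), and mean-shift declumping of
#' flagged components. Records carry global (row, col) coordinates via the
#' tile origin; nuclei whose centroid falls outside the glandular mask are
#' discarded.
#'
#' @param tile list with `image` (RGB array), `origin` (0-based (row, col)),
#'   `glandular_mask` (binary matrix), as produced by [tileImage()].
#' @param tileId integer id stored in the records.
#' @param otsuRatio Otsu threshold scale (default 1).
#' @param minArea minimum nucleus area, pixels.
#' @param clumpAreaFactor clump trigger: area factor over the median.
#' @param solidityThreshold clump trigger: solidity floor.
#' @param bandwidth mean-shift bandwidth; default
#'   `sqrt(median component area / pi)` (about one nucleus radius).
#' @param levelSet list of [refineContours()] parameters.
#' @return a [NucleusSet-class] for this tile.
#' @export
segmentNuclei <- function(tile, tileId = 1L, otsuRatio = 1, minArea = 10L,
                          clumpAreaFactor = 1.5, solidityThreshold = 0.9,
                          bandwidth = NULL,
                          levelSet = list(mu = 0.2, maxIters = 100L,
                                          tol = 1e-3)) {
  img <- tile$image
  gm <- tile$glandular_mask > 0
  origin <- if (!is.null(tile$origin)) tile$origin else c(0L, 0L)
  empty <- methods::new("NucleusSet",
                        records = data.frame(id = integer(0),
                                             tile_id = integer(0),
                                             row = numeric(0),
                                             col = numeric(0),
                                             area = integer(0),
                                             boundary = logical(0)),
                        contours = list(),
                        labelImage = matrix(0L, dim(img)[1], dim(img)[2]))
  if (!any(gm)) return(empty)
  norm <- normalizeTile(img)
  hema <- unmixStains(norm)$hematoxylin
  init <- initialNucleiMask(hema, otsuRatio, gm, minArea)
  if (!any(init)) return(empty)
  refined <- refineContours(init, hema, mu = levelSet$mu,
                            maxIters = levelSet$maxIters,
                            tol = levelSet$tol) & gm
  refined <- removeSmallComponents(refined, minArea)
  if (!any(refined)) return(empty)
  lab <- as.matrix(EBImage::bwlabel(EBImage::Image(refined * 1)))
  nComp <- max(lab)
  areas <- tabulate(lab[lab > 0], nbins = nComp)
  medArea <- stats::median(areas)
  if (is.null(bandwidth)) bandwidth <- sqrt(medArea / pi)
  final <- matrix(0L, nrow(lab), ncol(lab))
  nextId <- 0L
  for (cmp in seq_len(nComp)) {
    px <- which(lab == cmp, arr.ind = TRUE)
    isClump <- areas[cmp] > clumpAreaFactor * medArea ||
      componentSolidity(px) < solidityThreshold
    parts <- if (isClump) declump(px, bandwidth, minArea) else list(px)
    for (p in parts) {
      if (nrow(p) < minArea) next
      nextId <- nextId + 1L
      final[p] <- nextId
    }
  }
  if (nextId == 0L) return(empty)
  # records + contours, centroid-gated by the glandular mask
  recs <- list(); contours <- list(); keptLab <- matrix(0L, nrow(lab),
                                                        ncol(lab))
  oc <- EBImage::ocontour(EBImage::Image(final))
  keep <- 0L
  for (i in seq_len(nextId)) {
    px <- which(final == i, arr.ind = TRUE)
    ctr <- colMeans(px)
    cr <- round(ctr[1]); cc <- round(ctr[2])
    if (!gm[cr, cc]) next
    keep <- keep + 1L
    keptLab[px] <- keep
    contour <- oc[[i]] + 1L  # EBImage contours are 0-based
    # EBImage's first coordinate indexes the first array dimension (rows)
    contourGlobal <- cbind(contour[, 1] + origin[1],
                           contour[, 2] + origin[2])
    contours[[keep]] <- contourGlobal
    recs[[keep]] <- data.frame(
      id = keep, tile_id = tileId,
      row = ctr[1] + origin[1], col = ctr[2] + origin[2],
      area = nrow(px),
      boundary = any(px[, 1] <= 1 | px[, 2] <= 1 |
                     px[, 1] >= nrow(lab) | px[, 2] >= ncol(lab)))
  }
  if (keep == 0L) return(empty)
  records <- do.call(rbind, recs)
  stageLog("segment_nuclei", tile = tileId, nuclei = keep)
  methods::new("NucleusSet", records = records, contours = contours,
               labelImage = keptLab)
}
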
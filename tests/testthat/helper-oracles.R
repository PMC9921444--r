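# Independent oracles used by the unit and acceptance tests. Each is a
# deliberately naive reference computation, kept separate from the package
# implementation it checks.

# Benjamini-Hochberg by literal min-over-suffix double loop.
bruteBH <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  qs <- numeric(m)
  for (i in seq_len(m)) {
    best <- Inf
    for (j in i:m) best <- min(best, m * ps[j] / j)
    qs[i] <- min(best, 1)
  }
  out <- numeric(m)
  out[o] <- qs
  out
}

# Minimum spanning tree weight by exhaustive enumeration of edge subsets
# (n <= 7), with a hand-rolled union-find connectivity check.
bruteMSTWeight <- function(points) {
  n <- nrow(points)
  stopifnot(n <= 7)
  edges <- t(utils::combn(n, 2))
  w <- sqrt(rowSums((points[edges[, 1], , drop = FALSE] -
                     points[edges[, 2], , drop = FALSE])^2))
  best <- Inf
  for (subset in utils::combn(nrow(edges), n - 1, simplify = FALSE)) {
    parent <- seq_len(n)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    ok <- TRUE
    for (e in subset) {
      a <- find(edges[e, 1]); b <- find(edges[e, 2])
      if (a == b) { ok <- FALSE; break }
      parent[a] <- b
    }
    if (ok) best <- min(best, sum(w[subset]))
  }
  best
}

# Average symmetric Hausdorff by brute-force double loop over boundary
# pixels (boundary extraction shared with the package: the oracle checks
# the distance computation).
bruteAvgHausdorff <- function(a, b) {
  ba <- histomorph:::boundaryPixels(a)
  bb <- histomorph:::boundaryPixels(b)
  dmin <- function(from, to) {
    vapply(seq_len(nrow(from)), function(i)
      min(sqrt((to[, 1] - from[i, 1])^2 + (to[, 2] - from[i, 2])^2)),
      numeric(1))
  }
  (mean(dmin(ba, bb)) + mean(dmin(bb, ba))) / 2
}

# Otsu by exhaustive search over the 256 bin edges, recomputing both class
# means explicitly at every candidate.
bruteOtsu <- function(x, nbins = 256L) {
  x <- as.numeric(x)
  rng <- range(x)
  bins <- pmin(floor((x - rng[1]) / diff(rng) * nbins), nbins - 1L) + 1L
  mids <- rng[1] + (seq_len(nbins) - 0.5) / nbins * diff(rng)
  best <- -Inf; bestT <- NA
  for (t in seq_len(nbins)) {
    lo <- bins <= t; hi <- !lo
    if (!any(lo) || !any(hi)) next
    w0 <- mean(lo); w1 <- mean(hi)
    m0 <- mean(mids[bins[lo]]); m1 <- mean(mids[bins[hi]])
    sb <- w0 * w1 * (m0 - m1)^2
    if (sb > best) { best <- sb; bestT <- t }
  }
  rng[1] + bestT / nbins * diff(rng)
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# Rasterize a disk mask on an h x w grid.
diskMask <- function(h, w, cr, cc, r) {
  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  (rows - cr)^2 + (cols - cc)^2 <= r^2
}
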
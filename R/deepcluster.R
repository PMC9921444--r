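#' Z-score a matrix per feature to mean 0, sd 1
#'
#' Uses the population standard deviation (divide by n) so each feature hits
#' the normalization targets exactly; constant features map to all zeros
#' with a warning.
#'
#' @param x numeric matrix, samples x features.
#' @return matrix of the same shape.
#' @export
zscoreMatrix <- function(x) {
  stopIfNot(nrow(x) >= 2L, "need at least 2 samples")
  mu <- colMeans(x)
  sdv <- sqrt(colMeans(sweep(x, 2L, mu)^2))
  zero <- sdv == 0
  if (any(zero)) {
    warning(sum(zero), " constant feature(s) mapped to zeros")
    sdv[zero] <- 1
  }
  out <- sweep(sweep(x, 2L, mu), 2L, sdv, "/")
  out[, zero] <- 0
  out
}

#' k-means with within-cluster SSE
#'
#' k-means++ seeding with 10 restarts (best of restarts by SSE).
#'
#' @param x numeric matrix, samples x features.
#' @param k number of clusters (<= number of samples).
#' @param seed integer seed.
#' @param nstart restarts.
#' @return list with `labels` (integer vector), `sse` (sum over samples of
#'   the squared distance to the assigned centroid) and `centers`.
#' @export
kmeansSSE <- function(x, k, seed = 1L, nstart = 10L) {
  stopIfNot(k >= 1L && k <= nrow(x),
            "parameter error: need 1 <= k <= n samples")
  if (k == nrow(x))
    return(list(labels = seq_len(nrow(x)), sse = 0, centers = x))
  fit <- withSeed(seed, kmeansPP(x, k, nstart = nstart))
  list(labels = as.integer(fit$cluster), sse = fit$tot.withinss,
       centers = fit$centers)
}

#' Select the cluster count at the SSE elbow
#'
#' Computes the within-cluster SSE over `kRange` and selects the k with the
#' maximum discrete second difference (maximum curvature) of the SSE curve.
#' The full curve is returned for manual override; a weak curvature peak
#' (below 12% of the total SSE drop, i.e. a flat curve) flags the selection
#' as low-confidence.
#'
#' @param x numeric matrix, samples x features.
#' @param kRange ascending integer vector of candidate k (length >= 3).
#' @param seed integer seed.
#' @return an [ElbowResult-class].
#' @export
elbowSelect <- function(x, kRange = 1:14, seed = 1L) {
  stopIfNot(length(kRange) >= 3L,
            "cannot compute curvature from fewer than 3 k values")
  stopIfNot(all(diff(kRange) > 0), "kRange must be ascending")
  sse <- vapply(seq_along(kRange), function(i)
    kmeansSSE(x, kRange[i], seed = seed + i)$sse, numeric(1))
  n <- length(sse)
  d2 <- sse[1:(n - 2)] - 2 * sse[2:(n - 1)] + sse[3:n]
  pick <- which.max(d2) + 1L
  drop_ <- max(sse[1] - sse[n], .Machine$double.eps)
  low <- max(d2) < 0.12 * drop_ || max(d2) <= 0
  methods::new("ElbowResult", kValues = as.integer(kRange), sse = sse,
               selectedK = as.integer(kRange[pick]),
               lowConfidence = isTRUE(low))
}

# ---- minimal MLP (ReLU hidden layers + linear softmax head) with Adam ----

mlpInit <- function(sizes) {
  # sizes: input, hidden..., output; He initialization
  W <- list(); b <- list()
  for (l in seq_len(length(sizes) - 1L)) {
    W[[l]] <- matrix(rnorm(sizes[l] * sizes[l + 1L], 0,
                           sqrt(2 / sizes[l])), sizes[l], sizes[l + 1L])
    b[[l]] <- rep(0, sizes[l + 1L])
  }
  list(W = W, b = b)
}

mlpForward <- function(net, X) {
  L <- length(net$W)
  acts <- vector("list", L + 1L)
  acts[[1L]] <- X
  for (l in seq_len(L)) {
    z <- acts[[l]] %*% net$W[[l]] +
      matrix(net$b[[l]], nrow(X), length(net$b[[l]]), byrow = TRUE)
    acts[[l + 1L]] <- if (l < L) pmax(z, 0) else z
  }
  acts
}

softmaxCE <- function(logits, y, k) {
  m <- logits - matrixStats::rowMaxs(logits)
  p <- exp(m) / rowSums(exp(m))
  loss <- -mean(log(pmax(p[cbind(seq_along(y), y)], 1e-12)))
  grad <- p
  grad[cbind(seq_along(y), y)] <- grad[cbind(seq_along(y), y)] - 1
  list(loss = loss, grad = grad / length(y))
}

mlpTrain <- function(net, X, y, k, epochs, lr = 1e-3) {
  L <- length(net$W)
  mW <- lapply(net$W, function(w) w * 0); vW <- mW
  mB <- lapply(net$b, function(b) b * 0); vB <- mB
  b1 <- 0.9; b2 <- 0.999; epsA <- 1e-8
  lastLoss <- NA_real_
  for (ep in seq_len(epochs)) {
    acts <- mlpForward(net, X)
    sm <- softmaxCE(acts[[L + 1L]], y, k)
    if (!is.finite(sm$loss))
      stop("non-finite MLP loss: aborting deep clustering", call. = FALSE)
    lastLoss <- sm$loss
    delta <- sm$grad
    for (l in L:1) {
      gW <- t(acts[[l]]) %*% delta
      gB <- colSums(delta)
      if (l > 1L)
        delta <- (delta %*% t(net$W[[l]])) * (acts[[l]] > 0)
      mW[[l]] <- b1 * mW[[l]] + (1 - b1) * gW
      vW[[l]] <- b2 * vW[[l]] + (1 - b2) * gW^2
      mB[[l]] <- b1 * mB[[l]] + (1 - b1) * gB
      vB[[l]] <- b2 * vB[[l]] + (1 - b2) * gB^2
      mhW <- mW[[l]] / (1 - b1^ep); vhW <- vW[[l]] / (1 - b2^ep)
      mhB <- mB[[l]] / (1 - b1^ep); vhB <- vB[[l]] / (1 - b2^ep)
      net$W[[l]] <- net$W[[l]] - lr * mhW / (sqrt(vhW) + epsA)
      net$b[[l]] <- net$b[[l]] - lr * mhB / (sqrt(vhB) + epsA)
    }
  }
  net$loss <- lastLoss
  net
}

# Align `labels` to `reference` by Hungarian assignment on the contingency
# table (k-means labels are arbitrary; alignment stabilizes the training
# target across outer iterations).
alignLabels <- function(labels, reference, k) {
  tab <- matrix(0, k, k)
  for (i in seq_along(labels))
    tab[labels[i], reference[i]] <- tab[labels[i], reference[i]] + 1
  perm <- as.integer(clue::solve_LSAP(tab, maximum = TRUE))
  perm[labels]
}

# Chance-corrected agreement between two partitions.
adjustedRand <- function(a, b) {
  tab <- table(a, b)
  sumij <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2))
  bj <- sum(choose(colSums(tab), 2))
  n2 <- choose(sum(tab), 2)
  expected <- ai * bj / n2
  denom <- (ai + bj) / 2 - expected
  if (denom == 0) return(1)
  (sumij - expected) / denom
}

#' Iterative MLP + k-means deep clustering
#'
#' Alternates: (1) k-means (k-means++ with restarts) on the current
#' representation -- initially the z-scored input -- producing pseudo-labels,
#' Hungarian-aligned to the previous iteration's labels; (2) training of a
#' 3-hidden-layer ReLU MLP with a linear softmax head on
#' (features -> pseudo-labels) by full-batch Adam for `epochs` epochs;
#' (3) the new representation = z-scored activations of the last (50-unit)
#' hidden layer. Weights are warm-started across outer iterations, optimizer
#' state is re-initialized each time; the classifier head is discarded and
#' only the representation feeds k-means. Final labels are the last k-means
#' result.
#'
#' @param features numeric matrix, samples x features (row names = sample
#'   ids), or the `features` element of [generateFeatureCohort()].
#' @param k number of clusters.
#' @param hidden integer vector of the 3 hidden-layer widths.
#' @param epochs MLP epochs per outer iteration.
#' @param outerIters outer iterations.
#' @param lr Adam learning rate.
#' @param seed integer seed driving k-means inits, weight init and Adam.
#' @return a [DeepClusterResult-class].
#' @export
deepCluster <- function(features, k = 4L, hidden = c(100L, 100L, 50L),
                        epochs = 500L, outerIters = 50L, lr = 1e-3,
                        seed = 1L) {
  stopIfNot(all(is.finite(features)), "features must be finite")
  stopIfNot(nrow(features) >= k, "need at least k samples")
  sampleIds <- rownames(features)
  if (is.null(sampleIds)) sampleIds <- sprintf("S%d", seq_len(nrow(features)))
  X <- zscoreMatrix(features)
  withSeed(seed, {
    net <- mlpInit(c(ncol(X), hidden, k))
    rep_ <- X
    prev <- NULL
    sseHist <- numeric(0)
    ariHist <- numeric(0)
    labels <- NULL
    for (it in seq_len(outerIters)) {
      km <- kmeansPP(rep_, k, nstart = 10L)
      labels <- as.integer(km$cluster)
      if (!is.null(prev)) {
        labels <- alignLabels(labels, prev, k)
        ariHist <- c(ariHist, adjustedRand(labels, prev))
      }
      sseHist <- c(sseHist, km$tot.withinss)
      prev <- labels
      net <- mlpTrain(net, X, labels, k, epochs = epochs, lr = lr)
      acts <- mlpForward(net, X)
      # dead ReLU units yield constant columns; they carry no information
      # and are zeroed silently here
      rep_ <- suppressWarnings(zscoreMatrix(acts[[length(acts) - 1L]]))
      stageLog("deep_cluster", iter = it, sse = round(km$tot.withinss, 2),
               loss = round(net$loss, 4))
    }
    methods::new("DeepClusterResult", sampleIds = sampleIds,
                 labels = labels, representation = rep_,
                 sseHistory = sseHist, ariHistory = ariHist)
  })
}
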
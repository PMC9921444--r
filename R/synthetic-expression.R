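#' Generate a TPM-like expression matrix with planted cluster structure
#'
#' Draws counts gene-by-gene from a quasi-Poisson-compatible negative
#' binomial with `variance = dispersion * mean` (`dispersion = 1` collapses
#' to Poisson), multiplies the mean of each planted gene by `foldChange` in
#' exactly its one assigned cluster, and rescales every sample column to a
#' constant sum (`librarySize`, default 10^6) so values are on a TPM-like
#' scale. Gene lengths are taken equal, so the conversion is pure column
#' scaling.
#'
#' @param nSamples number of samples.
#' @param nGenes number of genes.
#' @param k number of clusters (>= 2); samples are split evenly.
#' @param nSpecificPerCluster planted cluster-specific genes per cluster
#'   (disjoint across clusters).
#' @param foldChange mean multiplier (> 1) of a planted gene in its cluster.
#' @param dispersion quasi-Poisson dispersion (>= 1).
#' @param librarySize target column sum after rescaling.
#' @param baseMeanLog mean/sd of the log-normal base expression means.
#' @param zeroGeneFrac fraction of near-silent genes (mean ~ 0.05) included
#'   so expression filtering has work to do.
#' @param seed integer seed.
#' @return list with `matrix` (a `SummarizedExperiment`, assay `"tpm"`),
#'   `true_labels` (integer vector, 1..k), `planted_genes` (list mapping
#'   cluster -> gene ids), `fold_change`, `dispersion`.
#' @export
generateExpression <- function(nSamples = 160L, nGenes = 2000L, k = 4L,
                               nSpecificPerCluster = 50L, foldChange = 4,
                               dispersion = 2, librarySize = 1e6,
                               baseMeanLog = c(mean = log(20), sd = 1.2),
                               zeroGeneFrac = 0.05, seed = 1L) {
  stopIfNot(k >= 2L, "parameter error: k must be >= 2")
  stopIfNot(nSpecificPerCluster * k <= nGenes,
            "parameter error: too many planted genes for nGenes")
  stopIfNot(foldChange > 1, "parameter error: foldChange must be > 1")
  stopIfNot(dispersion >= 1, "parameter error: dispersion must be >= 1")
  withSeed(seed, {
    labels <- rep(seq_len(k), length.out = nSamples)
    geneIds <- sprintf("GENE%05d", seq_len(nGenes))
    sampleIds <- sprintf("SAMP%04d", seq_len(nSamples))
    base <- exp(rnorm(nGenes, baseMeanLog[["mean"]], baseMeanLog[["sd"]]))
    nZero <- round(zeroGeneFrac * nGenes)
    if (nZero > 0)
      base[sample.int(nGenes, nZero)] <- 0.05
    planted <- vector("list", k)
    names(planted) <- paste0("cluster", seq_len(k))
    eligible <- which(base > 1)  # plant in expressed genes only
    pick <- sample(eligible, nSpecificPerCluster * k)
    mu <- matrix(base, nGenes, nSamples)
    for (c in seq_len(k)) {
      idx <- pick[seq_len(nSpecificPerCluster) + (c - 1L) * nSpecificPerCluster]
      planted[[c]] <- geneIds[idx]
      mu[idx, labels == c] <- mu[idx, labels == c] * foldChange
    }
    drawCounts <- function(m) {
      out <- numeric(length(m))
      pos <- m > 0
      if (dispersion == 1) out[pos] <- rpois(sum(pos), m[pos])
      else out[pos] <- rnbinom(sum(pos), size = m[pos] / (dispersion - 1),
                               mu = m[pos])
      out
    }
    counts <- matrix(drawCounts(mu), nGenes, nSamples)
    colSums <- pmax(base::colSums(counts), 1)
    tpm <- sweep(counts, 2L, colSums, "/") * librarySize
    dimnames(tpm) <- list(geneIds, sampleIds)
    se <- SummarizedExperiment::SummarizedExperiment(
      assays = list(tpm = tpm),
      colData = S4Vectors::DataFrame(true_label = labels,
                                     row.names = sampleIds))
    stageLog("generate_expression", genes = nGenes, samples = nSamples,
             planted = length(pick))
    list(matrix = se, true_labels = stats::setNames(labels, sampleIds),
         planted_genes = planted, fold_change = foldChange,
         dispersion = dispersion)
  })
}

#' Generate a synthetic 65-feature cohort with planted sample clusters
#'
#' Draws `nSamples` rows from `k` spherical Gaussian clusters in the
#' 65-dimensional morphometry feature space (unit within-cluster sd).
#' Cluster centroids are placed `separation` standard deviations apart
#' (pairwise), along random orthonormal directions so the planted signal is
#' spread over all features (per-feature standardization then preserves the
#' separation). Column names follow the frozen morphometry feature catalog.
#'
#' @param nSamples number of samples.
#' @param k number of planted clusters.
#' @param separation pairwise centroid distance in within-cluster sd units
#'   (>= 0; 0 gives exchangeable samples).
#' @param seed integer seed.
#' @return list with `features` (matrix, samples x 65, catalog column names)
#'   and `true_labels` (integer vector 1..k).
#' @export
generateFeatureCohort <- function(nSamples = 200L, k = 4L, separation = 8,
                                  seed = 1L) {
  stopIfNot(separation >= 0, "parameter error: separation must be >= 0")
  stopIfNot(k >= 1L && k <= nSamples, "parameter error: need 1 <= k <= n")
  catalog <- featureCatalog()
  p <- length(catalog)
  withSeed(seed, {
    labels <- sort(rep(seq_len(k), length.out = nSamples))
    # centroids at (separation / sqrt(2)) * q_c for random orthonormal q_c:
    # pairwise distance exactly `separation`
    Q <- qr.Q(qr(matrix(rnorm(p * k), p, k)))
    centroids <- t(Q) * separation / sqrt(2)
    x <- matrix(rnorm(nSamples * p), nSamples, p) + centroids[labels, ]
    dimnames(x) <- list(sprintf("SAMP%04d", seq_len(nSamples)), catalog)
    labels <- stats::setNames(labels, rownames(x))
    stageLog("generate_feature_cohort", samples = nSamples, k = k,
             separation = separation)
    list(features = x, true_labels = labels)
  })
}
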
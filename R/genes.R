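#' Expression filter
#'
#' Keeps a gene iff the proportion of samples with value > 0 strictly
#' exceeds `minProp`.
#'
#' @param mat genes x samples numeric matrix (TPM-like), or a
#'   `SummarizedExperiment` (first assay used).
#' @param minProp proportion threshold in `[0, 1)`.
#' @return list with `matrix` (filtered, same type as the input matrix) and
#'   `report` (`n_input_genes`, `n_retained`, `min_expr_prop`).
#' @export
filterGenes <- function(mat, minProp = 0.10) {
  stopIfNot(minProp >= 0 && minProp < 1, "minProp must lie in [0, 1)")
  vals <- if (methods::is(mat, "SummarizedExperiment"))
    SummarizedExperiment::assay(mat, 1L) else mat
  prop <- rowMeans(vals > 0)
  keep <- prop > minProp
  out <- if (methods::is(mat, "SummarizedExperiment")) mat[keep, ]
         else vals[keep, , drop = FALSE]
  report <- list(n_input_genes = nrow(vals), n_retained = sum(keep),
                 min_expr_prop = minProp)
  stageLog("filter_genes", input = report$n_input_genes,
           retained = report$n_retained)
  list(matrix = out, report = report)
}

#' Quasi-Poisson dispersion estimate for one gene
#'
#' `phi = max(1, Pearson / (n - k))` where the Pearson statistic sums
#' `(y - mu)^2 / mu` over samples whose fitted cluster mean is positive.
#' Under-dispersion is floored at 1 (treated as Poisson).
#'
#' @param y numeric vector of one gene's values across samples.
#' @param labels integer/factor cluster labels (every cluster non-empty).
#' @return numeric dispersion `phi >= 1`.
#' @export
estimateDispersion <- function(y, labels) {
  labels <- as.integer(factor(labels))
  k <- max(labels)
  mu <- tapply(y, labels, mean)[labels]
  ok <- mu > 0
  if (!any(ok)) return(1)
  pearson <- sum((y[ok] - mu[ok])^2 / mu[ok])
  max(1, pearson / (length(y) - k))
}

#' Over-expression contrast statistic T1
#'
#' Quasi-Poisson Wald contrast of the target-cluster mean against the
#' complement mean:
#' `T1 = (mu_t - mu_r) / sqrt(phi * (mu_t / n_t + mu_r / n_r))`; `T1 = 0`
#' when both means are zero. `p1` is the upper-tail standard-normal
#' probability (one-sided, over-expression).
#'
#' @param y numeric vector of one gene's values.
#' @param labels cluster labels.
#' @param t target cluster.
#' @param phi quasi-Poisson dispersion.
#' @return list with `T1` and `p1`.
#' @export
computeT1 <- function(y, labels, t, phi = 1) {
  inT <- labels == t
  stopIfNot(any(inT) && any(!inT),
            "parameter error: target cluster and complement must be non-empty")
  muT <- mean(y[inT]); muR <- mean(y[!inT])
  if (muT == 0 && muR == 0) return(list(T1 = 0, p1 = 0.5))
  se <- sqrt(phi * (muT / sum(inT) + muR / sum(!inT)))
  T1 <- (muT - muR) / se
  list(T1 = T1, p1 = stats::pnorm(T1, lower.tail = FALSE))
}

poissonDeviance <- function(y, mu) {
  term <- ifelse(y > 0, y * log(y / mu), 0)
  2 * sum(term - (y - mu))
}

#' Remaining-cluster homogeneity statistic T2
#'
#' Restricted to the samples outside the target cluster, T2 is the scaled
#' Poisson deviance difference between the one-common-mean (null) fit and
#' the per-cluster-means (full) fit: `T2 = (D_null - D_full) / phi`. Its
#' p-value is the upper tail of a chi-square with `k - 2` degrees of
#' freedom. An all-zero restriction gives `T2 = 0`, `p2 = 1`.
#'
#' @inheritParams computeT1
#' @return list with `T2` and `p2`.
#' @export
computeT2 <- function(y, labels, t, phi = 1) {
  labs <- as.integer(factor(labels))
  tt <- as.integer(factor(t, levels = levels(factor(labels))))
  k <- max(labs)
  stopIfNot(k >= 3L,
            "parameter error: T2 needs k >= 3 (at least 2 remaining clusters)")
  rest <- labs != tt
  yr <- y[rest]; lr <- labs[rest]
  if (all(yr == 0)) return(list(T2 = 0, p2 = 1))
  m0 <- mean(yr)
  mFull <- tapply(yr, lr, mean)[as.character(lr)]
  dNull <- poissonDeviance(yr, m0)
  dFull <- poissonDeviance(yr[mFull > 0], mFull[mFull > 0])
  T2 <- (dNull - dFull) / phi
  list(T2 = T2, p2 = stats::pchisq(T2, df = k - 2L, lower.tail = FALSE))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' `q_(i) = min_{j >= i} m * p_(j) / j`, capped at 1, mapped back to input
#' order.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return numeric vector of q-values.
#' @export
bhAdjust <- function(p) {
  stopIfNot(all(p >= 0 & p <= 1), "parameter error: p-values outside [0, 1]")
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

#' Identify cluster-specific genes by the dual-statistic, dual-FDR screen
#'
#' For every gene and every target cluster t, computes the quasi-Poisson
#' dispersion, the over-expression contrast T1 (with one-sided p1) and the
#' remaining-cluster homogeneity T2 (with upper-tail p2). BH adjustment is
#' applied per cluster, separately to the p1 family and the p2 family
#' (across genes). A (gene, cluster) pair is selected iff
#' `q1 < t1Fdr` and `q2 > t2Fdr` -- over-expressed in that one cluster while
#' statistically homogeneous among the rest. Genes qualifying in more than
#' one cluster are kept only in the cluster with the smallest p1 (logged);
#' within each cluster, selected genes are ranked by ascending p1.
#'
#' @param mat filtered genes x samples matrix (TPM-like) or
#'   `SummarizedExperiment`.
#' @param labels cluster labels covering all samples (k >= 3).
#' @param t1Fdr over-expression FDR gate (default 0.01).
#' @param t2Fdr homogeneity FDR gate (default 0.1).
#' @return data.frame with one row per (gene, cluster): `gene_id`,
#'   `cluster`, `T1`, `p1`, `q1`, `T2`, `p2`, `q2`, `dispersion`,
#'   `selected`, `rank` (NA when not selected).
#' @export
selectSpecificGenes <- function(mat, labels, t1Fdr = 0.01, t2Fdr = 0.1) {
  vals <- if (methods::is(mat, "SummarizedExperiment"))
    SummarizedExperiment::assay(mat, 1L) else mat
  stopIfNot(!anyNA(labels) && length(labels) == ncol(vals),
            "integrity error: every sample must carry a cluster label")
  labs <- as.integer(factor(labels))
  k <- max(labs)
  stopIfNot(k >= 3L, "parameter error: selection needs k >= 3 clusters")
  nG <- nrow(vals)
  geneIds <- rownames(vals)
  if (is.null(geneIds)) geneIds <- sprintf("G%d", seq_len(nG))
  n <- ncol(vals)
  nPer <- tabulate(labs, nbins = k)

  # vectorized per-cluster means and dispersions
  clMeans <- t(rowsum(t(vals), labs) / nPer)  # genes x k
  muFit <- clMeans[, labs, drop = FALSE]
  resid2 <- (vals - muFit)^2
  contrib <- ifelse(muFit > 0, resid2 / muFit, 0)
  phi <- pmax(1, rowSums(contrib) / (n - k))

  rows <- vector("list", k)
  for (t in seq_len(k)) {
    nT <- nPer[t]
    muT <- clMeans[, t]
    muR <- (rowSums(vals) - nT * muT) / (n - nT)
    se <- sqrt(phi * (muT / nT + muR / (n - nT)))
    T1 <- ifelse(muT == 0 & muR == 0, 0, (muT - muR) / se)
    p1 <- ifelse(muT == 0 & muR == 0, 0.5,
                 stats::pnorm(T1, lower.tail = FALSE))
    # homogeneity over the complement
    rest <- labs != t
    yr <- vals[, rest, drop = FALSE]
    lr <- labs[rest]
    restLevels <- sort(unique(lr))  # rowsum orders by sorted unique labels
    mR <- t(rowsum(t(yr), lr))      # genes x (k-1) cluster sums
    mR <- sweep(mR, 2L, tabulate(lr, nbins = k)[restLevels], "/")
    m0 <- rowMeans(yr)
    # deviance term with mu floored; where a fitted mean is 0 every y in
    # that cell is 0 and the floored term vanishes
    devTerm <- function(y, mu) {
      mu <- pmax(mu, 1e-300)
      ifelse(y > 0, y * log(y / mu), 0) - (y - mu)
    }
    muFullR <- mR[, match(lr, restLevels), drop = FALSE]
    mu0 <- matrix(m0, nrow(yr), ncol(yr))
    dFull <- 2 * rowSums(devTerm(yr, muFullR))
    dNull <- 2 * rowSums(devTerm(yr, mu0))
    T2 <- (dNull - dFull) / phi
    allZero <- rowSums(yr) == 0
    T2[allZero] <- 0
    p2 <- stats::pchisq(T2, df = k - 2L, lower.tail = FALSE)
    p2[allZero] <- 1
    rows[[t]] <- data.frame(gene_id = geneIds, cluster = t, T1 = T1,
                            p1 = p1, q1 = bhAdjust(p1), T2 = T2, p2 = p2,
                            q2 = bhAdjust(p2), dispersion = phi,
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, rows)
  res$selected <- res$q1 < t1Fdr & res$q2 > t2Fdr
  # a gene qualifying in several clusters stays with its smallest p1
  sel <- res[res$selected, ]
  dup <- unique(sel$gene_id[duplicated(sel$gene_id)])
  if (length(dup)) {
    stageLog("select_specific_genes", multi_cluster_dropped = length(dup))
    for (g in dup) {
      idx <- which(res$gene_id == g & res$selected)
      keepIdx <- idx[which.min(res$p1[idx])]
      res$selected[setdiff(idx, keepIdx)] <- FALSE
    }
  }
  res$rank <- NA_integer_
  for (t in seq_len(k)) {
    idx <- which(res$cluster == t & res$selected)
    if (length(idx))
      res$rank[idx[order(res$p1[idx])]] <- seq_along(idx)
  }
  stageLog("select_specific_genes", genes = nG,
           selected = sum(res$selected))
  rownames(res) <- NULL
  res
}
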
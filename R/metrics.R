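#' Dice coefficient and intersection-over-union of two binary masks
#'
#' `dice = 2|A n B| / (|A| + |B|)`; `iou = |A n B| / |A u B|`. By
#' convention (logged), both equal 1 when both masks are empty.
#'
#' @param a,b logical/binary matrices on one grid.
#' @return numeric scalar in `[0, 1]`.
#' @export
diceCoefficient <- function(a, b) {
  stopIfNot(all(dim(a) == dim(b)), "parameter error: mask shape mismatch")
  a <- a > 0; b <- b > 0
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) {
    stageLog("dice", note = "both_masks_empty_convention_1")
    return(1)
  }
  2 * sum(a & b) / (sa + sb)
}

#' @rdname diceCoefficient
#' @export
iouScore <- function(a, b) {
  stopIfNot(all(dim(a) == dim(b)), "parameter error: mask shape mismatch")
  a <- a > 0; b <- b > 0
  u <- sum(a | b)
  if (u == 0) {
    stageLog("iou", note = "both_masks_empty_convention_1")
    return(1)
  }
  sum(a & b) / u
}

# Boundary = mask pixels with at least one 8-neighbor outside the mask
# (pixels on the image frame count as boundary).
boundaryPixels <- function(mask) {
  mask <- mask > 0
  h <- nrow(mask); w <- ncol(mask)
  interior <- mask
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    shifted <- matrix(FALSE, h, w)
    rs <- seq_len(h) + dr; cs <- seq_len(w) + dc
    okR <- rs >= 1 & rs <= h; okC <- cs >= 1 & cs <= w
    shifted[okR, okC] <- mask[rs[okR], cs[okC]]
    shifted[!okR, ] <- FALSE; shifted[, !okC] <- FALSE
    interior <- interior & shifted
  }
  which(mask & !interior, arr.ind = TRUE)
}

#' Average (symmetric) Hausdorff distance between two mask boundaries
#'
#' Mean over boundary pixels of A of the Euclidean distance to B's boundary,
#' averaged symmetrically with the reverse direction. Boundaries are
#' 8-connected mask pixels adjacent to background.
#'
#' @param a,b non-empty binary masks on one grid.
#' @return numeric distance in pixels (0 iff the boundaries coincide).
#' @export
averageHausdorff <- function(a, b) {
  stopIfNot(all(dim(a) == dim(b)), "parameter error: mask shape mismatch")
  stopIfNot(any(a > 0) && any(b > 0),
            "parameter error: average Hausdorff undefined for empty masks")
  ba <- boundaryPixels(a); bb <- boundaryPixels(b)
  distTo <- function(from, toMask) {
    # exact Euclidean distance transform of the complement of the boundary
    bnd <- matrix(FALSE, nrow(a), ncol(a))
    bnd[toMask] <- TRUE
    dm <- as.matrix(EBImage::distmap(EBImage::Image((!bnd) * 1)))
    mean(dm[from])
  }
  (distTo(ba, bb) + distTo(bb, ba)) / 2
}

#' Greedy object matching between predicted and true label images
#'
#' Computes pairwise IoU between overlapping (prediction, truth) object
#' pairs and matches greedily in descending IoU, one-to-one, accepting
#' pairs with IoU >= `iouThreshold`.
#'
#' @param predLabels,trueLabels integer label matrices on one grid
#'   (0 = background).
#' @param iouThreshold acceptance threshold.
#' @return list with `pairs` (data.frame `pred`, `truth`, `iou`),
#'   `n_pred`, `n_true`, `n_matched`.
#' @export
matchObjects <- function(predLabels, trueLabels, iouThreshold = 0.5) {
  stopIfNot(all(dim(predLabels) == dim(trueLabels)),
            "parameter error: label image shape mismatch")
  predIds <- setdiff(sort(unique(as.vector(predLabels))), 0L)
  trueIds <- setdiff(sort(unique(as.vector(trueLabels))), 0L)
  both <- predLabels > 0 & trueLabels > 0
  ov <- table(pred = predLabels[both], truth = trueLabels[both])
  predArea <- tabulate(predLabels[predLabels > 0], nbins = max(predLabels, 1))
  trueArea <- tabulate(trueLabels[trueLabels > 0], nbins = max(trueLabels, 1))
  cand <- which(ov > 0, arr.ind = TRUE)
  if (nrow(cand)) {
    pi_ <- as.integer(rownames(ov))[cand[, 1]]
    ti <- as.integer(colnames(ov))[cand[, 2]]
    inter <- ov[cand]
    iou <- inter / (predArea[pi_] + trueArea[ti] - inter)
    ord <- order(iou, decreasing = TRUE)
    usedP <- logical(max(predLabels, 1)); usedT <- logical(max(trueLabels, 1))
    keep <- logical(length(ord))
    for (i in ord) {
      if (iou[i] < iouThreshold) next
      if (usedP[pi_[i]] || usedT[ti[i]]) next
      usedP[pi_[i]] <- TRUE; usedT[ti[i]] <- TRUE
      keep[i] <- TRUE
    }
    pairs <- data.frame(pred = pi_[keep], truth = ti[keep], iou = iou[keep])
  } else {
    pairs <- data.frame(pred = integer(0), truth = integer(0),
                        iou = numeric(0))
  }
  list(pairs = pairs, n_pred = length(predIds), n_true = length(trueIds),
       n_matched = nrow(pairs))
}
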
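# H&E optical-density vectors (Ruifrok-Johnston), rows = stains, unit norm.
heStainMatrix <- function() {
  h <- c(0.65, 0.70, 0.29)
  e <- c(0.07, 0.99, 0.11)
  r <- c(h[2] * e[3] - h[3] * e[2],
         h[3] * e[1] - h[1] * e[3],
         h[1] * e[2] - h[2] * e[1])
  m <- rbind(hematoxylin = h / sqrt(sum(h^2)),
             eosin = e / sqrt(sum(e^2)),
             residual = r / sqrt(sum(r^2)))
  colnames(m) <- c("R", "G", "B")
  m
}

# Render per-pixel hematoxylin/eosin concentration fields to 8-bit RGB via
# Beer-Lambert: I_c = 255 * 10^(-OD_c), OD = h*H + e*E.
renderHE <- function(h, e, stains = heStainMatrix()) {
  n <- length(h)
  od <- cbind(as.vector(h), as.vector(e)) %*% stains[1:2, , drop = FALSE]
  img <- array(0L, dim = c(nrow(h), ncol(h), 3L))
  for (c in 1:3) {
    plane <- round(255 * 10^(-od[, c]))
    img[, , c] <- matrix(pmin(pmax(plane, 0), 255), nrow(h), ncol(h))
  }
  storage.mode(img) <- "integer"
  img
}

# Four-region tissue layout: wavy quadrants. 0 background (top-left),
# 1 adipose (top-right), 2 connective (bottom-left), 3 glandular
# (bottom-right).
tissueLayout <- function(size) {
  rows <- matrix(seq_len(size), size, size)
  cols <- matrix(seq_len(size), size, size, byrow = TRUE)
  vsplit <- size / 2 + 0.04 * size * sin(2 * pi * rows / size * 1.5)
  hsplit <- size / 2 + 0.04 * size * cos(2 * pi * cols / size * 1.5)
  map <- matrix(0L, size, size)
  top <- rows <= hsplit
  left <- cols <= vsplit
  map[top & !left] <- 1L
  map[!top & left] <- 2L
  map[!top & !left] <- 3L
  map
}

#' Generate a ground-truthed synthetic H&E-like tile
#'
#' Renders an RGB tile partitioned into four tissue regions with distinct
#' color/texture statistics (background: near-white; adipose: bright,
#' low-texture; connective: pink, fibrous stripes; glandular: nucleus-dense
#' stroma), with elliptical hematoxylin-toned nuclei planted inside the
#' glandular region. A `clumpFraction` of the nuclei is placed overlapping a
#' neighbor (centers closer than the sum of semi-minor axes) to exercise
#' declumping. Rendering uses the standard H&E optical-density vectors, so
#' stain unmixing is exercised realistically.
#'
#' @param size tile side in pixels (>= 64).
#' @param nNuclei number of nuclei to plant.
#' @param nucleusSizeRange range of the semi-major axis in pixels.
#' @param eccentricityRange range of nucleus eccentricity in `[0, 1)`.
#' @param intensityParams list with `mean` and `sd` of the per-nucleus
#'   hematoxylin concentration (OD units).
#' @param clumpFraction fraction of nuclei placed overlapping a neighbor.
#' @param noiseSd per-pixel Gaussian noise sd, OD units.
#' @param seed integer seed; identical seeds give bit-identical tiles.
#' @return a [SyntheticTile-class] object.
#' @export
generateTile <- function(size = 512L, nNuclei = 50L,
                         nucleusSizeRange = c(4, 7),
                         eccentricityRange = c(0, 0.6),
                         intensityParams = list(mean = 0.9, sd = 0.08),
                         clumpFraction = 0.3, noiseSd = 0.02, seed = 1L) {
  stopIfNot(size >= 64L, "tile size must be >= 64")
  stopIfNot(diff(range(nucleusSizeRange)) >= 0 && min(nucleusSizeRange) > 1,
            "nucleusSizeRange must be positive")
  stopIfNot(min(eccentricityRange) >= 0 && max(eccentricityRange) < 1,
            "eccentricityRange must lie in [0, 1)")
  stopIfNot(clumpFraction >= 0 && clumpFraction <= 1,
            "clumpFraction must lie in [0, 1]")
  withSeed(seed, {
    map <- tissueLayout(size)

    # base concentration fields per class
    h <- matrix(0, size, size); e <- matrix(0, size, size)
    e[map == 0L] <- 0.015
    e[map == 1L] <- 0.18; h[map == 1L] <- 0.02
    rows <- matrix(seq_len(size), size, size)
    cols <- matrix(seq_len(size), size, size, byrow = TRUE)
    # fibrous stripes with a ~7.5 px wavelength: shorter than the robust
    # statistics window, so connective reads as one high-spread texture
    # class rather than splitting on stripe phase
    fib <- 0.14 * sin((rows + cols) / 1.2)
    e[map == 2L] <- 0.60 + fib[map == 2L]; h[map == 2L] <- 0.06
    e[map == 3L] <- 0.40; h[map == 3L] <- 0.10

    # feasible nucleus centers: glandular pixels with margin >= max semi-axis
    maxAx <- max(nucleusSizeRange)
    gl <- map == 3L
    dm <- EBImage::distmap(EBImage::Image(gl * 1))
    feasible <- which(as.matrix(dm) > maxAx + 1)

    labels <- matrix(0L, size, size)
    normRad <- matrix(Inf, size, size)
    params <- data.frame(id = integer(0), row = numeric(0), col = numeric(0),
                         a = numeric(0), b = numeric(0), theta = numeric(0),
                         hema = numeric(0), clumped = logical(0))
    nClump <- round(clumpFraction * nNuclei)
    nSolo <- nNuclei - nClump
    if (nNuclei > 0L && nSolo == 0L) { nSolo <- 1L; nClump <- nNuclei - 1L }
    maxAttempts <- 4000L

    placeOne <- function(center, a, b, theta, id, hema) {
      rr <- max(1L, floor(center[1] - a)):min(size, ceiling(center[1] + a))
      cc <- max(1L, floor(center[2] - a)):min(size, ceiling(center[2] + a))
      dr <- outer(rr - center[1], rep(1, length(cc)))
      dc <- outer(rep(1, length(rr)), cc - center[2])
      u <- (dr * cos(theta) + dc * sin(theta)) / a
      v <- (-dr * sin(theta) + dc * cos(theta)) / b
      nr <- u^2 + v^2
      inside <- nr <= 1
      sub <- cbind(rep(rr, times = length(cc))[inside],
                   rep(cc, each = length(rr))[inside])
      win <- normRad[sub] > nr[inside]
      take <- sub[win, , drop = FALSE]
      labels[take] <<- id
      normRad[take] <<- nr[inside][win]
      h[sub] <<- pmax(h[sub], hema)
      e[sub] <<- pmin(e[sub], 0.12)
    }

    if (nNuclei > 0) {
      # solo nuclei: enforced clearance so components stay separate
      centers <- matrix(NA_real_, nNuclei, 2L)
      axesA <- numeric(nNuclei); axesB <- numeric(nNuclei)
      thetas <- numeric(nNuclei); hemas <- numeric(nNuclei)
      clumped <- logical(nNuclei)
      placed <- 0L
      for (i in seq_len(nSolo)) {
        ok <- FALSE
        for (att in seq_len(maxAttempts)) {
          if (!length(feasible)) break
          px <- feasible[sample.int(length(feasible), 1L)]
          ctr <- c((px - 1L) %% size + 1L, (px - 1L) %/% size + 1L)
          a <- runif(1, nucleusSizeRange[1], nucleusSizeRange[2])
          if (placed == 0L ||
              all(sqrt(rowSums(sweep(centers[seq_len(placed), , drop = FALSE],
                                     2, ctr)^2)) >
                  a + axesA[seq_len(placed)] + 3)) {
            ecc <- runif(1, eccentricityRange[1], eccentricityRange[2])
            b <- a * sqrt(1 - ecc^2)
            placed <- placed + 1L
            centers[placed, ] <- ctr
            axesA[placed] <- a; axesB[placed] <- b
            thetas[placed] <- runif(1, 0, pi)
            hemas[placed] <- max(0.3, rnorm(1, intensityParams$mean,
                                            intensityParams$sd))
            clumped[placed] <- FALSE
            ok <- TRUE
            break
          }
        }
        if (!ok)
          stop("tile generation error: cannot place ", nNuclei,
               " nuclei without exceeding the overlap budget; ",
               "try fewer nuclei or a larger tile", call. = FALSE)
      }
      # clumped nuclei: overlap one existing solo partner
      for (i in seq_len(nClump)) {
        ok <- FALSE
        for (att in seq_len(maxAttempts)) {
          j <- sample.int(nSolo, 1L)
          a <- runif(1, nucleusSizeRange[1], nucleusSizeRange[2])
          ecc <- runif(1, eccentricityRange[1], eccentricityRange[2])
          b <- a * sqrt(1 - ecc^2)
          ang <- runif(1, 0, 2 * pi)
          d <- runif(1, 0.8, 0.98) * (b + axesB[j])
          ctr <- centers[j, ] + d * c(cos(ang), sin(ang))
          if (any(ctr < maxAx + 2) || any(ctr > size - maxAx - 1)) next
          if (!gl[round(ctr[1]), round(ctr[2])]) next
          dmv <- as.matrix(dm)[round(ctr[1]), round(ctr[2])]
          if (dmv <= a + 1) next
          others <- setdiff(seq_len(placed), j)
          if (length(others) &&
              any(sqrt(rowSums(sweep(centers[others, , drop = FALSE],
                                     2, ctr)^2)) <=
                  a + axesA[others] + 3)) next
          placed <- placed + 1L
          centers[placed, ] <- ctr
          axesA[placed] <- a; axesB[placed] <- b
          thetas[placed] <- runif(1, 0, pi)
          hemas[placed] <- max(0.3, rnorm(1, intensityParams$mean,
                                          intensityParams$sd))
          clumped[placed] <- TRUE
          ok <- TRUE
          break
        }
        if (!ok)
          stop("tile generation error: cannot place clumped nuclei; ",
               "try fewer nuclei or a lower clump fraction", call. = FALSE)
      }
      for (i in seq_len(placed))
        placeOne(centers[i, ], axesA[i], axesB[i], thetas[i], i, hemas[i])
      params <- data.frame(id = seq_len(placed), row = centers[, 1],
                           col = centers[, 2], a = axesA, b = axesB,
                           theta = thetas, hema = hemas, clumped = clumped)
    }

    h <- pmax(h + matrix(rnorm(size * size, 0, noiseSd), size, size), 0)
    e <- pmax(e + matrix(rnorm(size * size, 0, noiseSd), size, size), 0)
    img <- renderHE(h, e)
    stageLog("generate_tile", size = size, nuclei = nrow(params),
             clumped = sum(params$clumped))
    methods::new("SyntheticTile", image = img, tissueMap = map,
                 nucleusLabels = labels, nucleusParams = params)
  })
}
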
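test_that("the expression filter applies the strict >10% rule", {
  mk <- function(nonzero, n = 100) c(rep(5, nonzero), rep(0, n - nonzero))
  m <- rbind(g1 = mk(5), g2 = mk(11))
  colnames(m) <- sprintf("s%d", 1:100)
  fl <- filterGenes(m, 0.10)
  expect_equal(rownames(fl$matrix), "g2")
  expect_equal(fl$report$n_input_genes, 2L)
  expect_equal(fl$report$n_retained, 1L)

  # designed nonzero proportions 20%, 10%, 10.5%, 0%, 100%, 9% of 200
  props <- c(0.20, 0.10, 0.105, 0, 1, 0.09)
  m2 <- t(vapply(props, function(p) mk(round(p * 200), 200), numeric(200)))
  rownames(m2) <- sprintf("g%d", 1:6)
  fl2 <- filterGenes(m2, 0.10)
  expect_equal(fl2$report$n_retained, 3L)
  expect_setequal(rownames(fl2$matrix), c("g1", "g3", "g5"))
})

test_that("dispersion estimation respects the quasi-Poisson moment identity", {
  set.seed(61)
  labs <- rep(1:4, each = 2500)
  yP <- stats::rpois(10000, 30)
  expect_equal(estimateDispersion(yP, labs), 1, tolerance = 0.05)

  yNB <- stats::rnbinom(10000, size = 30 / 2, mu = 30)  # var = 3 x mean
  expect_equal(estimateDispersion(yNB, labs), 3, tolerance = 0.1)

  expect_equal(estimateDispersion(rep(7, 40), rep(1:4, 10)), 1)
  expect_equal(estimateDispersion(rep(0, 40), rep(1:4, 10)), 1)
})

test_that("T1 detects planted over-expression and agrees with a permutation test", {
  labs <- rep(1:4, each = 25)
  # identical values: zero contrast
  flat <- computeT1(rep(12, 100), labs, 1, phi = 1)
  expect_equal(flat$T1, 0)
  expect_equal(flat$p1, 0.5)

  set.seed(62)
  y <- stats::rpois(100, 10)
  y[labs == 2] <- stats::rpois(25, 40)
  phi <- estimateDispersion(y, labs)
  t1 <- computeT1(y, labs, 2, phi)
  expect_gt(t1$T1, 0)
  expect_lt(t1$p1, 1e-6)

  # permutation oracle: observed contrast never reached under relabeling
  obs <- mean(y[labs == 2]) - mean(y[labs != 2])
  perm <- replicate(2000, {
    l <- sample(labs)
    mean(y[l == 2]) - mean(y[l != 2])
  })
  expect_equal(mean(perm >= obs), 0)

  expect_error(computeT1(y, labs, 9, 1), "non-empty")
})

test_that("T2 passes homogeneous complements and fails heterogeneous ones", {
  labs <- rep(1:4, each = 25)
  # remaining clusters share one mean exactly
  y <- rep(c(50, 20, 20, 20), each = 25)
  t2 <- computeT2(y, labs, 1, phi = 1)
  expect_equal(t2$T2, 0)
  expect_equal(t2$p2, 1)

  # remaining clusters at means 10/10/40: homogeneity must fail
  set.seed(63)
  y2 <- c(stats::rpois(25, 30), stats::rpois(25, 10), stats::rpois(25, 10),
          stats::rpois(25, 40))
  phi <- estimateDispersion(y2, labs)
  t2b <- computeT2(y2, labs, 1, phi)
  expect_lt(t2b$p2, 1e-6)

  # permutation oracle within the complement: observed deviance gap extreme
  rest <- labs != 1
  obsGap <- t2b$T2
  permGap <- replicate(500, {
    l <- labs; l[rest] <- sample(l[rest])
    computeT2(y2, l, 1, phi)$T2
  })
  expect_lt(mean(permGap >= obsGap), 0.01)

  expect_error(computeT2(y2, rep(1:2, 50), 1, 1), "k >= 3")
  expect_equal(computeT2(c(rep(9, 25), rep(0, 75)), labs, 1, 1)$p2, 1)
})

test_that("BH adjustment equals the brute-force suffix-min oracle", {
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bhAdjust(rep(0.2, 5)), rep(0.2, 5))
  expect_error(bhAdjust(c(0.5, 1.2)), "parameter")

  set.seed(64)
  for (rep in 1:100) {
    p <- stats::runif(sample(3:40, 1))
    q <- bhAdjust(p)
    expect_equal(q, bruteBH(p))
    expect_true(all(q >= p - 1e-12))
    expect_true(all(diff(q[order(p)]) >= -1e-12))  # monotone in p
  }
})

test_that("the dual-gate screen is order-invariant and null-safe", {
  set.seed(65)
  labs <- rep(1:4, each = 20)
  m <- matrix(stats::rpois(400 * 80, 15), 400, 80,
              dimnames = list(sprintf("g%03d", 1:400),
                              sprintf("s%03d", 1:80)))
  res <- selectSpecificGenes(m, labs)
  # null matrix: at most ~1% of genes selected per cluster
  perCluster <- tapply(res$selected, res$cluster, mean)
  expect_true(all(perCluster <= 0.01))

  # gene- and sample-order invariance
  gp <- sample(400); sp <- sample(80)
  res2 <- selectSpecificGenes(m[gp, sp], labs[sp])
  res2 <- res2[order(match(res2$gene_id, res$gene_id), res2$cluster), ]
  res0 <- res[order(match(res$gene_id, res$gene_id), res$cluster), ]
  expect_equal(res2$T1, res0$T1, tolerance = 1e-9)
  expect_equal(res2$q1, res0$q1, tolerance = 1e-9)
  expect_equal(res2$selected, res0$selected)

  expect_error(selectSpecificGenes(m, labs[-1]), "integrity")
})

test_that("scaling all samples by c > 0 scales T1 by sqrt(c)", {
  set.seed(66)
  labs <- rep(1:4, each = 25)
  # overdispersed gene so the dispersion floor at 1 never binds
  y <- stats::rnbinom(100, size = 10, mu = 20)
  y[labs == 3] <- stats::rnbinom(25, size = 10, mu = 45)
  phi <- estimateDispersion(y, labs)
  expect_gt(phi, 1)
  for (cc in c(4, 9)) {
    # at fixed dispersion the Wald contrast scales exactly by sqrt(c)
    t1a <- computeT1(y, labs, 3, phi)
    t1b <- computeT1(cc * y, labs, 3, phi)
    expect_equal(t1b$T1 / t1a$T1, sqrt(cc), tolerance = 1e-9)
    # under the refitted dispersion the homogeneity p-value is stable
    t2a <- computeT2(y, labs, 3, phi)
    t2b <- computeT2(cc * y, labs, 3, estimateDispersion(cc * y, labs))
    expect_equal(t2b$p2, t2a$p2, tolerance = 0.05)
  }
})

test_that("a gene planted in two clusters is excluded by the homogeneity gate", {
  set.seed(67)
  labs <- rep(1:4, each = 30)
  m <- matrix(stats::rpois(300 * 120, 20), 300, 120,
              dimnames = list(sprintf("g%03d", 1:300),
                              sprintf("s%03d", 1:120)))
  m["g001", labs %in% c(1, 2)] <- stats::rpois(60, 80)
  res <- selectSpecificGenes(m, labs)
  expect_false(any(res$selected[res$gene_id == "g001"]))
})
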
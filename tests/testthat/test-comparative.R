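test_that("phylogenetic covariance matches path-length enumeration", {
  star <- ape::stree(4, type = "star")
  star$edge.length <- rep(1, 4)
  for (lam in c(0, 0.5, 1)) {
    V <- phyloCovariance(star, lam)
    expect_equal(unname(diag(V)), rep(1, 4))
    expect_true(all(V[upper.tri(V)] == 0))
  }
  sisters <- ape::read.tree(text = "((A:0.4,B:0.4):0.6,C:1.0);")
  expect_equal(phyloCovariance(sisters, 0.5)["A", "B"], 0.6 * 0.5)
  expect_equal(phyloCovariance(sisters, 1)["A", "A"], 1)

  tr <- simulatePhylogeny(16, seed = 12)
  V1 <- phyloCovariance(tr, 1)
  Vb <- bruteForceVCV(tr)[rownames(V1), colnames(V1)]
  expect_equal(V1, Vb, tolerance = 1e-12)
  # lambda acts linearly on the off-diagonal only
  V5 <- phyloCovariance(tr, 0.5)
  expect_equal(diag(V5), diag(V1))
  expect_equal(V5[1, 2], 0.5 * V1[1, 2])
  expect_error(phyloCovariance(ape::unroot(tr), 1), "rooted")
})

test_that("Blomberg's K equals its direct formula and external oracle", {
  tr <- fixedQuartet()
  y <- c(A = 1.2, B = 0.9, C = -0.4, D = -0.1)
  expect_equal(blombergK(tr, y), bruteForceK(tr, y), tolerance = 1e-10)
  skip_if_not_installed("picante")
  expect_equal(blombergK(tr, y),
               as.numeric(picante::Kcalc(y[tr$tip.label], tr)),
               tolerance = 1e-8)
  tr2 <- simulatePhylogeny(20, seed = 8)
  y2 <- simulateTraitsBM(tr2, seed = 9)
  expect_equal(blombergK(tr2, y2),
               as.numeric(picante::Kcalc(y2[tr2$tip.label], tr2)),
               tolerance = 1e-8)
  expect_error(blombergK(tr, c(A = 1, B = 1, C = 1, D = 1)), "constant")
})

test_that("K centres near 1 under Brownian motion and drops for iid traits", {
  tr <- simulatePhylogeny(32, seed = 42)
  kBM <- vapply(1:100, function(i)
    blombergK(tr, simulateTraitsBM(tr, lambda = 1, seed = i)), numeric(1))
  expect_gt(mean(kBM), 0.8)
  expect_lt(mean(kBM), 1.2)
  kIID <- vapply(1:100, function(i)
    blombergK(tr, simulateTraitsBM(tr, lambda = 0, seed = 7000 + i)),
    numeric(1))
  expect_lt(mean(kIID), 0.5)
})

test_that("the K permutation test is valid and reproducible", {
  tr <- simulatePhylogeny(24, seed = 3)
  y <- simulateTraitsBM(tr, lambda = 1, seed = 4)
  r1 <- signalPermutationTest(tr, y, nPerm = 199, seed = 10)
  r2 <- signalPermutationTest(tr, y, nPerm = 199, seed = 10)
  expect_identical(r1, r2)
  expect_gte(r1$p, 1 / 200)
  expect_lte(r1$p, 1)
  # strong signal on a deep tree should be detected
  expect_lt(r1$p, 0.05)
})

test_that("Pagel's lambda ML is a true profile maximum and matches phytools", {
  tr <- simulatePhylogeny(32, seed = 5)
  y <- simulateTraitsBM(tr, lambda = 0.7, seed = 6)
  pl <- pagelLambda(tr, y)
  expect_gte(pl$loglik, pl$loglik0 - 1e-9)
  V1 <- phyloCovariance(tr, 1)
  expect_gte(pl$lambda, 0); expect_lte(pl$lambda, 1)
  skip_if_not_installed("phytools")
  ps <- phytools::phylosig(tr, y, method = "lambda", test = TRUE)
  expect_equal(pl$lambda, ps$lambda, tolerance = 5e-3)
  # our profile optimum is never worse than the external one
  expect_gte(pl$loglik, ps$logL - 1e-6)
  expect_equal(pl$loglik, ps$logL, tolerance = 1e-4)
  expect_equal(pl$p, ps$P, tolerance = 1e-3)
})

test_that("phyloSignal bundles K and lambda coherently", {
  tr <- simulatePhylogeny(24, seed = 13)
  y <- simulateTraitsBM(tr, lambda = 1, seed = 14)
  res <- phyloSignal(tr, y, nPerm = 199, seed = 2, traitName = "demo")
  expect_s4_class(res, "PhyloSignalResult")
  expect_equal(res@k, blombergK(tr, y))
  expect_equal(res@lambdaHat, pagelLambda(tr, y)$lambda)
})

test_that("Pearson correlation and Bonferroni behave at the edges", {
  x <- rnorm(20)
  expect_equal(pearsonCorrelation(x, x)$r, 1)
  expect_equal(pearsonCorrelation(x, -2 * x)$r, -1)
  set.seed(31)
  a <- rnorm(5000); b <- rnorm(5000)
  expect_lt(abs(pearsonCorrelation(a, b)$r), 0.05)
  expect_error(pearsonCorrelation(rep(1, 5), rnorm(5)), "constant")

  expect_equal(bonferroniAdjust(0.02, m = 2), 0.04)
  expect_equal(bonferroniAdjust(0.9, m = 2), 1)
  expect_equal(bonferroniAdjust(c(0.1, 0.4), m = 2), c(0.2, 0.8))
  expect_equal(bonferroniAdjust(0.3, m = 1), 0.3)
  expect_error(bonferroniAdjust(1.2, m = 2), "\\[0, 1\\]")
  expect_error(bonferroniAdjust(c(0.1, 0.2, 0.3), m = 2), "family size")
})

test_that("loess smoothing is locally linear with the conventional span", {
  x <- seq(-3, 3, length.out = 20)
  yLin <- 2 + 0.5 * x
  for (span in c(0.75, 1, 1.5, 3)) {
    sm <- loessSmooth(x, yLin, span = span)
    expect_equal(sm$fitted, 2 + 0.5 * sm$x, tolerance = 1e-8)
  }
  # growing span on curved data shrinks towards the global line
  yQuad <- x^2
  lmFit <- lm(yQuad ~ x)
  dev <- vapply(c(1.5, 5, 50), function(sp) {
    sm <- loessSmooth(x, yQuad, span = sp)
    max(abs(sm$fitted - predict(lmFit, data.frame(x = sm$x))))
  }, numeric(1))
  expect_true(all(diff(dev) <= 1e-6))
  # symmetry of the smooth about a symmetric design
  sm <- loessSmooth(x, yQuad, span = 1.5, gridN = 41)
  expect_equal(sm$fitted, rev(sm$fitted), tolerance = 1e-6)
  expect_error(loessSmooth(x[1:3], yLin[1:3]), "at least 4")
})

test_that("climate PCA satisfies its algebraic identities", {
  cl <- simulateClimate(14, seed = 20)
  pca <- climatePCA(cl)
  expect_equal(sum(varExplained(pca)), 100, tolerance = 1e-9)
  # orthonormal loadings and exact reconstruction of the processed matrix
  L <- pcaLoadings(pca)
  expect_equal(t(L) %*% L, diag(ncol(L)), tolerance = 1e-10,
               ignore_attr = TRUE)
  proc <- scale(as.matrix(cl), center = TRUE, scale = TRUE)
  expect_equal(pcaScores(pca) %*% t(L), proc, tolerance = 1e-8,
               ignore_attr = TRUE)
  # orientation convention: warmer (higher minT) means larger PC1
  expect_gt(L["minT", 1], 0)

  two <- data.frame(a = cl$MAT, b = 3 * cl$MAT + 1)
  expect_equal(varExplained(climatePCA(two))[1], 100, tolerance = 1e-9)
  degenerate <- data.frame(a = cl$MAT, b = rep(2, 14))
  expect_error(climatePCA(degenerate), "zero-variance.*b")
})
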
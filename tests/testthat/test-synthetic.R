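test_that("simulated phylogenies are ultrametric, depth-1, deterministic", {
  tr <- simulatePhylogeny(3, seed = 5)
  expect_equal(ape::Ntip(tr), 3)
  depths <- ape::node.depth.edgelength(tr)[1:3]
  expect_equal(depths, rep(1, 3), tolerance = 1e-12)

  a <- ape::write.tree(simulatePhylogeny(14, seed = 1))
  b <- ape::write.tree(simulatePhylogeny(14, seed = 1))
  expect_identical(a, b)
  expect_false(identical(a, ape::write.tree(simulatePhylogeny(14, seed = 2))))

  for (s in 1:5) expect_equal(simulatePhylogeny(64, seed = s)$Nnode, 63)
  expect_error(simulatePhylogeny(2), "nTaxa")
})

test_that("Brownian trait simulation honours sigma2, root value and lambda", {
  tr <- simulatePhylogeny(8, seed = 3)
  # vanishing rate pins every tip at the root value
  y <- simulateTraitsBM(tr, sigma2 = 1e-12, rootValue = 7, lambda = 1,
                        seed = 1)
  expect_equal(unname(y), rep(7, 8), tolerance = 1e-4)

  # lambda = 1: empirical tip covariance matches sigma2 * V (independent
  # path-length enumeration oracle) in Frobenius norm
  nrep <- 2000
  Y <- vapply(seq_len(nrep), function(i)
    simulateTraitsBM(tr, sigma2 = 2, lambda = 1, seed = i), numeric(8))
  Vhat <- cov(t(Y))
  Vtrue <- 2 * bruteForceVCV(tr)[rownames(Vhat), colnames(Vhat)]
  relFrob <- norm(Vhat - Vtrue, "F") / norm(Vtrue, "F")
  expect_lt(relFrob, 0.08)

  # lambda = 0 erases cross-tip covariance between sisters
  pair <- vapply(seq_len(nrep), function(i) {
    z <- simulateTraitsBM(tr, sigma2 = 1, lambda = 0, seed = 40000 + i)
    z[1:2]
  }, numeric(2))
  cv <- cov(pair[1, ], pair[2, ])
  se <- 1 / sqrt(nrep)  # cov SE for unit-variance independent pairs
  expect_lt(abs(cv), 3 * se)
})

test_that("climate simulation reproduces the target correlation structure", {
  idc <- diag(5); dimnames(idc) <- dimnames(defaultClimateCorr())
  cl <- simulateClimate(5000, targetCorr = idc, seed = 2)
  off <- cor(cl)[upper.tri(diag(5))]
  expect_true(all(abs(off) < 0.05))

  C <- idc
  C["minT", "maxT"] <- C["maxT", "minT"] <- 0.9
  cl2 <- simulateClimate(5000, targetCorr = C, seed = 3)
  expect_equal(cor(cl2$minT, cl2$maxT), 0.9, tolerance = 0.03)

  expect_identical(simulateClimate(14, seed = 9), simulateClimate(14, seed = 9))
  expect_named(cl, c("MAT", "MAP", "maxT", "minT", "Pdq"))

  bad <- idc; bad[1, 2] <- bad[2, 1] <- 2
  expect_error(simulateClimate(10, targetCorr = bad), "positive definite")
})

test_that("trait-climate simulation follows its linear model", {
  tr <- simulatePhylogeny(12, seed = 4)
  cl <- simulateClimate(12, seed = 4)
  # zero coefficients and vanishing noise give a zero trait
  s <- simulateTraitClimate(tr, cl, beta = c(0, 0, 0), lambdaResid = 0,
                            sigma2 = 1e-12, seed = 1)
  expect_equal(unname(traitData(s$table)$trait), rep(0, 12),
               tolerance = 1e-4)
  # determinism
  s2 <- simulateTraitClimate(tr, cl, beta = c(1, -0.5, 0.2), seed = 8)
  s3 <- simulateTraitClimate(tr, cl, beta = c(1, -0.5, 0.2), seed = 8)
  expect_identical(traitData(s2$table), traitData(s3$table))
  # iid residuals: OLS (lambda fixed at 0) recovers beta within 3 SE
  s4 <- simulateTraitClimate(tr, cl, beta = c(2, -1, 0.5), lambdaResid = 0,
                             sigma2 = 0.09, seed = 21)
  fit <- pglsFit(trait ~ pc1 + subgenus, s4$table, tr, lambda = 0)
  ct <- coefTable(fit)
  z <- abs(ct$estimate[ct$term == "pc1"] - (-1)) / ct$se[ct$term == "pc1"]
  expect_lt(z, 3)
  expect_error(
    simulateTraitClimate(simulatePhylogeny(5, 1), cl, beta = c(0, 0, 0)),
    "one row per tip")
})

test_that("drydown image stacks encode the logistic vulnerability curve", {
  expect_equal(logisticVC(-4.5, p50 = -4.5), 50)

  sim <- simulateDrydownImages(p50 = -4, height = 48, width = 48,
                               nFrames = 60, nEvents = 15,
                               sizeRange = c(4, 12), noiseSd = 0.01,
                               shrinkEvents = 5, seed = 6)
  sim2 <- simulateDrydownImages(p50 = -4, height = 48, width = 48,
                                nFrames = 60, nEvents = 15,
                                sizeRange = c(4, 12), noiseSd = 0.01,
                                shrinkEvents = 5, seed = 6)
  expect_identical(frames(sim$stack), frames(sim2$stack))

  # cumulative event area is non-decreasing and ends at the full pool
  log <- sim$truth$eventLog
  expect_true(all(diff(log$frame) >= 0))
  expect_equal(sum(log$px), sim$truth$totalPx)
  expect_true(all(log$px >= 1))

  expect_error(simulateDrydownImages(p50 = -9), "between")
  expect_error(simulateDrydownImages(p50 = -4, nFrames = 10), "nFrames")
})

test_that("mass series are monotone pre-noise and linear once stomata close", {
  sim <- simulateMassSeries(noiseSdMass = 0, seed = 1)
  for (s in sim$series) expect_true(all(diff(s@masses) < 0))
  # starting at the cuticular conductance gives an exactly linear record
  lin <- simulateMassSeries(gminRef = 5, initialStomatalG = 5,
                            slopeBelow = 0, slopeAbove = 0,
                            noiseSdMass = 0, temps = c(25, 30, 35, 40, 45),
                            seed = 1)
  for (s in lin$series) {
    d2 <- diff(diff(s@masses))
    expect_lt(max(abs(d2)), 1e-12)
  }
  # VPD -> 0 as RH -> 100 shuts the flux down
  damp <- simulateMassSeries(rh = 99.9, noiseSdMass = 0, seed = 1)
  s <- damp$series[[1]]
  expect_lt(s@masses[1] - s@masses[length(s@masses)], 1e-3)
  expect_error(simulateMassSeries(rh = 100), "rh")
  # the noisy series decrements match the noiseless ones in expectation
  noisy <- simulateMassSeries(noiseSdMass = 5e-4, seed = 2)
  clean <- simulateMassSeries(noiseSdMass = 0, seed = 2)
  for (k in seq_along(noisy$series)) {
    dn <- diff(noisy$series[[k]]@masses)
    dc <- diff(clean$series[[k]]@masses)
    # the mean decrement differs only through the two endpoint noise draws
    expect_lt(abs(mean(dn) - mean(dc)), 1e-4)
  }
})
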
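test_that("Loiselle estimator equals the exhaustive small-instance oracle", {
  x <- makeRandomDataset(5, c(3, 4), seed = 31)
  co <- loiselleCoancestry(x)
  expect_equal(thetaMatrix(co), loiselleOracle(x), tolerance = 1e-12,
               ignore_attr = TRUE)
  # with missing data too
  y <- makeRandomDataset(6, c(4, 5), seed = 32)
  a1 <- alleleCalls(y)$allele1; a2 <- alleleCalls(y)$allele2
  a1[2, 1] <- a2[2, 1] <- NA; a1[5, 2] <- a2[5, 2] <- NA
  y <- GenotypeDataset(y@info, lociNames(y), a1, a2)
  expect_equal(thetaMatrix(loiselleCoancestry(y)), loiselleOracle(y),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("theta is sample-centred, order-invariant, and ~0.25 for parent-offspring", {
  x <- makeRandomDataset(60, rep(8, 10), seed = 33)
  co <- loiselleCoancestry(x)
  off <- thetaMatrix(co)[upper.tri(thetaMatrix(co))]
  expect_lt(abs(mean(off)), 0.01)   # sample-centred estimator

  perm <- sample(nIndividuals(x))
  co2 <- loiselleCoancestry(x[perm])
  expect_equal(thetaMatrix(co2)[x@info$id[perm], x@info$id[perm]],
               thetaMatrix(co)[x@info$id[perm], x@info$id[perm]])

  # pedigree simulation: parent-offspring pairs embedded in a large
  # unrelated background
  set.seed(34)
  nb <- 150; npairs <- 40; L <- 16; k <- 8
  n <- nb + 2 * npairs
  a1 <- matrix(NA_integer_, n, L); a2 <- matrix(NA_integer_, n, L)
  for (l in seq_len(L)) {
    p <- as.numeric(rgamma(k, 1)); p <- p / sum(p)
    a1[, l] <- sample.int(k, n, TRUE, prob = p)
    a2[, l] <- sample.int(k, n, TRUE, prob = p)
    # offspring: one allele from the parent, one from the pool
    for (q in seq_len(npairs)) {
      par <- nb + q; ch <- nb + npairs + q
      a1[ch, l] <- if (runif(1) < 0.5) a1[par, l] else a2[par, l]
    }
  }
  info <- data.frame(id = paste0("i", 1:n), stage = "s",
                     x = runif(n), y = runif(n))
  ped <- GenotypeDataset(info, sprintf("L%d", 1:L), a1, a2)
  th <- thetaMatrix(loiselleCoancestry(ped))
  po <- vapply(seq_len(npairs), function(q)
    th[nb + q, nb + npairs + q], 1)
  expect_equal(mean(po), 0.25, tolerance = 0.12)
})

test_that("distance classes have equal pair counts; degenerate input errors", {
  d <- as.matrix(dist(cbind(1:20 + c(0, 0.01)[1 + (1:20 %% 2)], 0)))
  # 20 points -> 190 pairs; use a 5-point case for the exact count check
  d5 <- as.matrix(dist(cbind(c(0, 1, 3, 7, 15), 0)))  # 10 distinct pairs
  b <- distanceClasses(d5, 10)
  cls <- findInterval(d5[upper.tri(d5)], b, left.open = TRUE) + 1L
  expect_equal(unname(tabulate(cls, 10)), rep(1L, 10))

  sq <- as.matrix(dist(rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1))))
  expect_error(distanceClasses(sq, 10), "distinct")
  same <- matrix(1, 4, 4); diag(same) <- 0
  expect_error(distanceClasses(same, 3), "distinct|degenerate")
})

test_that("correlogram envelope covers a null by construction and detects structure", {
  sim <- makeStudySim(seed = 36, nOffspring = 40)
  x <- subsetStage(sim$data, "reproductive")
  co <- loiselleCoancestry(x)
  D <- pairwiseDistances(x)
  # permuted coordinates: null by construction
  set.seed(37)
  p <- sample(nIndividuals(x))
  Dp <- D[p, p]; dimnames(Dp) <- dimnames(D)
  corr <- sgsCorrelogram(co, Dp, nPerm = 500, seed = 38)
  expect_gte(mean(!corr$significant), 0.8)
  expect_equal(sum(corr$nPairs), choose(nIndividuals(x), 2))
  expect_true(all(diff(corr$upper) > 0))

  # restricted seed dispersal in a 300 m plot: first-class theta positive
  cfg <- simulationConfig(plotWidth = 300, plotHeight = 300, nAdults = 40,
                          nOffspring = 120, s = 0, mp = 0,
                          seedKernel = KernelParams(15, 1),
                          pollenKernel = KernelParams(60, 1),
                          errorRate = 0, missingRate = 0, seed = 39)
  sim2 <- simulatePopulation(cfg)
  offs <- sim2$data[which(stages(sim2$data) != "reproductive")]
  co2 <- loiselleCoancestry(offs)
  D2 <- pairwiseDistances(offs)
  corr2 <- sgsCorrelogram(co2, D2, nPerm = 500, seed = 40)
  expect_gt(corr2$theta[1], corr2$hi[1])
})

test_that("Sp identity holds exactly and the slope test behaves", {
  expect_equal(spFromSlope(0, 0.02), 0)
  sim <- makeStudySim(seed = 41, nOffspring = 30)
  x <- subsetStage(sim$data, "reproductive")
  co <- loiselleCoancestry(x)
  D <- pairwiseDistances(x)
  sp <- spStatistic(co, D, nPerm = 300, seed = 42)
  expect_identical(sp$Sp, -sp$bk / (1 - sp$theta1))
  expect_gte(sp$bk_p, 0)
  expect_lte(sp$bk_p, 1)

  # strong isolation by distance gives a significantly negative slope
  cfg <- simulationConfig(plotWidth = 300, plotHeight = 300, nAdults = 40,
                          nOffspring = 160, s = 0, mp = 0,
                          seedKernel = KernelParams(12, 1),
                          pollenKernel = KernelParams(50, 1),
                          errorRate = 0, missingRate = 0, seed = 43)
  sim2 <- simulatePopulation(cfg)
  offs <- sim2$data[which(stages(sim2$data) != "reproductive")]
  sp2 <- spStatistic(loiselleCoancestry(offs), pairwiseDistances(offs),
                     nPerm = 300, seed = 44)
  expect_lt(sp2$bk, 0)
  expect_lt(sp2$bk_p, 0.05)
  expect_gt(sp2$Sp, 0)
})
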
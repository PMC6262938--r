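mkFreqTable <- function(freqList, nInd = 50L) {
  gc <- setNames(rep(as.integer(2 * nInd), length(freqList)), names(freqList))
  new("AlleleFrequencyTable", freqs = freqList, geneCounts = gc,
      sampleSizes = setNames(rep(as.integer(nInd), length(freqList)),
                             names(freqList)))
}

test_that("pair exclusion probability matches exhaustive enumeration", {
  # monomorphic locus contributes nothing
  f <- mkFreqTable(list(L1 = c(`1` = 1.0)))
  expect_equal(exclusionProbabilityPairs(f)$Pp, 0)

  for (p in list(c(0.5, 0.5), c(0.2, 0.3, 0.5), c(0.1, 0.2, 0.3, 0.4))) {
    names(p) <- seq_along(p)
    f <- mkFreqTable(list(L1 = p))
    expect_equal(unname(exclusionProbabilityPairs(f)$perLocus["L1"]),
                 enumPairExclusion(unname(p)), tolerance = 1e-12)
  }
  # multilocus combination
  p1 <- c(`1` = 0.5, `2` = 0.5); p2 <- c(`1` = 0.2, `2` = 0.3, `3` = 0.5)
  f <- mkFreqTable(list(L1 = p1, L2 = p2))
  Q <- exclusionProbabilityPairs(f)$perLocus
  expect_equal(exclusionProbabilityPairs(f)$Pp, 1 - prod(1 - Q))
})

test_that("LOD scores reproduce hand transition probabilities and exclusions", {
  info <- data.frame(id = c("off", "c1", "c2"), stage = c("o", "cand", "cand"),
                     x = c(0, 1, 2), y = 0)
  # locus with p(A)=p(C)=0.5; offspring A/B impossible from C/C at e=0
  x <- GenotypeDataset(info, "L1",
                       matrix(c(1L, 1L, 3L), 3), matrix(c(2L, 1L, 3L), 3))
  f <- mkFreqTable(list(L1 = c(`1` = 0.5, `3` = 0.5)))
  res <- lodScores("off", x, c("c1", "c2"), f, errorRate = 0)
  expect_identical(res$lodSingle[["c2"]], -Inf)
  expect_identical(res$mmSingle[[2]], 1L)

  # offspring A/A, candidate A/A, p(A) = 0.5: single-parent LOD = ln 2
  y <- GenotypeDataset(info, "L1",
                       matrix(c(1L, 1L, 3L), 3), matrix(c(1L, 1L, 3L), 3))
  res <- lodScores("off", y, c("c1", "c2"), f, errorRate = 0)
  expect_equal(res$lodSingle[["c1"]], log(2))
  # pair (c1, c1) = selfing: T = 1, HWE prob = 0.25 -> LOD = ln 4
  expect_equal(res$lodPair["c1", "c1"], log(4))
})

test_that("the true father attains the top LOD in simulated trios", {
  set.seed(81)
  sim <- simulatePopulation(simulationConfig(
    nAdults = 50, nOffspring = 60, s = 0, mp = 0,
    errorRate = 0.01, missingRate = 0, seed = 82))
  f <- alleleFrequencies(sim$data)
  cand <- sim$data@info$id[stages(sim$data) == "reproductive"]
  hits <- vapply(seq_len(60), function(k) {
    oid <- sim$truth$offspring[k]
    res <- lodScores(oid, sim$data, cand, f, errorRate = 0.01)
    best <- cand[which.max(res$lodSingle)]
    best %in% c(sim$truth$father[k], sim$truth$mother[k])
  }, TRUE)
  expect_gte(mean(hits), 0.95)
})

test_that("the Delta criterion is deterministic, shrinks with full sampling, and calibrates", {
  sim <- makeStudySim(seed = 83, nOffspring = 20)
  f <- alleleFrequencies(sim$data)
  m1 <- parentageModel(nSim = 300, propSampled = 1, errorRate = 0)
  d1 <- simulateDeltaCriterion(m1, f, nCandidates = 59, seed = 84)
  d1b <- simulateDeltaCriterion(m1, f, nCandidates = 59, seed = 84)
  expect_identical(d1$criticalDelta, d1b$criticalDelta)
  # all parents sampled, no error, 18 informative loci: near-certain assignment
  expect_lt(d1$criticalDelta, 1)
  expect_gt(d1$successRate, 0.95)

  # held-out calibration: correctness above the threshold on an independent
  # test set reaches the stated confidence (within Monte Carlo error)
  m2 <- parentageModel(nSim = 500, propSampled = 0.6, errorRate = 0.01,
                       confidence = 0.80)
  crit <- simulateDeltaCriterion(m2, f, nCandidates = 40, seed = 85)
  held <- simulateDeltaCriterion(m2, f, nCandidates = 40, seed = 87,
                                 details = TRUE)
  above <- held$deltas >= crit$criticalDelta
  expect_gt(sum(above), 50)
  expect_gte(mean(held$correct[above]), 0.75)
})

test_that("gene-flow rates are exact count ratios and partition the offspring", {
  s <- geneFlowSummary(total = 189, bothParents = 107, selfed = 8,
                       noParent = 7, nCandidates = 59, nParticipating = 49)
  expect_identical(s$noFather, 189L - 107L - 8L)
  expect_identical(s$s, 8 / 189)
  expect_identical(s$mp, 74 / 189)
  expect_identical(s$seedImmigration, 7 / 189)
  expect_identical(s$propAtLeastOneParent, 182 / 189)
  expect_identical(s$bothParents + s$selfed + s$noFather, s$total)
  expect_error(geneFlowSummary(10, 8, 3, 0), "")
})

test_that("error-free assignment has zero mismatches and low cryptic flow", {
  cfg <- simulationConfig(nAdults = 40, nOffspring = 80, s = 0.05, mp = 0,
                          errorRate = 0, missingRate = 0, seed = 91)
  sim <- simulatePopulation(cfg)
  model <- parentageModel(errorRate = 0, nSim = 300, propSampled = 1)
  res <- assignParentage(sim$data, model, seed = 92)
  asg <- res$assignments
  accepted <- asg$category != "unassigned"
  expect_true(all(asg$mismatches[accepted] == 0))
  # mp_true = 0: estimated pollen immigration bounded by cryptic-flow bias
  expect_lte(res$summary$mp, 0.05)
  # selfed offspring are exactly those with father == mother
  selfed <- asg$classification == "selfed"
  expect_true(all(asg$father[selfed] == asg$mother[selfed]))
  expect_true(all(asg$pollenDist[selfed] == 0))
})

test_that("dispersal summaries obey their identities", {
  sim <- makeStudySim(seed = 93)
  model <- parentageModel(nSim = 300)
  res <- assignParentage(sim$data, model, seed = 94)
  ds <- dispersalSummaries(res, sim$data)
  expect_equal(ds$Aep_m2, 2 * pi * ds$sigmaP2)
  expect_equal(ds$radius, sqrt(ds$Aep_m2 / pi))
  expect_true(all(ds$pollen$distances > 0))  # selfing excluded
  expect_true(all(ds$seed$distances >= 0))
  expect_gte(ds$ks$p, 0); expect_lte(ds$ks$p, 1)
  # identical samples: KS D = 0, p = 1
  d <- c(10, 20, 30)
  ks <- suppressWarnings(ks.test(d, d))
  expect_equal(unname(ks$statistic), 0)
  expect_equal(ks$p.value, 1)
  # helper identity used for the neighbourhood area
  pn <- pollinationNeighborhood(316)
  expect_equal(pn$Aep_m2, 2 * pi * 316^2)
  expect_equal(pn$radius, 316 * sqrt(2))
})
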
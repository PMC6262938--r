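test_that("the exponential-power density normalises and orders tails correctly", {
  for (b in c(0.5, 1, 2)) {
    kp <- KernelParams(3, b)
    I <- integrate(function(r) 2 * pi * r * expPowerPdf(r, kp),
                   0, Inf, rel.tol = 1e-9)$value
    expect_equal(I, 1, tolerance = 1e-6)
  }
  expect_equal(expPowerPdf(0, KernelParams(1, 1)), 1 / (2 * pi))
  # fat tail: b = 0.5 exceeds b = 1 at r = 10a
  a <- 5
  expect_gt(expPowerPdf(10 * a, KernelParams(a, 0.5)),
            expPowerPdf(10 * a, KernelParams(a, 1)))
})

test_that("kernel mean distance matches closed forms and Monte Carlo draws", {
  expect_equal(kernelMeanDistance(KernelParams(7, 1)), 14)
  expect_equal(kernelMeanDistance(KernelParams(3, 2)), 3 * sqrt(pi) / 2)
  set.seed(101)
  for (par in list(c(50, 0.6), c(200, 1), c(30, 2))) {
    kp <- KernelParams(par[1], par[2])
    r <- sampleKernel(1e6, kp)[, "r"]
    expect_equal(mean(r), kernelMeanDistance(kp), tolerance = 0.005)
  }
})

# small fixed instance shared by the likelihood oracle tests
mkNmInstance <- function(seed = 111, nCand = 6, nOff = 5, L = 2) {
  set.seed(seed)
  k <- 4
  a1 <- matrix(sample.int(k, (nCand + nOff) * L, TRUE), ncol = L)
  a2 <- matrix(sample.int(k, (nCand + nOff) * L, TRUE), ncol = L)
  info <- data.frame(
    id = c(paste0("A", 1:nCand), paste0("O", 1:nOff)),
    stage = c(rep("reproductive", nCand), rep("seedling", nOff)),
    x = runif(nCand + nOff, 0, 100), y = runif(nCand + nOff, 0, 100))
  x <- GenotypeDataset(info, sprintf("L%d", 1:L), a1, a2)
  mothers <- setNames(sample(paste0("A", 1:nCand), nOff, TRUE),
                      paste0("O", 1:nOff))
  list(x = x, mothers = mothers)
}

test_that("the neighborhood likelihood equals a brute-force mating-event sum", {
  inst <- mkNmInstance()
  x <- inst$x
  f <- alleleFrequencies(x)
  e <- 0.02
  pre <- nmPrecompute(x, mothers = inst$mothers, freqs = f, errorRate = e)
  s <- 0.07; mp <- 0.3
  pk <- KernelParams(40, 1)
  got <- nmLoglikelihood(pre, s, mp, pk)

  # independent brute force: explicit sums over loci, gametes and fathers
  candIds <- x@info$id[stages(x) == "reproductive"]
  D <- pairwiseDistances(x)
  calls <- alleleCalls(x)
  trioT <- function(o1, o2, g1, g2) {
    tr <- function(g, a) ((g[1] == a) + (g[2] == a)) / 2
    if (o1 == o2) tr(g1, o1) * tr(g2, o1)
    else tr(g1, o1) * tr(g2, o2) + tr(g1, o2) * tr(g2, o1)
  }
  singleT <- function(o1, o2, g, p) {
    tr <- function(g, a) ((g[1] == a) + (g[2] == a)) / 2
    if (o1 == o2) tr(g, o1) * p[as.character(o1)]
    else tr(g, o1) * p[as.character(o2)] + tr(g, o2) * p[as.character(o1)]
  }
  total <- 0
  for (oid in names(inst$mothers)) {
    m <- inst$mothers[[oid]]
    w <- expPowerPdf(D[m, candIds], pk); w[candIds == m] <- 0
    w <- w / sum(w)
    Lo <- 1; Lself <- 1; Lbg <- 1
    Lf <- setNames(rep(1, length(candIds)), candIds)
    for (l in seq_len(nLoci(x))) {
      o1 <- calls$allele1[oid, l]; o2 <- calls$allele2[oid, l]
      p <- f@freqs[[l]]
      P0 <- if (o1 == o2) p[as.character(o1)]^2 else
        2 * p[as.character(o1)] * p[as.character(o2)]
      gm <- c(calls$allele1[m, l], calls$allele2[m, l])
      Lself <- Lself * ((1 - e) * trioT(o1, o2, gm, gm) + e * P0)
      Lbg <- Lbg * ((1 - e) * singleT(o1, o2, gm, p) + e * P0)
      for (cid in candIds) {
        gf <- c(calls$allele1[cid, l], calls$allele2[cid, l])
        Lf[cid] <- Lf[cid] * ((1 - e) * trioT(o1, o2, gm, gf) + e * P0)
      }
    }
    within <- sum(w * Lf)
    total <- total + log(s * Lself + mp * Lbg + (1 - s - mp) * within)
  }
  expect_equal(got, unname(total), tolerance = 1e-10)
})

test_that("likelihood structure: immigration-only ignores the kernel; weights normalise", {
  inst <- mkNmInstance(seed = 112)
  pre <- nmPrecompute(inst$x, mothers = inst$mothers, errorRate = 0.01)
  l1 <- nmLoglikelihood(pre, s = 0, mp = 1, KernelParams(10, 0.7))
  l2 <- nmLoglikelihood(pre, s = 0, mp = 1, KernelParams(500, 2))
  expect_equal(l1, l2)
  # distance-unit invariance: rescaling distances and a together
  pre2 <- pre
  pre2$Dcc <- pre$Dcc * 3.5
  expect_equal(nmLoglikelihood(pre, 0.1, 0.2, KernelParams(40, 1)),
               nmLoglikelihood(pre2, 0.1, 0.2, KernelParams(140, 1)))
  expect_error(nmLoglikelihood(pre, 0.6, 0.6, KernelParams(40, 1)), "s \\+ mp")
})

test_that("with a single candidate father the within-plot term is the plain trio", {
  inst <- mkNmInstance(seed = 113, nCand = 2, nOff = 4)
  # mothers fixed to A1 so the only possible father is A2
  mothers <- setNames(rep("A1", 4), paste0("O", 1:4))
  pre <- nmPrecompute(inst$x, mothers = mothers, errorRate = 0)
  la <- nmLoglikelihood(pre, 0, 0, KernelParams(10, 0.5))
  lb <- nmLoglikelihood(pre, 0, 0, KernelParams(900, 2))
  expect_equal(la, lb)  # kernel cannot matter with one father
})

test_that("the fitted model recovers boundary selfing and shows no spurious tail", {
  cfg <- simulationConfig(nAdults = 40, nOffspring = 250, s = 0, mp = 0.3,
                          pollenKernel = KernelParams(150, 2),
                          errorRate = 0.01, missingRate = 0, seed = 121)
  sim <- simulatePopulation(cfg)
  mothers <- setNames(sim$truth$mother, sim$truth$offspring)
  pre <- nmPrecompute(sim$data, mothers = mothers, errorRate = 0.01)
  fit <- fitNeighborhoodModel(pre, starts = 4, seed = 122)
  expect_lte(fit$s, 0.02)
  fit2 <- fitNeighborhoodModel(pre, starts = 4, seed = 123, fixShape = 2)
  expect_lte(abs(fit$loglik - fit2$loglik), 2)
})
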
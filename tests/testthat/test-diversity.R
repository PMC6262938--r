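test_that("allele counts equal brute-force set sizes and A = sum(k)/L", {
  x <- makeRandomDataset(40, c(4, 7, 12), seed = 2)
  ac <- alleleCounts(x)
  calls <- alleleCalls(x)
  for (l in seq_len(nLoci(x))) {
    seen <- unique(na.omit(c(calls$allele1[, l], calls$allele2[, l])))
    expect_identical(ac$k[[l]], length(seen))
  }
  expect_equal(ac$A, sum(ac$k) / nLoci(x))

  info <- data.frame(id = c("a", "b"), stage = "s", x = 0:1, y = 0:1)
  mono <- GenotypeDataset(info, "L1", matrix(1L, 2), matrix(1L, 2))
  expect_equal(alleleCounts(mono)$k[["L1"]], 1L)
  expect_equal(alleleCounts(mono)$A, 1)
})

test_that("allelic richness matches exhaustive subsampling and is monotone in g", {
  # counts {A:3, B:1}: enumerate all 2-gene subsamples of the 4 copies
  info <- data.frame(id = c("a", "b"), stage = "s", x = 0:1, y = 0:1)
  x <- GenotypeDataset(info, "L1", matrix(c(1L, 1L), 2), matrix(c(1L, 2L), 2))
  copies <- c(1, 1, 1, 2)
  pairs <- combn(4, 2)
  exhaustive <- mean(apply(pairs, 2, function(ix)
    length(unique(copies[ix]))))
  expect_equal(allelicRichness(x, g = 2)$Ar[["L1"]], exhaustive)

  # g = full gene count recovers k exactly
  expect_equal(allelicRichness(x, g = 4)$Ar[["L1"]], 2)

  y <- makeRandomDataset(30, c(6, 10), seed = 5)
  ar <- vapply(2:20, function(g) allelicRichness(y, g = g)$overall, 1)
  expect_true(all(diff(ar) >= -1e-12))

  # two stages with identical genotypes give identical Ar
  z <- makeRandomDataset(20, c(5, 5), seed = 9)
  info2 <- z@info; info2$stage <- "s2"; info2$id <- paste0("c", seq_len(20))
  both <- GenotypeDataset(rbind(z@info, info2), lociNames(z),
                          rbind(alleleCalls(z)$allele1, alleleCalls(z)$allele1),
                          rbind(alleleCalls(z)$allele2, alleleCalls(z)$allele2))
  expect_equal(allelicRichness(both, "s1", g = 10)$Ar,
               allelicRichness(both, "s2", g = 10)$Ar)
  expect_error(allelicRichness(y, g = 1), ">= 2")
})

test_that("private alleles are those confined to exactly one stage", {
  info <- data.frame(id = c("a", "b", "c"), stage = c("s1", "s2", "s3"),
                     x = 1:3, y = 1:3)
  # allele 9 only in s3; allele 1 in s1+s2; allele 2 in s1 only
  x <- GenotypeDataset(info, "L1",
                       matrix(c(1L, 1L, 9L), 3), matrix(c(2L, 1L, 9L), 3))
  Ap <- privateAlleles(x)
  expect_identical(Ap[["s3"]], 1L)
  expect_identical(Ap[["s1"]], 1L)  # allele 2
  expect_identical(Ap[["s2"]], 0L)

  # simulated 4-stage panel against brute-force set differences
  sim <- makeStudySim(seed = 4, nOffspring = 60)
  Ap <- privateAlleles(sim$data)
  calls <- alleleCalls(sim$data)
  stg <- unique(stages(sim$data))
  expected <- setNames(integer(length(stg)), stg)
  for (l in seq_len(nLoci(sim$data))) {
    per <- lapply(stg, function(s) {
      i <- stages(sim$data) == s
      unique(na.omit(c(calls$allele1[i, l], calls$allele2[i, l])))
    })
    for (si in seq_along(stg)) {
      others <- unique(unlist(per[-si]))
      expected[si] <- expected[si] + sum(!per[[si]] %in% others)
    }
  }
  expect_identical(Ap[names(expected)], expected)
})

test_that("heterozygosities match hand values and Hardy-Weinberg expectation", {
  info <- data.frame(id = c("a", "b"), stage = "s", x = 0:1, y = 0:1)
  hom <- GenotypeDataset(info, "L1", matrix(c(1L, 2L), 2), matrix(c(1L, 2L), 2))
  expect_equal(heterozygosities(hom)$Ho[["L1"]], 0)

  het <- GenotypeDataset(info, "L1", matrix(1L, 2), matrix(2L, 2))
  h <- heterozygosities(het)
  expect_equal(h$Ho[["L1"]], 1)
  expect_equal(h$HE[["L1"]], 4 / 3 * 0.5)  # Nei unbiased, n = 2

  set.seed(8)
  n <- 4000
  info <- data.frame(id = paste0("i", 1:n), stage = "s",
                     x = runif(n), y = runif(n))
  big <- GenotypeDataset(info, "L1",
                         matrix(sample(1:2, n, TRUE), n),
                         matrix(sample(1:2, n, TRUE), n))
  h <- heterozygosities(big)
  expect_equal(h$meanHo, 0.5, tolerance = 0.05)
  expect_equal(h$meanHE, 0.5, tolerance = 0.05)
})

test_that("HE is invariant under allele relabelling", {
  x <- makeRandomDataset(40, c(5, 8), seed = 13)
  calls <- alleleCalls(x)
  relab <- GenotypeDataset(x@info, lociNames(x),
                           calls$allele1 * 100L, calls$allele2 * 100L)
  expect_equal(heterozygosities(relab)$HE, heterozygosities(x)$HE,
               ignore_attr = TRUE)
})

test_that("fixation index flags complete selfing and stays calibrated under HWE", {
  # all homozygotes at a polymorphic locus: F = 1, significant
  set.seed(21)
  n <- 40
  info <- data.frame(id = paste0("i", 1:n), stage = "s",
                     x = runif(n), y = runif(n))
  a <- matrix(sample(1:4, 2 * n, TRUE), n)
  selfed <- GenotypeDataset(info, c("L1", "L2"), a, a)
  fx <- fixationIndex(selfed, nPerm = 200, seed = 1)
  expect_equal(fx$F, 1)
  expect_lt(fx$p, 0.05)

  # permutation p-values stable across seeds (Monte Carlo error bound)
  x <- makeRandomDataset(40, c(6, 6, 6), seed = 17)
  ps <- vapply(1:20, function(s)
    fixationIndex(x, nPerm = 200, seed = s)$p, 1)
  p0 <- mean(ps)
  expect_lt(max(abs(ps - p0)), 3 * sqrt(p0 * (1 - p0) / 200) + 1 / 200)
})
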
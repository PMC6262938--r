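# shared fixtures and independent oracles, all built in code

# tiny hand-made dataset: 4 individuals, 2 loci, one missing call
makeTinyDataset <- function() {
  info <- data.frame(
    id = c("i1", "i2", "i3", "i4"),
    stage = c("reproductive", "reproductive", "seedling", "seedling"),
    x = c(0, 3, 0, 10), y = c(0, 4, 5, 0),
    stringsAsFactors = FALSE)
  a1 <- matrix(c(101L, 101L, 103L, NA,
                 7L,   7L,   8L,  9L), 4, 2)
  a2 <- matrix(c(101L, 103L, 103L, NA,
                 7L,   8L,   8L,  9L), 4, 2)
  GenotypeDataset(info, c("LocA", "LocB"), a1, a2)
}

# random HWE dataset with given per-locus allele counts (no structure)
makeRandomDataset <- function(n = 50, loci = c(4, 6, 8), stages = "s1",
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  L <- length(loci)
  a1 <- matrix(NA_integer_, n, L); a2 <- matrix(NA_integer_, n, L)
  for (l in seq_len(L)) {
    p <- as.numeric(stats::rgamma(loci[l], 1)); p <- p / sum(p)
    a1[, l] <- sample.int(loci[l], n, replace = TRUE, prob = p)
    a2[, l] <- sample.int(loci[l], n, replace = TRUE, prob = p)
  }
  info <- data.frame(id = paste0("r", seq_len(n)),
                     stage = rep_len(stages, n),
                     x = stats::runif(n, 0, 300), y = stats::runif(n, 0, 300),
                     stringsAsFactors = FALSE)
  GenotypeDataset(info, sprintf("L%d", seq_len(L)), a1, a2)
}

# independent scalar-loop implementation of the Loiselle estimator
loiselleOracle <- function(x) {
  a1 <- alleleCalls(x)$allele1; a2 <- alleleCalls(x)$allele2
  n <- nIndividuals(x); L <- nLoci(x)
  perLocus <- lapply(seq_len(L), function(l) {
    typed <- which(!is.na(a1[, l]))
    copies <- c(a1[typed, l], a2[typed, l])
    alleles <- sort(unique(copies))
    p <- vapply(alleles, function(a) mean(copies == a), 1)
    list(typed = typed, alleles = alleles, p = p,
         w = sum(p * (1 - p)), nl = length(copies))
  })
  th <- matrix(NA_real_, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    num <- 0; den <- 0
    for (l in seq_len(L)) {
      pl <- perLocus[[l]]
      if (pl$w <= 0 || !(i %in% pl$typed) || !(j %in% pl$typed)) next
      di <- vapply(pl$alleles, function(a)
        ((a1[i, l] == a) + (a2[i, l] == a)) / 2, 1)
      dj <- vapply(pl$alleles, function(a)
        ((a1[j, l] == a) + (a2[j, l] == a)) / 2, 1)
      num <- num + sum((di - pl$p) * (dj - pl$p)) + pl$w / (pl$nl - 1)
      den <- den + pl$w
    }
    th[i, j] <- th[j, i] <- num / den
  }
  th
}

# exhaustive parent-pair exclusion probability for one locus by enumeration
enumPairExclusion <- function(p) {
  k <- length(p)
  gts <- expand.grid(a1 = seq_len(k), a2 = seq_len(k))
  gts <- gts[gts$a1 <= gts$a2, ]
  gprob <- ifelse(gts$a1 == gts$a2, p[gts$a1]^2, 2 * p[gts$a1] * p[gts$a2])
  tr <- function(g1, g2, a) ((g1 == a) + (g2 == a)) / 2
  trio <- function(o1, o2, m, f) {
    if (o1 == o2) tr(m[1], m[2], o1) * tr(f[1], f[2], o1)
    else tr(m[1], m[2], o1) * tr(f[1], f[2], o2) +
         tr(m[1], m[2], o2) * tr(f[1], f[2], o1)
  }
  tot <- 0
  for (o in seq_len(nrow(gts))) for (i in seq_len(nrow(gts)))
    for (j in seq_len(nrow(gts))) {
      if (trio(gts$a1[o], gts$a2[o],
               c(gts$a1[i], gts$a2[i]), c(gts$a1[j], gts$a2[j])) == 0)
        tot <- tot + gprob[o] * gprob[i] * gprob[j]
    }
  tot
}

# small study-like simulation (fewer offspring) for fast end-to-end checks
makeStudySim <- function(seed, nOffspring = 189, ...) {
  simulatePopulation(simulationConfig(seed = seed, nOffspring = nOffspring,
                                      ...))
}
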
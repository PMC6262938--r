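#' Allele counts per locus
#'
#' Counts distinct non-missing alleles per locus (`k`) within a stage, their
#' total, and the mean number of alleles per locus `A = sum(k) / L`.
#'
#' @param x a [GenotypeDataset-class].
#' @param stage optional stage label(s); `NULL` = whole sample.
#' @return list with `k` (named per-locus counts), `total`, and `A`.
#' @export
alleleCounts <- function(x, stage = NULL) {
  if (!is.null(stage)) x <- subsetStage(x, stage)
  k <- vapply(seq_along(x@loci), function(l) {
    length(unique(stats::na.omit(c(x@allele1[, l], x@allele2[, l]))))
  }, 1L)
  names(k) <- x@loci
  list(k = k, total = sum(k), A = sum(k) / length(k))
}

#' Rarefied allelic richness
#'
#' Expected number of distinct alleles in a random subsample of `g` gene
#' copies, by hypergeometric rarefaction:
#' \deqn{A_r = \sum_a \left[1 - {G - N_a \choose g} / {G \choose g}\right]}
#' with \eqn{N_a} the observed copies of allele \eqn{a} and \eqn{G} the gene
#' count at the locus. Makes per-locus richness comparable across groups with
#' unequal sample sizes; `g` should not exceed the smallest per-locus gene
#' count among the groups being compared.
#'
#' @param x a [GenotypeDataset-class].
#' @param stage optional stage label(s).
#' @param g rarefaction size in gene copies (>= 2).
#' @return list with `Ar` (named per-locus values) and `overall` (mean).
#' @export
allelicRichness <- function(x, stage = NULL, g) {
  if (g < 2) stop("rarefaction size g must be >= 2")
  if (!is.null(stage)) x <- subsetStage(x, stage)
  Ar <- vapply(seq_along(x@loci), function(l) {
    copies <- stats::na.omit(c(x@allele1[, l], x@allele2[, l]))
    G <- length(copies)
    if (G < g) stop("locus ", x@loci[l], ": gene count ", G, " < g = ", g)
    Na <- table(copies)
    sum(1 - exp(lchoose(G - Na, g) - lchoose(G, g)))
  }, 1)
  names(Ar) <- x@loci
  list(Ar = Ar, overall = mean(Ar))
}

#' Private alleles per stage
#'
#' An allele is private to a stage when it is observed in exactly one stage.
#'
#' @param x a [GenotypeDataset-class] with at least two stages.
#' @return named integer vector: private allele count (`Ap`) per stage.
#' @export
privateAlleles <- function(x) {
  stg <- unique(x@info$stage)
  if (length(stg) < 2L) stop("private alleles need at least two stages")
  Ap <- setNames(integer(length(stg)), stg)
  for (l in seq_along(x@loci)) {
    seen <- lapply(stg, function(s) {
      i <- x@info$stage == s
      unique(stats::na.omit(c(x@allele1[i, l], x@allele2[i, l])))
    })
    all_alleles <- unique(unlist(seen))
    for (a in all_alleles) {
      hit <- vapply(seen, function(v) a %in% v, TRUE)
      if (sum(hit) == 1L) Ap[which(hit)] <- Ap[which(hit)] + 1L
    }
  }
  Ap
}

#' Observed and expected heterozygosity
#'
#' `Ho` is the fraction of heterozygous genotypes among non-missing calls.
#' `HE` is Nei's unbiased expected heterozygosity
#' \eqn{\frac{2n}{2n-1}(1 - \sum_a p_a^2)} with `n` the genotyped individuals
#' at the locus. Multilocus means are unweighted across loci.
#'
#' @param x a [GenotypeDataset-class].
#' @param stage optional stage label(s).
#' @return list with per-locus vectors `Ho`, `HE`, `n`, and multilocus means
#'   `meanHo`, `meanHE`.
#' @export
heterozygosities <- function(x, stage = NULL) {
  if (!is.null(stage)) x <- subsetStage(x, stage)
  L <- length(x@loci)
  Ho <- HE <- nl <- numeric(L)
  for (l in seq_len(L)) {
    ok <- !is.na(x@allele1[, l])
    n <- sum(ok)
    nl[l] <- n
    if (n < 1) { Ho[l] <- HE[l] <- NA_real_; next }
    Ho[l] <- mean(x@allele1[ok, l] != x@allele2[ok, l])
    p <- table(c(x@allele1[ok, l], x@allele2[ok, l])) / (2 * n)
    HE[l] <- if (n > 1) (2 * n / (2 * n - 1)) * (1 - sum(p^2)) else NA_real_
  }
  names(Ho) <- names(HE) <- names(nl) <- x@loci
  list(Ho = Ho, HE = HE, n = nl,
       meanHo = mean(Ho, na.rm = TRUE), meanHE = mean(HE, na.rm = TRUE))
}

#' Fixation index with permutation test
#'
#' Multilocus fixation index \eqn{F = \sum_l (H_{E,l} - H_{o,l}) / \sum_l
#' H_{E,l}} (equivalently \eqn{1 - \sum H_o / \sum H_E}; the summed form
#' weights loci by their diversity and is robust to near-monomorphic loci).
#' Significance against \eqn{F = 0} is assessed by Monte Carlo permutation of
#' the `2n` allele copies among individuals within each locus (the
#' Hardy-Weinberg null), two-sided: `p = (1 + #{|F*| >= |F|}) / (1 + nPerm)`.
#'
#' @param x a [GenotypeDataset-class].
#' @param stage optional stage label(s).
#' @param nPerm number of permutations (default 1000).
#' @param alpha significance level for the returned flag.
#' @param nTests Bonferroni family size for the flag (default 1 = unadjusted;
#'   use 4 when testing the four stage-level values together).
#' @param seed optional integer seed for reproducibility.
#' @return list with `F` (multilocus), `perLocus` (per-locus F), `p`
#'   (two-sided permutation p-value), `significant` (logical, at
#'   `alpha / nTests`), `nPerm`, `seed`.
#' @export
fixationIndex <- function(x, stage = NULL, nPerm = 1000, alpha = 0.05,
                          nTests = 1L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (!is.null(stage)) x <- subsetStage(x, stage)
  het <- heterozygosities(x)
  use <- which(!is.na(het$HE) & het$HE > 0)
  if (length(use) < length(x@loci))
    warning("excluding ", length(x@loci) - length(use),
            " loci with HE = 0 or no data")
  if (!length(use)) stop("no usable loci for F")
  Fobs <- sum(het$HE[use] - het$Ho[use]) / sum(het$HE[use])
  perLocus <- 1 - het$Ho / het$HE
  # permutation: shuffle allele copies among individuals within each locus
  copies <- lapply(use, function(l) {
    ok <- !is.na(x@allele1[, l])
    c(x@allele1[ok, l], x@allele2[ok, l])
  })
  HEl <- het$HE[use]
  Fstar <- vapply(seq_len(nPerm), function(b) {
    Hob <- vapply(copies, function(cp) {
      cp <- sample(cp)
      n <- length(cp) / 2
      mean(cp[seq_len(n)] != cp[n + seq_len(n)])
    }, 1)
    sum(HEl - Hob) / sum(HEl)
  }, 1)
  p <- (1 + sum(abs(Fstar) >= abs(Fobs))) / (1 + nPerm)
  list(F = Fobs, perLocus = perLocus, p = p,
       significant = p < alpha / nTests, nPerm = nPerm, seed = seed)
}

#' Per-stage diversity summary table
#'
#' Convenience wrapper assembling, per ontogenetic stage, the sample size and
#' the standard diversity indices: total alleles `k`, rarefied richness `Ar`,
#' private alleles `Ap`, mean alleles per locus `A`, observed/expected
#' heterozygosity, and the fixation index with its permutation p-value
#' (Bonferroni-adjusted across the stages tested).
#'
#' @param x a [GenotypeDataset-class].
#' @param stages stage labels to summarise (default: all present, in order of
#'   appearance).
#' @param rarefactionN rarefaction size in gene copies; default = the smallest
#'   per-locus gene count across the stages.
#' @param nPerm permutations for the F test.
#' @param seed integer seed.
#' @return data.frame with one row per stage: `stage, n, k, Ar, Ap, A, Ho,
#'   HE, F, F_p, F_significant`.
#' @export
diversitySummary <- function(x, stages = unique(x@info$stage),
                             rarefactionN = NULL, nPerm = 1000, seed = NULL) {
  if (is.null(rarefactionN)) {
    rarefactionN <- min(vapply(stages, function(s) {
      xs <- subsetStage(x, s)
      min(vapply(seq_along(xs@loci), function(l)
        2L * sum(!is.na(xs@allele1[, l])), 1L))
    }, 1L))
  }
  Ap <- if (length(unique(x@info$stage)) >= 2L) privateAlleles(x) else NULL
  rows <- lapply(seq_along(stages), function(i) {
    s <- stages[i]
    ac <- alleleCounts(x, s)
    ar <- allelicRichness(x, s, g = rarefactionN)
    het <- heterozygosities(x, s)
    fx <- fixationIndex(x, s, nPerm = nPerm, nTests = length(stages),
                        seed = if (is.null(seed)) NULL else seed + i)
    data.frame(stage = s, n = sum(x@info$stage == s), k = ac$total,
               Ar = ar$overall, Ap = if (is.null(Ap)) NA_integer_ else Ap[[s]],
               A = ac$A, Ho = het$meanHo, HE = het$meanHE,
               F = fx$F, F_p = fx$p, F_significant = fx$significant,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "rarefactionN") <- rarefactionN
  out
}
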
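#' @import methods
#' @importFrom stats setNames na.omit quantile rgamma runif var sd median
#'   cor ks.test optim rbinom sample.int plogis
#' @importFrom utils read.csv write.csv
NULL

# align an AlleleFrequencyTable with a locus-name vector; NULL where absent
.alignFreqs <- function(freqs, loci) {
  lapply(loci, function(l) {
    if (!l %in% names(freqs@freqs)) return(NULL)
    list(p = freqs@freqs[[l]], gc = freqs@geneCounts[[l]])
  })
}

# symmetric-Dirichlet draw (gamma representation)
.rdirichlet <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha)
  if (sum(g) == 0) g[sample.int(length(g), 1L)] <- 1
  g / sum(g)
}

# frequency lookup with a small floor for alleles unseen in the reference table
.lookupFreq <- function(p, code, geneCount) {
  v <- unname(p[as.character(code)])
  v[is.na(v)] <- 1 / (2 * geneCount + 1)
  v
}

# HWE genotype probability
.hweProb <- function(p1, p2, het) ifelse(het, 2 * p1 * p2, p1 * p2)

# Draw n HWE genotypes at one locus: returns 2 x n allele codes (integer)
.drawGenotypes <- function(n, codes, p) {
  matrix(codes[sample.int(length(codes), 2L * n, replace = TRUE, prob = p)],
         nrow = 2L)
}

#' @noRd
# Core parentage likelihood engine for ONE offspring against a candidate set.
#
# off1/off2: integer vectors (L) of the offspring's allele codes (NA missing).
# cand1/cand2: nC x L integer matrices of candidate allele codes.
# flist: per-locus list aligned with the columns of cand1 (see .alignFreqs);
#        NULL elements (loci absent from the frequency table) are skipped.
# e: per-locus class-I genotyping error rate; the error-tolerant transition is
#    T_e = (1 - e) T + e P_HWE(offspring).
#
# Returns pair LOD matrix (nC x nC, diagonal = selfing), pair Mendelian
# mismatch counts, single-parent LOD vector, single mismatch counts.
.lodEngine <- function(off1, off2, cand1, cand2, flist, e,
                       needPair = TRUE, needSingle = TRUE, needMM = TRUE) {
  nC <- nrow(cand1)
  Rpair <- if (needPair) matrix(1, nC, nC) else NULL
  MMpair <- if (needPair && needMM) matrix(0L, nC, nC) else NULL
  Rsing <- if (needSingle) rep(1, nC) else NULL
  MMsing <- if (needSingle && needMM) integer(nC) else NULL
  for (l in seq_along(off1)) {
    o1 <- off1[l]; o2 <- off2[l]
    if (is.na(o1) || is.null(flist[[l]])) next
    p <- flist[[l]]$p
    gc <- flist[[l]]$gc
    p1 <- .lookupFreq(p, o1, gc)
    p2 <- .lookupFreq(p, o2, gc)
    het <- o1 != o2
    P0 <- .hweProb(p1, p2, het)
    c1 <- cand1[, l]; c2 <- cand2[, l]
    miss <- is.na(c1)
    u1 <- (ifelse(c1 == o1, 1L, 0L) + ifelse(c2 == o1, 1L, 0L)) / 2
    u2 <- (ifelse(c1 == o2, 1L, 0L) + ifelse(c2 == o2, 1L, 0L)) / 2
    u1[miss] <- 0; u2[miss] <- 0
    if (needPair) {
      T0 <- if (het) outer(u1, u2) + outer(u2, u1) else outer(u1, u1)
      ratio <- ((1 - e) * T0 + e * P0) / P0
      ratio[miss, ] <- 1; ratio[, miss] <- 1
      Rpair <- Rpair * ratio
      if (needMM) {
        mm <- (T0 == 0)
        mm[miss, ] <- FALSE; mm[, miss] <- FALSE
        MMpair <- MMpair + mm
      }
    }
    if (needSingle) {
      Ts <- if (het) u1 * p2 + u2 * p1 else u1 * p1
      rs <- ((1 - e) * Ts + e * P0) / P0
      rs[miss] <- 1
      Rsing <- Rsing * rs
      if (needMM) {
        ms <- (Ts == 0)
        ms[miss] <- FALSE
        MMsing <- MMsing + ms
      }
    }
  }
  list(lodPair = if (needPair) log(Rpair) else NULL,
       mmPair = MMpair,
       lodSingle = if (needSingle) log(Rsing) else NULL,
       mmSingle = MMsing)
}

# best and runner-up over the upper triangle + diagonal of a pair LOD matrix,
# subject to a logical mask of allowed pairs; returns indices, lod, delta
.bestPair <- function(lod, allowed) {
  lod[lower.tri(lod)] <- -Inf
  lod[!allowed] <- -Inf
  if (all(!is.finite(lod))) return(NULL)
  o1 <- arrayInd(which.max(lod), dim(lod))
  best <- lod[o1]
  lod[o1] <- -Inf
  second <- suppressWarnings(max(lod))
  list(i = o1[1], j = o1[2], lod = best,
       delta = if (is.finite(second)) best - second else best)
}

# reflect positions into [0, w] x [0, h]
.reflectInto <- function(xy, w, h) {
  fold <- function(v, lim) {
    v <- v %% (2 * lim)
    ifelse(v > lim, 2 * lim - v, v)
  }
  cbind(fold(xy[, 1], w), fold(xy[, 2], h))
}
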
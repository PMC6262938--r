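#' Pairwise Loiselle coancestry
#'
#' Multilocus pairwise coancestry (kinship) coefficients between all pairs of
#' individuals, after Loiselle et al. (1995). Per locus \eqn{l}, with
#' \eqn{p_{i,a}} the dosage/2 of allele \eqn{a} in individual \eqn{i},
#' \eqn{\bar p_a} the reference frequency, and \eqn{n_l} the gene count
#' (2 x genotyped individuals) at the locus:
#' \deqn{f_{ij,l} = \frac{\sum_a (p_{i,a}-\bar p_a)(p_{j,a}-\bar p_a)
#'   + \sum_a \bar p_a(1-\bar p_a) / (n_l - 1)}
#'   {\sum_a \bar p_a (1-\bar p_a)}}
#' The multilocus \eqn{\theta_{ij}} is the weighted mean over loci with
#' weights \eqn{w_l = \sum_a \bar p_a(1-\bar p_a)} (so loci missing in either
#' member of a pair simply drop out of both sums). Monomorphic loci carry zero
#' weight and are excluded. The estimator is sample-centred: with frequencies
#' computed from the analysed group itself, the mean over all pairs is close
#' to zero (small negative, order 1/n).
#'
#' @param x a [GenotypeDataset-class].
#' @param stage optional stage label; the reference frequencies default to
#'   this same group, matching a per-stage analysis.
#' @param freqs optional [AlleleFrequencyTable-class] of reference
#'   frequencies (default: computed from `x` after stage subsetting).
#' @return A [CoancestryMatrix-class].
#' @export
loiselleCoancestry <- function(x, stage = NULL, freqs = NULL) {
  if (!is.null(stage)) x <- subsetStage(x, stage)
  if (is.null(freqs)) freqs <- alleleFrequencies(x)
  n <- nIndividuals(x)
  NUM <- matrix(0, n, n)
  DEN <- matrix(0, n, n)
  wl <- numeric(0)
  for (l in names(freqs@freqs)) {
    p <- freqs@freqs[[l]]
    w <- sum(p * (1 - p))
    if (w <= 0) next  # monomorphic: zero weight
    li <- match(l, x@loci)
    a1 <- x@allele1[, li]; a2 <- x@allele2[, li]
    typed <- !is.na(a1)
    nl <- freqs@geneCounts[[l]]
    if (nl < 2) next
    codes <- names(p)
    X <- (outer(as.character(a1), codes, "==") +
          outer(as.character(a2), codes, "==")) / 2
    C <- sweep(X, 2L, p)
    C[!typed, ] <- 0
    M <- tcrossprod(C)
    G <- tcrossprod(as.numeric(typed))
    NUM <- NUM + M + (w / (nl - 1)) * G
    DEN <- DEN + w * G
    wl <- c(wl, setNames(w, l))
  }
  if (!length(wl)) stop("no polymorphic loci for coancestry")
  theta <- NUM / DEN
  theta[DEN == 0] <- NA_real_
  diag(theta) <- NA_real_
  dimnames(theta) <- list(x@info$id, x@info$id)
  new("CoancestryMatrix", theta = theta,
      stage = if (is.null(stage)) "all" else paste(stage, collapse = "+"),
      lociWeights = wl)
}

#' Equal-frequency distance classes
#'
#' Partitions the pairwise distances into `nClasses` classes of approximately
#' equal pair counts; class bounds are the empirical distance quantiles at the
#' class break points, and pairs tied exactly on a bound fall in the lower
#' class.
#'
#' @param d symmetric distance matrix (or vector of pair distances).
#' @param nClasses number of classes (default 10).
#' @return numeric vector of strictly increasing upper bounds (meters), of
#'   length `nClasses`; the last bound is the maximum distance.
#' @export
distanceClasses <- function(d, nClasses = 10) {
  v <- if (is.matrix(d)) d[upper.tri(d)] else as.numeric(d)
  if (length(unique(v)) < nClasses)
    stop("fewer than ", nClasses, " distinct pairwise distances")
  sv <- sort(v)
  np <- length(sv)
  bounds <- sv[ceiling(seq_len(nClasses) * np / nClasses)]
  if (any(diff(bounds) <= 0))
    stop("degenerate distance distribution: ties collapse class bounds")
  bounds
}

.pairClass <- function(d, bounds) {
  # ties on a bound go to the lower class; bound k is the inclusive upper edge
  findInterval(d, bounds, left.open = TRUE) + 1L
}

#' Coancestry correlogram with permutation envelope
#'
#' Mean pairwise coancestry per distance class, with a 95% (by default)
#' null envelope from Monte Carlo permutation of the individuals' spatial
#' positions: each permutation shuffles the mapped locations against the
#' genotypes, reassigns pairs to the fixed distance classes, and recomputes
#' the class means; the envelope is the 2.5/97.5 percentile band. A class
#' whose observed mean falls outside its envelope is flagged significant.
#'
#' @param coan a [CoancestryMatrix-class].
#' @param distances symmetric matrix of pairwise distances (same individuals
#'   and ordering as `coan`).
#' @param classes class upper bounds from [distanceClasses()] (default:
#'   computed with 10 classes).
#' @param nPerm number of permutations (default 10000).
#' @param ci envelope coverage (default 0.95).
#' @param seed optional integer seed.
#' @return data.frame with one row per class: `class, upper, meanDist,
#'   nPairs, theta, lo, hi, significant`; attributes `nPerm`, `seed`.
#' @export
sgsCorrelogram <- function(coan, distances, classes = NULL, nPerm = 10000,
                           ci = 0.95, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  th <- coan@theta
  n <- nrow(th)
  stopifnot(identical(dim(th), dim(distances)))
  ut <- which(upper.tri(th), arr.ind = TRUE)
  ok <- !is.na(th[ut])
  ut <- ut[ok, , drop = FALSE]
  I <- ut[, 1]; J <- ut[, 2]
  thv <- th[ut]
  dv <- distances[ut]
  if (is.null(classes)) classes <- distanceClasses(dv)
  k <- length(classes)
  cls <- .pairClass(dv, classes)
  nPairs <- tabulate(cls, k)
  obs <- vapply(seq_len(k), function(c)
    mean(thv[cls == c]), 1)
  meanDist <- vapply(seq_len(k), function(c) mean(dv[cls == c]), 1)
  permMeans <- matrix(NA_real_, nPerm, k)
  for (b in seq_len(nPerm)) {
    p <- sample.int(n)
    dp <- distances[cbind(p[I], p[J])]
    cb <- .pairClass(dp, classes)
    sums <- vapply(seq_len(k), function(c) sum(thv[cb == c]), 1)
    cnts <- tabulate(cb, k)
    permMeans[b, ] <- sums / cnts
  }
  a <- (1 - ci) / 2
  lo <- apply(permMeans, 2L, stats::quantile, probs = a, na.rm = TRUE)
  hi <- apply(permMeans, 2L, stats::quantile, probs = 1 - a, na.rm = TRUE)
  out <- data.frame(class = seq_len(k), upper = classes, meanDist = meanDist,
                    nPairs = nPairs, theta = obs, lo = lo, hi = hi,
                    significant = obs < lo | obs > hi)
  attr(out, "nPerm") <- nPerm
  attr(out, "seed") <- seed
  out
}

#' Sp statistic from a regression slope and first-class coancestry
#'
#' The standardised intensity of spatial genetic structure,
#' \eqn{Sp = -b_k / (1 - \theta_1)}, where \eqn{b_k} is the least-squares
#' slope of pairwise coancestry on ln(distance) and \eqn{\theta_1} the mean
#' coancestry in the first distance class.
#'
#' @param bk regression slope of \eqn{\theta_{ij}} on \eqn{\ln d_{ij}}.
#' @param theta1 mean coancestry in the first distance class.
#' @return Sp (numeric scalar).
#' @export
spFromSlope <- function(bk, theta1) -bk / (1 - theta1)

#' SGS summary: regression slope, permutation test, and Sp
#'
#' Regresses the pairwise coancestry coefficients on the natural log of the
#' pairwise spatial distances (over all individual pairs; zero-distance pairs
#' are excluded with a warning), tests the slope \eqn{b_k} against the
#' spatially random null by permuting the individuals' positions, and returns
#' the Sp statistic \eqn{-b_k/(1-\theta_1)}.
#'
#' @inheritParams sgsCorrelogram
#' @param classes class bounds for \eqn{\theta_1} (default: 10 equal-frequency
#'   classes).
#' @return list with `theta1`, `firstClassUpper`, `bk`, `bk_p` (two-sided
#'   permutation p-value), `Sp`, `nPerm`, `seed`.
#' @export
spStatistic <- function(coan, distances, classes = NULL, nPerm = 10000,
                        seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  th <- coan@theta
  n <- nrow(th)
  ut <- which(upper.tri(th), arr.ind = TRUE)
  ut <- ut[!is.na(th[ut]), , drop = FALSE]
  I <- ut[, 1]; J <- ut[, 2]
  thv <- th[ut]
  dv <- distances[ut]
  if (any(dv <= 0)) {
    warning("excluding ", sum(dv <= 0), " zero-distance pair(s) from the regression")
  }
  if (is.null(classes)) classes <- distanceClasses(dv)
  cls <- .pairClass(dv, classes)
  theta1 <- mean(thv[cls == 1L])
  keep <- dv > 0
  slope <- function(y, ld) {
    ldc <- ld - mean(ld)
    sum(ldc * y) / sum(ldc^2)
  }
  bk <- slope(thv[keep], log(dv[keep]))
  exceed <- 0L
  for (b in seq_len(nPerm)) {
    p <- sample.int(n)
    dp <- distances[cbind(p[I], p[J])]
    kp <- dp > 0
    bstar <- slope(thv[kp], log(dp[kp]))
    if (abs(bstar) >= abs(bk)) exceed <- exceed + 1L
  }
  pval <- (1 + exceed) / (1 + nPerm)
  list(theta1 = theta1, firstClassUpper = classes[1], bk = bk, bk_p = pval,
       Sp = spFromSlope(bk, theta1), nPerm = nPerm, seed = seed)
}
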
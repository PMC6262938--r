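#' Parentage model settings
#'
#' Bundles the settings of the categorical maximum-likelihood parentage
#' analysis: the candidate-parent stage, the per-locus genotyping error rate
#' used in the error-tolerant transition probabilities, the number of Delta
#' simulation replicates, the assumed proportion of candidate fathers sampled,
#' the assignment confidence level, and the maximum number of mismatching loci
#' tolerated per offspring-parent(s) comparison.
#'
#' @param candidateStage stage label of the candidate parents
#'   (default `"reproductive"`).
#' @param errorRate per-locus genotyping error rate in `[0, 0.5)`.
#' @param nSim Delta simulation replicates (default 10000).
#' @param propSampled assumed proportion of candidate fathers sampled, in
#'   (0, 1].
#' @param confidence assignment confidence level in (0, 1) (default 0.80).
#' @param maxMismatch maximum mismatching loci per comparison (default 3).
#' @param allowSelfing logical; consider self-fertilisation (default TRUE).
#' @return list of class `"ParentageModel"`.
#' @export
parentageModel <- function(candidateStage = "reproductive", errorRate = 0.01,
                           nSim = 10000, propSampled = 0.5, confidence = 0.80,
                           maxMismatch = 3L, allowSelfing = TRUE) {
  stopifnot(errorRate >= 0, errorRate < 0.5,
            propSampled > 0, propSampled <= 1,
            confidence > 0, confidence < 1, nSim >= 1)
  structure(list(candidateStage = candidateStage, errorRate = errorRate,
                 nSim = as.integer(nSim), propSampled = propSampled,
                 confidence = confidence, maxMismatch = as.integer(maxMismatch),
                 allowSelfing = isTRUE(allowSelfing)),
            class = "ParentageModel")
}

#' Parent-pair exclusion probability (Dow & Ashley)
#'
#' Per-locus probability of excluding a random, unrelated candidate parent
#' pair for a random offspring, from the allele frequencies (Jamieson & Taylor
#' closed form in the allele-frequency power sums \eqn{S_k = \sum_a p_a^k}):
#' \deqn{Q = 1 + 4S_4 - 4S_5 - 3S_6 - 8S_2^2 + 8S_2S_3 + 2S_3^2}
#' Loci combine as \eqn{P_p = 1 - \prod_l (1 - Q_l)}; a monomorphic locus
#' contributes 0.
#'
#' @param freqs an [AlleleFrequencyTable-class].
#' @return list with `Pp` (combined) and `perLocus` (named vector).
#' @export
exclusionProbabilityPairs <- function(freqs) {
  Q <- vapply(freqs@freqs, function(p) {
    S <- vapply(2:6, function(k) sum(p^k), 1)
    1 + 4 * S[3] - 4 * S[4] - 3 * S[5] - 8 * S[1]^2 + 8 * S[1] * S[2] +
      2 * S[2]^2
  }, 1)
  list(Pp = 1 - prod(1 - Q), perLocus = Q)
}

#' LOD scores of candidate parents for one offspring
#'
#' Log-likelihood ratios of parenthood versus an unrelated individual drawn
#' from the reference allele frequencies, summed over loci typed in the
#' offspring. Pair LODs (including the selfing pair, the matrix diagonal) use
#' the trio transition probability; single-parent LODs draw the second gamete
#' from the population. With error rate `e` the error-tolerant transition
#' \eqn{T_e = (1-e)\,T + e\,P_{HWE}} is used, so at `e = 0` a Mendelian
#' impossibility gives LOD \eqn{-\infty}. Loci missing in the offspring or a
#' candidate are skipped.
#'
#' @param offspring a single-row [GenotypeDataset-class] subset, or an index
#'   into `x`.
#' @param x a [GenotypeDataset-class] holding the candidates (and offspring).
#' @param candidateIds character vector of candidate ids in `x`.
#' @param freqs an [AlleleFrequencyTable-class] of reference frequencies.
#' @param errorRate per-locus genotyping error rate.
#' @return list with `lodPair` (candidate x candidate matrix), `mmPair`
#'   (mismatching-locus counts), `lodSingle`, `mmSingle`.
#' @export
lodScores <- function(offspring, x, candidateIds, freqs, errorRate = 0.01) {
  if (is(offspring, "GenotypeDataset")) {
    stopifnot(nIndividuals(offspring) == 1L)
    off1 <- offspring@allele1[1L, ]; off2 <- offspring@allele2[1L, ]
  } else {
    oi <- if (is.character(offspring)) match(offspring, x@info$id) else offspring
    stopifnot(length(oi) == 1L, !is.na(oi))
    off1 <- x@allele1[oi, ]; off2 <- x@allele2[oi, ]
  }
  ci <- match(candidateIds, x@info$id)
  stopifnot(!anyNA(ci))
  flist <- .alignFreqs(freqs, x@loci)
  res <- .lodEngine(off1, off2,
                    x@allele1[ci, , drop = FALSE],
                    x@allele2[ci, , drop = FALSE],
                    flist, errorRate)
  dimnames(res$lodPair) <- list(candidateIds, candidateIds)
  names(res$lodSingle) <- candidateIds
  res
}

#' Simulate the critical Delta for categorical assignment
#'
#' Calibrates the LOD-gap (Delta) acceptance threshold by simulation, in the
#' manner of CERVUS: in each replicate a true parent pair is drawn from the
#' reference allele frequencies under Hardy-Weinberg, the mother is placed in
#' a candidate set of `nCandidates` frequency-drawn genotypes, the father is
#' in the set with probability `propSampled` (else he is an unsampled
#' immigrant), the offspring genotype is built from Mendelian gametes and
#' perturbed by the class-I error model, and the best candidate (pair or
#' single parent) and its Delta are recorded. The critical Delta is the
#' smallest threshold such that the proportion of *correct* assignments among
#' simulated assignments at or above it reaches the model's confidence level.
#'
#' @param model a [parentageModel()] list.
#' @param freqs an [AlleleFrequencyTable-class].
#' @param nCandidates size of the candidate set.
#' @param type `"pair"` (parent-pair assignment) or `"single"`.
#' @param seed optional integer seed.
#' @param details if TRUE, also return the per-replicate `deltas` and
#'   `correct` vectors (for calibration checks).
#' @return list with `criticalDelta`, `successRate` (proportion of simulated
#'   offspring assigned at or above the threshold), `type`, `nSim`, and
#'   optionally `deltas`/`correct`.
#' @export
simulateDeltaCriterion <- function(model, freqs, nCandidates,
                                   type = c("pair", "single"), seed = NULL,
                                   details = FALSE) {
  type <- match.arg(type)
  if (!is.null(seed)) set.seed(seed)
  loci <- names(freqs@freqs)
  L <- length(loci)
  flist <- lapply(loci, function(l)
    list(p = freqs@freqs[[l]], gc = freqs@geneCounts[[l]]))
  codesL <- lapply(flist, function(f) as.integer(names(f$p)))
  e <- model$errorRate
  nS <- model$nSim
  deltas <- numeric(nS)
  correct <- logical(nS)
  for (b in seq_len(nS)) {
    cand1 <- matrix(NA_integer_, nCandidates, L)
    cand2 <- matrix(NA_integer_, nCandidates, L)
    imm1 <- integer(L); imm2 <- integer(L)
    for (l in seq_len(L)) {
      g <- .drawGenotypes(nCandidates + 1L, codesL[[l]], flist[[l]]$p)
      cand1[, l] <- g[1L, seq_len(nCandidates)]
      cand2[, l] <- g[2L, seq_len(nCandidates)]
      imm1[l] <- g[1L, nCandidates + 1L]; imm2[l] <- g[2L, nCandidates + 1L]
    }
    mi <- sample.int(nCandidates, 1L)
    fatherSampled <- stats::runif(1) < model$propSampled
    fi <- if (fatherSampled) sample.int(nCandidates, 1L) else NA_integer_
    f1 <- if (fatherSampled) cand1[fi, ] else imm1
    f2 <- if (fatherSampled) cand2[fi, ] else imm2
    pick <- function(a, b) ifelse(stats::runif(L) < 0.5, a, b)
    o1 <- pick(cand1[mi, ], cand2[mi, ])
    o2 <- pick(f1, f2)
    err <- stats::runif(L) < e
    for (l in which(err)) {
      g <- .drawGenotypes(1L, codesL[[l]], flist[[l]]$p)
      o1[l] <- g[1L]; o2[l] <- g[2L]
    }
    if (type == "pair") {
      res <- .lodEngine(o1, o2, cand1, cand2, flist, e,
                        needSingle = FALSE, needMM = FALSE)
      lod <- res$lodPair
      if (!model$allowSelfing) diag(lod) <- -Inf
      bp <- .bestPair(lod, matrix(TRUE, nCandidates, nCandidates))
      deltas[b] <- bp$delta
      correct[b] <- fatherSampled &&
        setequal(c(bp$i, bp$j), c(mi, fi))
    } else {
      res <- .lodEngine(o1, o2, cand1, cand2, flist, e,
                        needPair = FALSE, needMM = FALSE)
      ls <- res$lodSingle
      top <- which.max(ls)
      s1 <- ls[top]; ls[top] <- -Inf
      s2 <- suppressWarnings(max(ls))
      deltas[b] <- if (is.finite(s2)) s1 - s2 else s1
      # either true parent counts as a correct single-parent assignment
      correct[b] <- top == mi || (fatherSampled && top == fi)
    }
  }
  ord <- order(deltas, decreasing = TRUE)
  frac <- cumsum(correct[ord]) / seq_len(nS)
  ok <- which(frac >= model$confidence)
  if (!length(ok)) {
    warning("no Delta threshold reaches the requested confidence; ",
            "using the maximum observed Delta")
    crit <- max(deltas)
    succ <- mean(deltas >= crit)
  } else {
    kmax <- max(ok)
    crit <- if (kmax == nS) 0 else max(deltas[ord][kmax], 0)
    succ <- kmax / nS
  }
  if (length(unique(deltas)) == 1L)
    warning("degenerate Delta distribution: all simulated Deltas identical")
  out <- list(criticalDelta = crit, successRate = succ, type = type,
              nSim = nS)
  if (details) {
    out$deltas <- deltas
    out$correct <- correct
  }
  out
}

#' Categorical parentage assignment
#'
#' Assigns, for each offspring (every individual outside the candidate
#' stage, unless `offspringIds` is given), the best candidate parent pair by
#' LOD subject to the mismatch cap, accepting it when its Delta reaches the
#' simulation-calibrated critical value. Offspring whose pair is not accepted
#' fall back to single-parent assignment (own Delta criterion); the single
#' parent is taken as the mother and the father is deemed unsampled (pollen
#' immigrant). Offspring with no accepted parent are seed immigrants. For an
#' accepted pair the spatially nearer member is labelled mother and the other
#' father; a pair of one individual with itself is a selfing event.
#'
#' @param x a [GenotypeDataset-class] (candidates + offspring).
#' @param model a [parentageModel()].
#' @param freqs reference frequencies (default: from the whole of `x`).
#' @param offspringIds optional character vector restricting the offspring.
#' @param exclude optional character vector of ids to drop from the analysis
#'   entirely (explicit exclusion list).
#' @param seed optional integer seed (drives the Delta simulations).
#' @return list of class `"ParentageResult"`: `assignments` (data.frame with
#'   columns `offspring, father, mother, lod, delta, mismatches, category,
#'   classification, pollenDist, seedDist`), `summary` (see
#'   [geneFlowSummary()]), `criticalDelta` (pair and single), `model`.
#' @export
assignParentage <- function(x, model = parentageModel(), freqs = NULL,
                            offspringIds = NULL, exclude = NULL, seed = NULL) {
  if (!is.null(exclude)) x <- x[which(!x@info$id %in% exclude)]
  if (is.null(freqs)) freqs <- alleleFrequencies(x)
  candIds <- x@info$id[x@info$stage == model$candidateStage]
  if (!length(candIds)) stop("no candidates in stage ", model$candidateStage)
  if (is.null(offspringIds))
    offspringIds <- setdiff(x@info$id, candIds)
  nC <- length(candIds)
  ci <- match(candIds, x@info$id)
  critPair <- simulateDeltaCriterion(model, freqs, nC, "pair",
                                     seed = if (is.null(seed)) NULL else seed)
  critSing <- simulateDeltaCriterion(model, freqs, nC, "single",
                                     seed = if (is.null(seed)) NULL else seed + 1L)
  D <- pairwiseDistances(x)
  flist <- .alignFreqs(freqs, x@loci)
  cand1 <- x@allele1[ci, , drop = FALSE]
  cand2 <- x@allele2[ci, , drop = FALSE]
  rows <- vector("list", length(offspringIds))
  for (k in seq_along(offspringIds)) {
    oid <- offspringIds[k]
    oi <- match(oid, x@info$id)
    res <- .lodEngine(x@allele1[oi, ], x@allele2[oi, ], cand1, cand2,
                      flist, model$errorRate)
    allowed <- res$mmPair <= model$maxMismatch
    if (!model$allowSelfing) diag(allowed) <- FALSE
    bp <- .bestPair(res$lodPair, allowed)
    row <- data.frame(offspring = oid, father = NA_character_,
                      mother = NA_character_, lod = NA_real_,
                      delta = NA_real_, mismatches = NA_integer_,
                      category = "unassigned", classification = "seed-immigrant",
                      pollenDist = NA_real_, seedDist = NA_real_,
                      stringsAsFactors = FALSE)
    if (!is.null(bp) && bp$delta >= critPair$criticalDelta &&
        is.finite(bp$lod)) {
      idA <- candIds[bp$i]; idB <- candIds[bp$j]
      if (idA == idB) {
        row$father <- row$mother <- idA
        row$classification <- "selfed"
        row$pollenDist <- 0
        row$seedDist <- D[oid, idA]
      } else {
        # nearer parent is the mother
        if (D[oid, idA] <= D[oid, idB]) {
          row$mother <- idA; row$father <- idB
        } else {
          row$mother <- idB; row$father <- idA
        }
        row$classification <- "outcross-within"
        row$pollenDist <- D[idA, idB]
        row$seedDist <- D[oid, row$mother]
      }
      row$lod <- bp$lod; row$delta <- bp$delta
      row$mismatches <- res$mmPair[bp$i, bp$j]
      row$category <- "assigned-pair"
    } else {
      ls <- res$lodSingle
      ls[res$mmSingle > model$maxMismatch] <- -Inf
      if (any(is.finite(ls))) {
        top <- which.max(ls)
        s1 <- ls[top]; ls2 <- ls; ls2[top] <- -Inf
        s2 <- suppressWarnings(max(ls2))
        dlt <- if (is.finite(s2)) s1 - s2 else s1
        if (dlt >= critSing$criticalDelta && is.finite(s1)) {
          row$mother <- candIds[top]
          row$classification <- "pollen-immigrant"
          row$seedDist <- D[oid, row$mother]
          row$lod <- s1; row$delta <- dlt
          row$mismatches <- res$mmSingle[top]
          row$category <- "assigned-single"
        }
      }
    }
    rows[[k]] <- row
  }
  assignments <- do.call(rbind, rows)
  total <- nrow(assignments)
  selfed <- sum(assignments$classification == "selfed")
  both <- sum(assignments$classification == "outcross-within")
  noParent <- sum(assignments$classification == "seed-immigrant")
  parents <- unique(stats::na.omit(c(assignments$father, assignments$mother)))
  summ <- geneFlowSummary(total = total, bothParents = both, selfed = selfed,
                          noParent = noParent,
                          nCandidates = nC, nParticipating = length(parents))
  structure(list(assignments = assignments, summary = summ,
                 criticalDelta = list(pair = critPair, single = critSing),
                 model = model),
            class = "ParentageResult")
}

#' Gene-flow rates from assignment counts
#'
#' Turns categorical-assignment counts into the standard gene-flow rates; all
#' rates are exact count ratios. `noFather = total - bothParents - selfed` is
#' the number of offspring without an assigned within-plot father, so the
#' pollen immigration rate is `mp = noFather / total`; the seed immigration
#' rate is `noParent / total`; the selfing rate is `selfed / total`.
#'
#' @param total number of offspring analysed.
#' @param bothParents offspring with an accepted within-plot outcross pair.
#' @param selfed offspring with an accepted selfing pair.
#' @param noParent offspring with no accepted parent at all.
#' @param nCandidates,nParticipating optional candidate counts for the
#'   fraction of candidates participating as parents.
#' @return list with the counts, `s`, `mp`, `seedImmigration`,
#'   `propBothParents`, `propAtLeastOneParent`, and (when candidate counts are
#'   given) `propCandidatesParticipating`.
#' @export
geneFlowSummary <- function(total, bothParents, selfed, noParent,
                            nCandidates = NULL, nParticipating = NULL) {
  stopifnot(total >= bothParents + selfed, noParent <= total)
  total <- as.integer(total); bothParents <- as.integer(bothParents)
  selfed <- as.integer(selfed); noParent <- as.integer(noParent)
  noFather <- total - bothParents - selfed
  out <- list(total = total, bothParents = bothParents, selfed = selfed,
              noFather = noFather, noParent = noParent,
              s = selfed / total,
              mp = noFather / total,
              seedImmigration = noParent / total,
              propBothParents = bothParents / total,
              propAtLeastOneParent = (total - noParent) / total)
  if (!is.null(nCandidates) && !is.null(nParticipating))
    out$propCandidatesParticipating <- nParticipating / nCandidates
  out
}

#' Dispersal-distance summaries
#'
#' Summarises realised pollen and seed dispersal from accepted assignments.
#' Pollen distance is the distance between the two assigned parents (selfing
#' events, distance 0, are excluded from the pollen distribution so they do
#' not distort the kernel comparison); seed distance is the offspring-to-
#' mother (nearer parent) distance. The axial variance of pollen dispersal is
#' taken as half the variance of the pollen distances under isotropy, giving
#' the effective pollination neighbourhood area \eqn{A_{ep} = 2\pi\sigma_p^2}
#' and its circular radius \eqn{\sqrt{A_{ep}/\pi}}. The pollen-distance
#' distribution is compared with the all-pairs intermate (candidate-candidate)
#' distance distribution by a two-sample Kolmogorov-Smirnov test, and the
#' mating-frequency/distance association is the squared Pearson correlation of
#' per-class mating counts with class mean distance over 10 equal-frequency
#' distance classes.
#'
#' @param result a `"ParentageResult"` from [assignParentage()], or a
#'   data.frame of assignments with the same columns.
#' @param x the [GenotypeDataset-class] the assignments refer to.
#' @param candidateStage stage of the candidate parents (for the intermate
#'   distance distribution).
#' @param nClasses distance classes for the R-squared binning.
#' @return list with `pollen` and `seed` components (`distances`, `mean`,
#'   `median`, `sd`, `R2`), `sigmaP2` (axial variance, m^2), `Aep_m2`,
#'   `Aep_ha`, `radius`, and `ks` (statistic `D` and `p`).
#' @export
dispersalSummaries <- function(result, x, candidateStage = "reproductive",
                               nClasses = 10) {
  asg <- if (inherits(result, "ParentageResult")) result$assignments else result
  dp <- asg$pollenDist[asg$classification == "outcross-within"]
  ds <- asg$seedDist[!is.na(asg$seedDist)]
  if (!length(dp)) stop("no accepted outcross assignments: no pollen distances")
  cand <- subsetStage(x, candidateStage)
  Dc <- pairwiseDistances(cand)
  intermate <- Dc[upper.tri(Dc)]
  sigmaP2 <- stats::var(dp) / 2
  Aep <- 2 * pi * sigmaP2
  ks <- suppressWarnings(stats::ks.test(dp, intermate))
  classR2 <- function(d, ref) {
    bounds <- distanceClasses(ref, nClasses)
    cls <- .pairClass(d, bounds)
    cls[d > bounds[nClasses]] <- nClasses
    counts <- tabulate(cls, nClasses)
    mids <- vapply(seq_len(nClasses), function(c) {
      inC <- .pairClass(ref, bounds) == c
      mean(ref[inC])
    }, 1)
    stats::cor(counts, mids)^2
  }
  offCandDist <- {
    D <- pairwiseDistances(x)
    offIds <- asg$offspring
    as.numeric(D[offIds, cand@info$id, drop = FALSE])
  }
  list(
    pollen = list(distances = dp, mean = mean(dp), median = stats::median(dp),
                  sd = if (length(dp) > 1) stats::sd(dp) else NA_real_,
                  R2 = classR2(dp, intermate)),
    seed = list(distances = ds, mean = mean(ds), median = stats::median(ds),
                sd = if (length(ds) > 1) stats::sd(ds) else NA_real_,
                R2 = classR2(ds, offCandDist)),
    sigmaP2 = sigmaP2,
    Aep_m2 = Aep, Aep_ha = Aep / 1e4,
    radius = sqrt(Aep / pi),
    ks = list(D = unname(ks$statistic), p = ks$p.value)
  )
}

#' Effective pollination neighbourhood from the axial SD
#'
#' \eqn{A_{ep} = 2\pi\sigma_p^2} with circular radius \eqn{\sqrt{A_{ep}/\pi}
#' = \sigma_p\sqrt{2}}.
#'
#' @param sigmaP axial standard deviation of pollen dispersal, meters.
#' @return list with `Aep_m2`, `Aep_ha`, `radius` (m).
#' @export
pollinationNeighborhood <- function(sigmaP) {
  Aep <- 2 * pi * sigmaP^2
  list(Aep_m2 = Aep, Aep_ha = Aep / 1e4, radius = sqrt(Aep / pi))
}
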
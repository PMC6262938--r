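#' Precompute genotype likelihood components for the neighborhood model
#'
#' The spatially explicit mixed mating model decomposes each offspring's
#' paternity into selfing (probability `s`), pollen immigration (`mp`), and
#' kernel-weighted siring by a within-plot candidate (`1 - s - mp`). The
#' genotypic transition probabilities do not depend on the mating parameters,
#' so they are computed once here and reused across likelihood evaluations.
#'
#' Two mother modes are supported: `"known"` (a mother id per offspring, e.g.
#' the nearer parent of a categorical assignment) and `"marginal"`, which
#' treats the mother as unknown and marginalises over all candidate mothers
#' weighted by a seed dispersal kernel evaluated at the offspring-candidate
#' distance (the seed kernel is then fitted jointly).
#'
#' @param x a [GenotypeDataset-class].
#' @param candidateStage stage of the candidate parents.
#' @param mothers named character vector (offspring id -> mother id) for the
#'   `"known"` mode, or `NULL` for `"marginal"`.
#' @param offspringIds offspring to include (default: all non-candidates;
#'   in `"known"` mode, those with a resolvable mother -- others are dropped
#'   and counted).
#' @param freqs reference allele frequencies (default: whole sample).
#' @param errorRate per-locus class-I genotyping error rate.
#' @return an opaque list consumed by [nmLoglikelihood()] and
#'   [fitNeighborhoodModel()]; element `nDropped` counts offspring excluded
#'   for lack of a mother.
#' @export
nmPrecompute <- function(x, candidateStage = "reproductive", mothers = NULL,
                         offspringIds = NULL, freqs = NULL, errorRate = 0.01) {
  if (is.null(freqs)) freqs <- alleleFrequencies(x)
  candIds <- x@info$id[x@info$stage == candidateStage]
  nC <- length(candIds)
  if (nC < 2L) stop("need at least two candidates")
  if (is.null(offspringIds)) offspringIds <- setdiff(x@info$id, candIds)
  mode <- if (is.null(mothers)) "marginal" else "known"
  nDropped <- 0L
  if (mode == "known") {
    mid <- mothers[offspringIds]
    ok <- !is.na(mid) & mid %in% candIds
    nDropped <- sum(!ok)
    offspringIds <- offspringIds[ok]
    mid <- mid[ok]
  }
  nO <- length(offspringIds)
  if (!nO) stop("no usable offspring")
  ci <- match(candIds, x@info$id)
  oi <- match(offspringIds, x@info$id)
  flist <- .alignFreqs(freqs, x@loci)
  cand1 <- x@allele1[ci, , drop = FALSE]
  cand2 <- x@allele2[ci, , drop = FALSE]
  D <- pairwiseDistances(x)
  Dcc <- D[candIds, candIds]
  e <- errorRate
  # background (HWE) product per offspring
  B <- vapply(seq_len(nO), function(k) {
    o1 <- x@allele1[oi[k], ]; o2 <- x@allele2[oi[k], ]
    pr <- 1
    for (l in seq_along(o1)) {
      if (is.na(o1[l]) || is.null(flist[[l]])) next
      p1 <- .lookupFreq(flist[[l]]$p, o1[l], flist[[l]]$gc)
      p2 <- .lookupFreq(flist[[l]]$p, o2[l], flist[[l]]$gc)
      pr <- pr * .hweProb(p1, p2, o1[l] != o2[l])
    }
    pr
  }, 1)
  if (mode == "known") {
    mIdx <- match(mid, candIds)
    M <- matrix(NA_real_, nO, nC)     # T_e(g_o | g_m(o), g_f) product
    S <- numeric(nO)                  # selfing: T_e(g_o | g_m, g_m)
    Bm <- numeric(nO)                 # immigrant father: single-parent L | mother
    for (k in seq_len(nO)) {
      res <- .lodEngine(x@allele1[oi[k], ], x@allele2[oi[k], ],
                        cand1, cand2, flist, e, needMM = FALSE)
      Tpair <- exp(res$lodPair) * B[k]   # back to likelihood scale
      M[k, ] <- Tpair[mIdx[k], ]
      S[k] <- Tpair[mIdx[k], mIdx[k]]
      Bm[k] <- exp(res$lodSingle[mIdx[k]]) * B[k]
    }
    list(mode = "known", nOff = nO, nCand = nC, offspringIds = offspringIds,
         candIds = candIds, mIdx = mIdx, M = M, S = S, Bm = Bm, B = B,
         Dcc = Dcc, nDropped = nDropped)
  } else {
    M3 <- array(NA_real_, c(nO, nC, nC))
    Bs <- matrix(NA_real_, nO, nC)    # single-parent L given each mother
    for (k in seq_len(nO)) {
      res <- .lodEngine(x@allele1[oi[k], ], x@allele2[oi[k], ],
                        cand1, cand2, flist, e, needMM = FALSE)
      M3[k, , ] <- exp(res$lodPair) * B[k]
      Bs[k, ] <- exp(res$lodSingle) * B[k]
    }
    Doc <- D[offspringIds, candIds, drop = FALSE]
    list(mode = "marginal", nOff = nO, nCand = nC,
         offspringIds = offspringIds, candIds = candIds,
         M3 = M3, Bs = Bs, B = B, Dcc = Dcc, Doc = Doc, nDropped = nDropped)
  }
}

#' Neighborhood-model log-likelihood
#'
#' Per offspring `o` with mother `m`:
#' \deqn{L_o = s\,T(g_o|g_m,g_m) + m_p\,P_{bg}(g_o|g_m) +
#'   (1-s-m_p) \sum_{f \ne m} w_{mf}\, T(g_o|g_m,g_f)}
#' with kernel weights \eqn{w_{mf} \propto p(d_{mf})} normalised over the
#' candidate fathers \eqn{f \ne m}, and the background term drawing the
#' paternal gamete from the reference allele pool. In the marginal-mother mode
#' the same expression is averaged over candidate mothers with seed-kernel
#' weights \eqn{v_{om} \propto p_s(d_{om})}.
#'
#' @param pre a precompute object from [nmPrecompute()].
#' @param s selfing probability (`s >= 0`).
#' @param mp pollen immigration probability (`mp >= 0`, `s + mp <= 1`).
#' @param pollenKernel a [KernelParams-class].
#' @param seedKernel a [KernelParams-class]; required in marginal mode.
#' @return total log-likelihood (numeric scalar).
#' @export
nmLoglikelihood <- function(pre, s, mp, pollenKernel, seedKernel = NULL) {
  if (s < 0 || mp < 0 || s + mp > 1)
    stop("require s, mp >= 0 and s + mp <= 1")
  W <- expPowerPdf(pre$Dcc, pollenKernel)
  diag(W) <- 0
  rs <- rowSums(W)
  if (any(rs <= 0) || any(!is.finite(rs)))
    stop("pollen kernel weights degenerate (underflow); narrow the kernel")
  W <- W / rs
  if (pre$mode == "known") {
    Wm <- W[pre$mIdx, , drop = FALSE]  # w_{m(o), f}; w_{mm} = 0 already
    within <- rowSums(pre$M * Wm)
    L <- s * pre$S + mp * pre$Bm + (1 - s - mp) * within
  } else {
    if (is.null(seedKernel)) stop("marginal mode needs a seedKernel")
    V <- expPowerPdf(pre$Doc, seedKernel)
    vs <- rowSums(V)
    if (any(vs <= 0) || any(!is.finite(vs)))
      stop("seed kernel weights degenerate (underflow); narrow the kernel")
    V <- V / vs
    nO <- pre$nOff; nC <- pre$nCand
    A <- matrix(0, nO, nC)        # within-plot outcross term per mother
    for (m in seq_len(nC)) {
      A[, m] <- pre$M3[, m, ] %*% W[m, ]
    }
    Self <- matrix(pre$M3[cbind(rep(seq_len(nO), nC),
                                rep(seq_len(nC), each = nO),
                                rep(seq_len(nC), each = nO))], nO, nC)
    L <- rowSums(V * (s * Self + mp * pre$Bs + (1 - s - mp) * A))
  }
  if (any(L <= 0)) return(-Inf)
  sum(log(L))
}

#' Fit the neighborhood mating model by maximum likelihood
#'
#' Maximises the mixed-mating likelihood over `(s, mp, a, b)` (plus the seed
#' kernel `(a_s, b_s)` in marginal-mother mode) with a derivative-free
#' Nelder-Mead search on transformed parameters (multinomial logit for
#' `s, mp`; log scale for kernel parameters, shape constrained to (0.05, 10)),
#' restarted from jittered starting points because the likelihood can be
#' multimodal in the kernel parameters.
#'
#' @param pre a precompute object from [nmPrecompute()].
#' @param starts number of jittered starts (default 8).
#' @param seed optional integer seed (jitter reproducibility).
#' @param fixShape optional fixed value for the pollen-kernel shape `b`
#'   (e.g. 2 for a Gaussian kernel); `NULL` = fitted.
#' @param control passed to [stats::optim()] (default `maxit = 500`).
#' @return list of class `"NeighborhoodFit"`: `s`, `mp`, `pollenKernel`,
#'   `delta` (mean pollen dispersal distance), `seedKernel` and `deltaSeed`
#'   (marginal mode), `loglik`, `converged`, `nOff`, `starts` (per-start
#'   log-likelihoods).
#' @export
fitNeighborhoodModel <- function(pre, starts = 8, seed = NULL,
                                 fixShape = NULL,
                                 control = list(maxit = 500)) {
  if (!is.null(seed)) set.seed(seed)
  marginal <- pre$mode == "marginal"
  unpack <- function(z) {
    es <- exp(z[1]); em <- exp(z[2])
    den <- 1 + es + em
    b <- if (is.null(fixShape)) 0.05 + 9.95 * stats::plogis(z[4]) else fixShape
    out <- list(s = es / den, mp = em / den,
                pk = KernelParams(exp(z[3]), b))
    if (marginal)
      out$sk <- KernelParams(exp(z[5]), 0.05 + 9.95 * stats::plogis(z[6]))
    out
  }
  negll <- function(z) {
    par <- unpack(z)
    v <- tryCatch(
      nmLoglikelihood(pre, par$s, par$mp, par$pk,
                      if (marginal) par$sk else NULL),
      error = function(e) -Inf)
    if (!is.finite(v)) 1e10 else -v
  }
  dscale <- log(max(stats::median(pre$Dcc[upper.tri(pre$Dcc)]), 1))
  base <- c(log(0.05), log(0.4), dscale, 0)
  if (marginal) base <- c(base, dscale - 1, 0)
  bestFit <- NULL
  startLL <- numeric(starts)
  for (i in seq_len(starts)) {
    z0 <- base + if (i == 1) 0 else stats::rnorm(length(base), 0, 1)
    fit <- stats::optim(z0, negll, method = "Nelder-Mead", control = control)
    startLL[i] <- -fit$value
    if (is.null(bestFit) || fit$value < bestFit$value) bestFit <- fit
  }
  par <- unpack(bestFit$par)
  converged <- bestFit$convergence == 0
  if (!converged)
    warning("optimizer did not report convergence; returning best point")
  out <- list(s = par$s, mp = par$mp, pollenKernel = par$pk,
              delta = kernelMeanDistance(par$pk),
              loglik = -bestFit$value, converged = converged,
              nOff = pre$nOff, starts = startLL)
  if (marginal) {
    out$seedKernel <- par$sk
    out$deltaSeed <- kernelMeanDistance(par$sk)
  }
  structure(out, class = "NeighborhoodFit")
}
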
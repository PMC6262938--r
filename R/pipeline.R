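#' Run the full analysis pipeline
#'
#' Orchestrates the whole analysis on a mapped, stage-labelled SSR dataset:
#' per-stage diversity indices with the fixation-index permutation test,
#' per-stage Loiselle coancestry with the SGS correlogram, regression slope
#' and Sp statistic, group coancestry and effective size, categorical
#' parentage with gene-flow and dispersal summaries, and (optionally) the
#' neighborhood mating model fit.
#'
#' @param x a [GenotypeDataset-class].
#' @param candidateStage stage of the candidate parents.
#' @param profile `"default"` (1,000 F permutations; 10,000 SGS permutations;
#'   10,000 Delta simulation replicates) or `"fast"` (100 / 1,000 / 1,000).
#' @param errorRate genotyping error rate for the parentage/NM likelihoods.
#' @param nmMode `"known"` (nearer assigned parent as mother), `"marginal"`,
#'   or `"skip"`.
#' @param nmStarts optimizer starts for the NM fit.
#' @param seed integer seed; all stochastic stages derive their seeds from it
#'   and record them.
#' @param exclude optional ids to exclude.
#' @param out optional path: the report is additionally written as JSON.
#' @return list of class `"AnalysisReport"` with elements `diversity`, `sgs`
#'   (per stage: summary + correlogram), `effectiveSize`, `parentage`
#'   (assignments + gene-flow summary + exclusion probability), `dispersal`,
#'   `nm` (unless skipped), and `provenance`.
#' @export
runPipeline <- function(x, candidateStage = "reproductive",
                        profile = c("default", "fast"),
                        errorRate = 0.01,
                        nmMode = c("known", "marginal", "skip"),
                        nmStarts = 8, seed = 1, exclude = NULL,
                        out = NULL) {
  profile <- match.arg(profile)
  nmMode <- match.arg(nmMode)
  perms <- if (profile == "default") {
    list(f = 1000, sgs = 10000, sim = 10000)
  } else list(f = 100, sgs = 1000, sim = 1000)
  if (!is.null(exclude)) x <- x[which(!x@info$id %in% exclude)]
  stages <- unique(x@info$stage)
  report <- list()
  report$provenance <- list(
    package = "palmflow",
    version = as.character(utils::packageVersion("palmflow")),
    rversion = R.version.string,
    seed = seed, profile = profile, errorRate = errorRate,
    nIndividuals = nIndividuals(x), nLoci = nLoci(x),
    stages = as.list(table(x@info$stage)),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  report$diversity <- diversitySummary(x, stages, nPerm = perms$f, seed = seed)
  D <- pairwiseDistances(x)
  report$sgs <- list()
  report$effectiveSize <- list()
  for (i in seq_along(stages)) {
    s <- stages[i]
    xs <- subsetStage(x, s)
    coan <- loiselleCoancestry(xs)
    Ds <- D[xs@info$id, xs@info$id]
    classes <- distanceClasses(Ds)
    corr <- sgsCorrelogram(coan, Ds, classes, nPerm = perms$sgs,
                           seed = seed + 100 + i)
    sp <- spStatistic(coan, Ds, classes, nPerm = perms$sgs,
                      seed = seed + 200 + i)
    report$sgs[[s]] <- list(summary = sp, correlogram = corr)
    Fhat <- report$diversity$F[report$diversity$stage == s]
    report$effectiveSize[[s]] <- groupCoancestry(coan, F = Fhat)
  }
  model <- parentageModel(candidateStage = candidateStage,
                          errorRate = errorRate, nSim = perms$sim)
  freqs <- alleleFrequencies(x)
  par <- assignParentage(x, model, freqs = freqs, seed = seed + 300)
  par$exclusionProbability <- exclusionProbabilityPairs(freqs)$Pp
  report$parentage <- par
  report$dispersal <- tryCatch(
    dispersalSummaries(par, x, candidateStage),
    error = function(e) list(error = conditionMessage(e)))
  if (nmMode != "skip") {
    mothers <- NULL
    if (nmMode == "known") {
      asg <- par$assignments
      mothers <- setNames(asg$mother, asg$offspring)
    }
    pre <- nmPrecompute(x, candidateStage, mothers = mothers,
                        freqs = freqs, errorRate = errorRate)
    report$nm <- fitNeighborhoodModel(pre, starts = nmStarts,
                                      seed = seed + 400)
  }
  class(report) <- "AnalysisReport"
  if (!is.null(out)) {
    strip <- function(z) {
      if (is(z, "KernelParams")) return(list(a = z@a, b = z@b))
      if (inherits(z, "ParentageResult") || inherits(z, "NeighborhoodFit") ||
          inherits(z, "ParentageModel")) z <- unclass(z)
      if (is.list(z) && !is.data.frame(z)) return(lapply(z, strip))
      z
    }
    jsonlite::write_json(strip(unclass(report)), out, auto_unbox = TRUE,
                         digits = NA, null = "null", force = TRUE)
  }
  report
}
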
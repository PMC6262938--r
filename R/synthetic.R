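#' Simulation settings for a mapped SSR population
#'
#' The defaults emulate the field design this package targets: an elongated
#' ~10 ha riverside plot (1500 m x 70 m, so intermate distances span
#' 0-1.5 km), 59 reproductive adults, 189 regenerated offspring labelled
#' immature/young/seedling in study-like proportions (70/60/59), 18
#' microsatellite loci with 4-18 alleles each, a selfing rate of 0.04, pollen
#' immigration of 0.4, a fat-ish exponential pollen kernel (a = 200 m, b = 1)
#' and a shorter seed kernel (a = 50 m, b = 1), class-I genotyping error 0.01
#' and 2% missing calls.
#'
#' @param plotWidth,plotHeight plot dimensions, meters.
#' @param nAdults number of reproductive adults.
#' @param adultProcess `"uniform"`, or `list(kind = "clustered", nParents =,
#'   sd =)` for a Thomas-like clustered point process.
#' @param nOffspring number of offspring.
#' @param offspringStages named numeric of stage weights for offspring labels.
#' @param nLoci number of loci.
#' @param allelesPerLocus integer vector of allele counts, recycled over loci
#'   (default: cycles over 4..18).
#' @param freqSharpness symmetric-Dirichlet concentration of the founder
#'   allele frequencies (1 = uniform over the simplex; smaller = spikier).
#' @param s true selfing probability.
#' @param mp true pollen-immigration probability (`s + mp <= 1`).
#' @param pollenKernel,seedKernel [KernelParams-class] objects.
#' @param errorRate class-I genotyping error probability per genotype.
#' @param missingRate probability that a call is masked as missing.
#' @param immigrantDivergence if > 0, immigrant allele frequencies are
#'   resampled from a Dirichlet centred on the plot frequencies with
#'   concentration `1/immigrantDivergence`, creating private immigrant
#'   alleles; 0 = immigrants share the plot's pool (immigration hardest to
#'   detect).
#' @param seed integer RNG seed.
#' @return list of class `"SimulationConfig"`.
#' @export
simulationConfig <- function(plotWidth = 1500, plotHeight = 70,
                             nAdults = 59, adultProcess = "uniform",
                             nOffspring = 189,
                             offspringStages = c(immature = 70, young = 60,
                                                 seedling = 59),
                             nLoci = 18,
                             allelesPerLocus = 4:18,
                             freqSharpness = 1,
                             s = 0.04, mp = 0.4,
                             pollenKernel = KernelParams(200, 1),
                             seedKernel = KernelParams(50, 1),
                             errorRate = 0.01, missingRate = 0.02,
                             immigrantDivergence = 0,
                             seed = NULL) {
  stopifnot(s >= 0, mp >= 0, s + mp <= 1,
            nAdults >= 2, nOffspring >= 1, nLoci >= 1,
            plotWidth > 0, plotHeight > 0,
            errorRate >= 0, errorRate < 1, missingRate >= 0, missingRate < 1)
  structure(list(plotWidth = plotWidth, plotHeight = plotHeight,
                 nAdults = nAdults, adultProcess = adultProcess,
                 nOffspring = nOffspring, offspringStages = offspringStages,
                 nLoci = nLoci, allelesPerLocus = allelesPerLocus,
                 freqSharpness = freqSharpness, s = s, mp = mp,
                 pollenKernel = pollenKernel, seedKernel = seedKernel,
                 errorRate = errorRate, missingRate = missingRate,
                 immigrantDivergence = immigrantDivergence, seed = seed),
            class = "SimulationConfig")
}

#' Forward-simulate a mapped SSR population with known pedigree
#'
#' Adults are placed by the configured spatial process and given
#' Hardy-Weinberg genotypes from per-locus founder frequencies (symmetric
#' Dirichlet draws). Each offspring picks a mother uniformly among adults;
#' with probability `s` it is selfed, else with probability `mp` sired by an
#' unsampled immigrant (genotype drawn from the immigrant frequency pool),
#' else by a within-plot father drawn with probability proportional to the
#' pollen-kernel density at the mother-father distance. Offspring genotypes
#' are Mendelian gamete draws; the offspring position is the mother's plus a
#' seed-kernel displacement, reflected at the plot boundary. Observed
#' genotypes are then perturbed by the class-I error model (a genotype is
#' replaced by a random Hardy-Weinberg genotype with probability
#' `errorRate`) and masked at the missing rate. The true pedigree and
#' dispersal distances are recorded.
#'
#' @param config a [simulationConfig()].
#' @return list with `data` (a [GenotypeDataset-class]: adults are stage
#'   `"reproductive"`, ids `A1..`; offspring ids `O1..`) and `truth`
#'   (data.frame per offspring: `offspring, mother, father` (`"IMMIGRANT"`
#'   for immigrant sires), `selfed`, `pollenDist` (NA for immigrants),
#'   `seedDist`; the generating config is attached as attribute `config`).
#' @export
simulatePopulation <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  if (!is.null(config$seed)) set.seed(config$seed)
  W <- config$plotWidth; H <- config$plotHeight
  nA <- config$nAdults; nO <- config$nOffspring
  L <- config$nLoci
  # adult positions
  ap <- config$adultProcess
  if (identical(ap, "uniform")) {
    ax <- stats::runif(nA, 0, W); ay <- stats::runif(nA, 0, H)
  } else if (is.list(ap) && identical(ap$kind, "clustered")) {
    cx <- stats::runif(ap$nParents, 0, W); cy <- stats::runif(ap$nParents, 0, H)
    pick <- sample.int(ap$nParents, nA, replace = TRUE)
    pos <- .reflectInto(cbind(cx[pick] + stats::rnorm(nA, 0, ap$sd),
                              cy[pick] + stats::rnorm(nA, 0, ap$sd)), W, H)
    ax <- pos[, 1]; ay <- pos[, 2]
  } else stop("unknown adultProcess")
  # founder frequencies
  kPer <- rep_len(config$allelesPerLocus, L)
  freqs <- lapply(kPer, function(k) {
    p <- .rdirichlet(rep(config$freqSharpness, k))
    # avoid effectively-lost alleles so the realised allele counts match
    p <- pmax(p, 0.01 / k)
    p / sum(p)
  })
  immFreqs <- if (config$immigrantDivergence > 0) {
    lapply(freqs, function(p) .rdirichlet(p / config$immigrantDivergence))
  } else freqs
  codes <- lapply(kPer, seq_len)
  # true adult genotypes
  ad1 <- matrix(NA_integer_, nA, L); ad2 <- matrix(NA_integer_, nA, L)
  for (l in seq_len(L)) {
    g <- .drawGenotypes(nA, codes[[l]], freqs[[l]])
    ad1[, l] <- g[1L, ]; ad2[, l] <- g[2L, ]
  }
  Daa <- as.matrix(stats::dist(cbind(ax, ay)))
  Wk <- expPowerPdf(Daa, config$pollenKernel)
  diag(Wk) <- 0
  if (any(rowSums(Wk) <= 0) || any(!is.finite(Wk)))
    stop("pollen kernel underflows across the plot; ",
         "use a wider scale or smaller plot")
  of1 <- matrix(NA_integer_, nO, L); of2 <- matrix(NA_integer_, nO, L)
  mother <- integer(nO); father <- integer(nO); selfed <- logical(nO)
  ox <- numeric(nO); oy <- numeric(nO)
  for (k in seq_len(nO)) {
    m <- sample.int(nA, 1L)
    u <- stats::runif(1)
    if (u < config$s) {
      f <- m; selfed[k] <- TRUE
    } else if (u < config$s + config$mp) {
      f <- NA_integer_
    } else {
      f <- sample.int(nA, 1L, prob = Wk[m, ])
    }
    mother[k] <- m; father[k] <- f
    halfM <- ifelse(stats::runif(L) < 0.5, ad1[m, ], ad2[m, ])
    halfF <- if (is.na(f)) {
      vapply(seq_len(L), function(l) {
        g <- .drawGenotypes(1L, codes[[l]], immFreqs[[l]])
        if (stats::runif(1) < 0.5) g[1L] else g[2L]
      }, 1L)
    } else ifelse(stats::runif(L) < 0.5, ad1[f, ], ad2[f, ])
    of1[k, ] <- halfM; of2[k, ] <- halfF
    disp <- sampleKernel(1L, config$seedKernel)
    pos <- .reflectInto(cbind(ax[m] + disp[1, "dx"], ay[m] + disp[1, "dy"]),
                        W, H)
    ox[k] <- pos[1, 1]; oy[k] <- pos[1, 2]
  }
  # observation model: class-I error then missingness
  obs <- function(a1, a2) {
    n <- nrow(a1)
    for (l in seq_len(L)) {
      err <- which(stats::runif(n) < config$errorRate)
      if (length(err)) {
        g <- .drawGenotypes(length(err), codes[[l]], freqs[[l]])
        a1[err, l] <- g[1L, ]; a2[err, l] <- g[2L, ]
      }
      mis <- stats::runif(n) < config$missingRate
      a1[mis, l] <- NA_integer_; a2[mis, l] <- NA_integer_
    }
    list(a1, a2)
  }
  oa <- obs(ad1, ad2); oo <- obs(of1, of2)
  wts <- config$offspringStages / sum(config$offspringStages)
  cnt <- floor(wts * nO)
  short <- nO - sum(cnt)
  if (short > 0) {
    extra <- order(wts * nO - cnt, decreasing = TRUE)[seq_len(short)]
    cnt[extra] <- cnt[extra] + 1L
  }
  stageLab <- sample(rep(names(cnt), cnt))
  info <- data.frame(
    id = c(paste0("A", seq_len(nA)), paste0("O", seq_len(nO))),
    stage = c(rep("reproductive", nA), stageLab),
    x = c(ax, ox), y = c(ay, oy), stringsAsFactors = FALSE)
  lociNames <- sprintf("L%02d", seq_len(L))
  data <- GenotypeDataset(info, lociNames,
                          rbind(oa[[1]], oo[[1]]), rbind(oa[[2]], oo[[2]]))
  motherId <- paste0("A", mother)
  fatherId <- ifelse(is.na(father), "IMMIGRANT", paste0("A", father))
  pollenDist <- ifelse(is.na(father), NA_real_,
                       Daa[cbind(mother, ifelse(is.na(father), mother, father))])
  seedDist <- sqrt((ox - ax[mother])^2 + (oy - ay[mother])^2)
  truth <- data.frame(offspring = paste0("O", seq_len(nO)),
                      mother = motherId, father = fatherId,
                      selfed = selfed, pollenDist = pollenDist,
                      seedDist = seedDist, stringsAsFactors = FALSE)
  attr(truth, "config") <- config
  list(data = data, truth = truth)
}

#' Write simulation fixtures to disk
#'
#' Writes the genotype table in both dialects (CSV and GenePop + coordinate
#' side file), the truth table, and a JSON snapshot of the generating
#' configuration. Deterministic given the data.
#'
#' @param data a [GenotypeDataset-class].
#' @param truth truth data.frame from [simulatePopulation()].
#' @param dir output directory (created if needed).
#' @return named character vector of the files written, invisibly.
#' @export
writeFixtures <- function(data, truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- c(csv = file.path(dir, "genotypes.csv"),
             genepop = file.path(dir, "genotypes.gen"),
             coords = file.path(dir, "genotypes.gen.coords.csv"),
             truth = file.path(dir, "truth.csv"),
             config = file.path(dir, "config.json"))
  writeGenotypes(data, files[["csv"]], "csv")
  writeGenotypes(data, files[["genepop"]], "genepop",
                 coordsPath = files[["coords"]])
  utils::write.csv(truth, files[["truth"]], row.names = FALSE, quote = FALSE)
  cfg <- attr(truth, "config")
  if (!is.null(cfg)) {
    cfg$pollenKernel <- list(a = cfg$pollenKernel@a, b = cfg$pollenKernel@b)
    cfg$seedKernel <- list(a = cfg$seedKernel@a, b = cfg$seedKernel@b)
    jsonlite::write_json(unclass(cfg), files[["config"]], auto_unbox = TRUE,
                         digits = NA, null = "null")
  }
  invisible(files)
}
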
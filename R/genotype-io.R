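#' Read mapped SSR genotypes
#'
#' Reads a genotype table in one of two dialects.
#'
#' **CSV dialect**: header `id,stage,x,y,<locus>.1,<locus>.2,...` with one row
#' per individual; allele code `0` (or empty) marks a missing call, and both
#' columns of a locus must then be missing.
#'
#' **GenePop dialect**: title line, one locus name per line (or a single
#' comma-separated line), `POP` markers, then `id , g1 g2 ...` rows with 4- or
#' 6-digit concatenated allele codes; `0000`/`000000` marks a missing call.
#' GenePop files carry no stage or coordinates, so `coordsPath` must point to
#' a CSV with columns `id,stage,x,y`.
#'
#' @param path path to the genotype file.
#' @param dialect `"csv"` or `"genepop"`.
#' @param coordsPath optional path to an `id,stage,x,y` CSV (required for
#'   GenePop input).
#' @return A [GenotypeDataset-class].
#' @export
readGenotypes <- function(path, dialect = c("csv", "genepop"),
                          coordsPath = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "csv") .readGenotypesCsv(path) else {
    if (is.null(coordsPath))
      stop("GenePop input requires coordinates via coordsPath")
    .readGenotypesGenepop(path, coordsPath)
  }
}

.readGenotypesCsv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("id", "stage", "x", "y")
  if (!all(need %in% names(tab)))
    stop("CSV must have columns id, stage, x, y; got: ",
         paste(names(tab)[1:min(4, ncol(tab))], collapse = ", "))
  gcols <- setdiff(names(tab), need)
  if (length(gcols) %% 2L != 0L)
    stop("odd number of allele columns (", length(gcols),
         "): every locus needs a .1 and a .2 column")
  loci <- unique(sub("\\.[12]$", "", gcols))
  if (!all(c(paste0(loci, ".1"), paste0(loci, ".2")) %in% gcols))
    stop("allele columns must come in <locus>.1/<locus>.2 pairs")
  if (anyDuplicated(tab$id))
    stop("duplicate id: ", tab$id[anyDuplicated(tab$id)][1])
  a1 <- as.matrix(tab[, paste0(loci, ".1"), drop = FALSE])
  a2 <- as.matrix(tab[, paste0(loci, ".2"), drop = FALSE])
  storage.mode(a1) <- "integer"; storage.mode(a2) <- "integer"
  a1[a1 == 0L] <- NA_integer_; a2[a2 == 0L] <- NA_integer_
  half <- which(is.na(a1) != is.na(a2), arr.ind = TRUE)
  if (nrow(half) > 0L)
    stop("half-call (one allele missing) at row ", half[1, 1] + 1L,
         " (line ", half[1, 1] + 1L, " of ", path, "), locus ",
         loci[half[1, 2]])
  GenotypeDataset(tab[, need], loci, a1, a2)
}

.readGenotypesGenepop <- function(path, coordsPath) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 3L) stop("malformed GenePop file: too short")
  body <- lines[-1L]
  popAt <- grep("^\\s*pop\\s*$", body, ignore.case = TRUE)
  if (length(popAt) == 0L) stop("malformed GenePop file: no POP line")
  lociLines <- body[seq_len(popAt[1] - 1L)]
  loci <- trimws(unlist(strsplit(lociLines, ",")))
  loci <- loci[nzchar(loci)]
  rows <- body[-seq_len(popAt[1])]
  rows <- rows[!grepl("^\\s*pop\\s*$", rows, ignore.case = TRUE)]
  ids <- character(length(rows))
  a1 <- matrix(NA_integer_, length(rows), length(loci))
  a2 <- matrix(NA_integer_, length(rows), length(loci))
  for (r in seq_along(rows)) {
    parts <- strsplit(rows[r], ",")[[1]]
    if (length(parts) != 2L)
      stop("malformed GenePop genotype row (line with id '",
           trimws(rows[r]), "')")
    ids[r] <- trimws(parts[1])
    codes <- strsplit(trimws(parts[2]), "\\s+")[[1]]
    if (length(codes) != length(loci))
      stop("row for id ", ids[r], " has ", length(codes),
           " genotypes, expected ", length(loci))
    w <- nchar(codes)
    if (!all(w %in% c(4L, 6L)))
      stop("row for id ", ids[r], ": allele codes must be 4 or 6 digits")
    half <- w / 2L
    x1 <- as.integer(substr(codes, 1L, half))
    x2 <- as.integer(substr(codes, half + 1L, w))
    x1[x1 == 0L] <- NA_integer_; x2[x2 == 0L] <- NA_integer_
    bad <- is.na(x1) != is.na(x2)
    if (any(bad))
      stop("half-call for id ", ids[r], " at locus ", loci[which(bad)[1]])
    a1[r, ] <- x1; a2[r, ] <- x2
  }
  if (anyDuplicated(ids)) stop("duplicate id: ", ids[anyDuplicated(ids)][1])
  co <- utils::read.csv(coordsPath, stringsAsFactors = FALSE)
  if (!all(c("id", "stage", "x", "y") %in% names(co)))
    stop("coordinates file must have columns id, stage, x, y")
  m <- match(ids, as.character(co$id))
  if (anyNA(m)) stop("no coordinates for id: ", ids[which(is.na(m))[1]])
  info <- data.frame(id = ids, stage = as.character(co$stage[m]),
                     x = co$x[m], y = co$y[m], stringsAsFactors = FALSE)
  GenotypeDataset(info, loci, a1, a2)
}

#' Write mapped SSR genotypes
#'
#' Inverse of [readGenotypes()]; a write/read round trip reproduces the
#' dataset exactly. For the GenePop dialect the stage and coordinates go to a
#' side CSV at `coordsPath`, and allele codes are zero-padded to 3 digits
#' (6-digit genotypes) when any code exceeds 99, else 2 digits.
#'
#' @param x a [GenotypeDataset-class].
#' @param path output file path.
#' @param dialect `"csv"` or `"genepop"`.
#' @param coordsPath side-file path for GenePop coordinates (default:
#'   `paste0(path, ".coords.csv")`).
#' @return `path`, invisibly.
#' @export
writeGenotypes <- function(x, path, dialect = c("csv", "genepop"),
                           coordsPath = paste0(path, ".coords.csv")) {
  dialect <- match.arg(dialect)
  a1 <- x@allele1; a2 <- x@allele2
  if (dialect == "csv") {
    g <- matrix(0L, nrow(a1), 2L * ncol(a1))
    g[, seq(1L, ncol(g), 2L)] <- ifelse(is.na(a1), 0L, a1)
    g[, seq(2L, ncol(g), 2L)] <- ifelse(is.na(a2), 0L, a2)
    colnames(g) <- as.vector(rbind(paste0(x@loci, ".1"), paste0(x@loci, ".2")))
    out <- cbind(x@info, as.data.frame(g))
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  } else {
    digits <- if (max(c(a1, a2), na.rm = TRUE) > 99L) 3L else 2L
    fmt <- function(m) {
      v <- formatC(ifelse(is.na(m), 0L, m), width = digits, flag = "0")
      matrix(v, nrow(m), ncol(m))
    }
    s1 <- fmt(a1); s2 <- fmt(a2)
    geno <- matrix(paste0(s1, s2), nrow(a1), ncol(a1))
    rows <- paste0(x@info$id, " , ", apply(geno, 1L, paste, collapse = " "))
    writeLines(c("palmflow export", x@loci, "POP", rows), path)
    utils::write.csv(x@info, coordsPath, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Per-locus allele frequencies
#'
#' Relative allele frequencies per locus from non-missing calls, optionally
#' restricted to a subset of ontogenetic stages. Loci entirely missing in the
#' subset are dropped with a warning.
#'
#' @param x a [GenotypeDataset-class].
#' @param stage optional character vector of stage labels; `NULL` = all.
#' @return An [AlleleFrequencyTable-class].
#' @export
alleleFrequencies <- function(x, stage = NULL) {
  if (!is.null(stage)) x <- subsetStage(x, stage)
  freqs <- vector("list", length(x@loci))
  names(freqs) <- x@loci
  gc <- ss <- integer(length(x@loci))
  names(gc) <- names(ss) <- x@loci
  drop <- character()
  for (l in seq_along(x@loci)) {
    ok <- !is.na(x@allele1[, l])
    if (!any(ok)) { drop <- c(drop, x@loci[l]); next }
    copies <- c(x@allele1[ok, l], x@allele2[ok, l])
    tab <- table(copies)
    freqs[[l]] <- as.numeric(tab) / length(copies)
    names(freqs[[l]]) <- names(tab)
    gc[l] <- length(copies)
    ss[l] <- sum(ok)
  }
  if (length(drop)) {
    warning("dropping loci with no data in subset: ",
            paste(drop, collapse = ", "))
    keep <- setdiff(x@loci, drop)
    freqs <- freqs[keep]; gc <- gc[keep]; ss <- ss[keep]
  }
  new("AlleleFrequencyTable", freqs = freqs, geneCounts = gc,
      sampleSizes = ss)
}

#' Pairwise Euclidean distances between mapped individuals
#'
#' @param x a [GenotypeDataset-class].
#' @return A symmetric `n x n` matrix of distances in meters (zero diagonal),
#'   row/col names are ids.
#' @export
pairwiseDistances <- function(x) {
  d <- as.matrix(stats::dist(coords(x)))
  dimnames(d) <- list(x@info$id, x@info$id)
  d
}

#' Project lon/lat GPS coordinates to local planar meters
#'
#' Local equirectangular projection about the centroid; adequate for plots of
#' a few tens of hectares where projection error is negligible.
#'
#' @param lon,lat numeric vectors of degrees.
#' @return A two-column matrix `x`, `y` in meters, origin at the centroid.
#' @export
projectLonLat <- function(lon, lat) {
  R <- 6371008.8
  lat0 <- mean(lat) * pi / 180
  x <- (lon - mean(lon)) * pi / 180 * R * cos(lat0)
  y <- (lat - mean(lat)) * pi / 180 * R
  cbind(x = x, y = y)
}
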
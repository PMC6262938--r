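#' Group coancestry and status effective population size
#'
#' Group coancestry of a sample of `n` individuals,
#' \deqn{\Theta = \frac{0.5\,n\,(1+F) + \sum_i \sum_{j \ne i} \theta_{ij}}{n^2}}
#' where the double sum runs over ordered pairs (each unordered pair counted
#' twice), `F` is the group's inbreeding coefficient (negative values floored
#' at zero), and \eqn{\theta_{ij}} the pairwise coancestry. With all
#' \eqn{\theta_{ij} = 0} and `F = 0` this reduces to \eqn{\Theta = 1/(2n)}.
#' The status effective size follows as \eqn{N_e = 0.5/\Theta}.
#'
#' @param coan a [CoancestryMatrix-class] for the group (used for the pairwise
#'   sum and, by default, `n`), or `NULL` if `theta` is supplied directly.
#' @param F inbreeding coefficient (fixation index) of the group; negative
#'   values are treated as zero.
#' @param n sample size (default: taken from `coan`).
#' @param theta optionally, a precomputed group coancestry \eqn{\Theta}; when
#'   given, `coan` and `F` are ignored and only `Ne` is derived.
#' @return list with `theta`, `Fused`, `n`, `Ne`, `ratio` (= `Ne/n`). If
#'   `theta <= 0`, `Ne` is `NA` with a warning.
#' @export
groupCoancestry <- function(coan = NULL, F = 0, n = NULL, theta = NULL) {
  if (is.null(theta)) {
    stopifnot(is(coan, "CoancestryMatrix"))
    if (is.null(n)) n <- nrow(coan@theta)
    Fused <- max(F, 0)
    th <- coan@theta
    diag(th) <- 0
    theta <- (0.5 * n * (1 + Fused) + sum(th, na.rm = TRUE)) / n^2
  } else {
    Fused <- max(F, 0)
    if (is.null(n)) n <- NA_integer_
  }
  if (theta <= 0) {
    warning("group coancestry <= 0; Ne undefined")
    Ne <- NA_real_
  } else Ne <- 0.5 / theta
  list(theta = theta, Fused = Fused, n = n, Ne = Ne, ratio = Ne / n)
}

#' Effective size from a group coancestry value
#'
#' \eqn{N_e = 0.5/\Theta}.
#'
#' @param theta group coancestry, in (0, 1].
#' @return Ne (numeric scalar).
#' @export
effectiveSize <- function(theta) {
  stopifnot(is.finite(theta), theta > 0)
  0.5 / theta
}
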
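#' Exponential-power dispersal density
#'
#' Isotropic two-dimensional dispersal density per unit area at distance `r`
#' from the source:
#' \deqn{p(r) = \frac{b}{2 \pi a^2 \Gamma(2/b)} \exp\{-(r/a)^b\}}
#' which integrates to 1 over the plane. `b = 2` is the Gaussian kernel,
#' `b = 1` exponential, `b < 1` fat-tailed.
#'
#' @param r nonnegative distance(s), meters.
#' @param params a [KernelParams-class].
#' @return density per square meter at each `r`.
#' @export
expPowerPdf <- function(r, params) {
  stopifnot(all(r >= 0))
  a <- params@a; b <- params@b
  b / (2 * pi * a^2 * gamma(2 / b)) * exp(-(r / a)^b)
}

#' Mean dispersal distance of an exponential-power kernel
#'
#' \deqn{\delta = a \, \Gamma(3/b) / \Gamma(2/b)}
#'
#' @param params a [KernelParams-class].
#' @return mean dispersal distance, meters.
#' @export
kernelMeanDistance <- function(params) {
  params@a * gamma(3 / params@b) / gamma(2 / params@b)
}

#' Draw dispersal vectors from an exponential-power kernel
#'
#' Distances follow the radial density \eqn{2\pi r\, p(r)}; writing
#' \eqn{u = (r/a)^b}, `u` is Gamma(2/b, 1) distributed, so draws are
#' `a * rgamma(n, 2/b)^(1/b)` with a uniform direction.
#'
#' @param n number of draws.
#' @param params a [KernelParams-class].
#' @return matrix with columns `dx`, `dy`, `r`.
#' @export
sampleKernel <- function(n, params) {
  r <- params@a * stats::rgamma(n, shape = 2 / params@b)^(1 / params@b)
  ang <- stats::runif(n, 0, 2 * pi)
  cbind(dx = r * cos(ang), dy = r * sin(ang), r = r)
}
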
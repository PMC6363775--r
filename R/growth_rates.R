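#' Expected producer fraction in a focal cell's neighborhood
#'
#' A focal cell shares the public good with \code{n - 1} neighbors drawn
#' from a large well-mixed population with cooperator fraction \code{y}.
#' The expected fraction of producers among the \code{n} cells supplying
#' the good is
#' \deqn{N_C = [1 + (n-1)y]/n} for a focal cooperator (which counts its own
#' contribution) and \deqn{N_D = (n-1)y/n} for a focal defector. The
#' self-benefit gap \eqn{N_C - N_D = 1/n} is what lets producers outgrow
#' free-riders in small neighborhoods.
#'
#' @param y cooperator fraction, in \[0, 1\] (vectorized).
#' @param n neighborhood size, >= 1 (real values allowed).
#' @param focal focal strategy, \code{"C"} or \code{"D"}.
#' @return Expected producer fraction in \[0, 1\], same length as \code{y}.
#' @examples
#' expected_producers(0, 5, "C")   # lone producer's self-benefit: 1/5
#' expected_producers(0, 5, "D")   # a defector sees no producers: 0
#' expected_producers(1, 17, "C")  # all-producer neighborhood: 1
#' @export
expected_producers <- function(y, n, focal = c("C", "D")) {
  focal <- match.arg(focal)
  if (any(y < 0 | y > 1, na.rm = FALSE) || anyNA(y))
    stop("y must lie in [0, 1]")
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 1)
    stop("n must be a single number >= 1")
  if (focal == "C") (1 + (n - 1) * y) / n else (n - 1) * y / n
}

# sigmoidal benefit factor (1+e^sigma)/(1+e^(sigma - beta*N)); equals 1 at
# N = 0 and increases to (1+e^sigma)/(1+e^(sigma-beta)) at N = 1
sigmoid_benefit <- function(N, beta, sigma) {
  (1 + exp(sigma)) / (1 + exp(sigma - beta * N))
}

#' Frequency-dependent intrinsic growth rates
#'
#' Intrinsic (density-independent) per-capita growth rates of cooperators
#' and defectors at cooperator fraction \code{y}:
#' \deqn{r_C(y) = \alpha_C \frac{1+e^\sigma}{1+e^{\sigma-\beta N_C}} - \kappa,
#'       \quad
#'       r_D(y) = \alpha_D \frac{1+e^\sigma}{1+e^{\sigma-\beta N_D}},}
#' with \eqn{N_C} and \eqn{N_D} the expected producer fractions from
#' [expected_producers()], evaluated at the type's own neighborhood size
#' (\code{n_C} for cooperators, \code{n_D} for defectors). With
#' \eqn{\beta = 0} the benefit factor is 1 and the rates reduce to
#' \eqn{r_C = \alpha_C - \kappa}, \eqn{r_D = \alpha_D}. Rates may be
#' negative when the cost exceeds the benefit; they are only clamped where
#' they become jump-process propensities.
#'
#' @param y cooperator fraction, in \[0, 1\] (vectorized).
#' @param params a [pgg_params()] object.
#' @param focal \code{"C"}, \code{"D"}, or \code{"both"} (default), in
#'   which case a list with components \code{r_C} and \code{r_D} is
#'   returned.
#' @return Numeric vector of rates (per day), or a list of two for
#'   \code{focal = "both"}.
#' @examples
#' p <- pgg_params(kappa = 0.5, beta = 5, sigma = 2, n = 5)
#' growth_rates(0, p)      # lone-cooperator self-benefit vs. bare alpha_D
#' growth_rates(0.5, p, "C")
#' @export
growth_rates <- function(y, params, focal = c("both", "C", "D")) {
  stopifnot(inherits(params, "pgg_params"))
  focal <- match.arg(focal)
  rC <- function() {
    N <- expected_producers(y, params$n_C, "C")
    params$alpha_C * sigmoid_benefit(N, params$beta, params$sigma) -
      params$kappa
  }
  rD <- function() {
    N <- expected_producers(y, params$n_D, "D")
    params$alpha_D * sigmoid_benefit(N, params$beta, params$sigma)
  }
  switch(focal,
         C = rC(), D = rD(),
         both = list(r_C = rC(), r_D = rD()))
}

#' Growth-rate difference between cooperators and defectors
#'
#' \eqn{r_C(y) - r_D(y)}: the selection gradient driving the cooperator
#' fraction in the equal-death-rate case. For \eqn{\beta = 0} it is
#' constantly \eqn{-\kappa}; for \eqn{\beta > \sigma} parameter sets it
#' can be non-monotonic with an interior maximum, which is what permits
#' two interior equilibria.
#'
#' @inheritParams growth_rates
#' @return Numeric vector, \code{r_C(y) - r_D(y)} (per day).
#' @examples
#' p <- pgg_params(alpha_C = 1, alpha_D = 1, kappa = 0.25,
#'                 beta = 3.67, sigma = 1.87, n = 22)
#' growth_rate_difference(c(0.1, 0.5, 0.9), p)
#' @export
growth_rate_difference <- function(y, params) {
  r <- growth_rates(y, params, "both")
  r$r_C - r$r_D
}

#' Inflection point of the sigmoidal benefit
#'
#' Location \eqn{\sigma/\beta} (on the producer-fraction scale \eqn{N}) at
#' which the marginal benefit of adding producers is maximal: below it,
#' additional cooperators create synergy; above it, diminishing returns.
#'
#' @param params a [pgg_params()] object with \code{beta > 0}.
#' @return \code{sigma / beta}.
#' @examples
#' inflection_point(pgg_params(beta = 4, sigma = 2))  # 0.5
#' @export
inflection_point <- function(params) {
  stopifnot(inherits(params, "pgg_params"))
  if (params$beta <= 0)
    stop("inflection point is undefined for beta = 0 (no frequency dependence)")
  params$sigma / params$beta
}
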
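#' Model parameters for the nonlinear public goods game
#'
#' Bundles all rates and game parameters of the eco-evolutionary model:
#' baseline birth rates, death rates, the cost of public-good production,
#' the carrying capacity, the two benefit parameters of the sigmoidal
#' frequency-dependent growth rates, and the interaction neighborhood
#' size(s).
#'
#' The benefit of the public good is a sigmoid in the expected producer
#' fraction \eqn{N} seen by a focal cell: \eqn{(1+e^\sigma)/(1+e^{\sigma -
#' \beta N})}. \code{beta} sets the strength of the frequency-dependent
#' effect, \code{sigma} a frequency-independent background; the inflection
#' of the benefit sits at \eqn{N = \sigma/\beta}. Producers pay a flat cost
#' \code{kappa} on their intrinsic growth rate.
#'
#' @param alpha_C,alpha_D baseline birth rates (per day), both > 0.
#' @param delta_C,delta_D death rates (per day), both >= 0.
#' @param kappa cost of public-good production (per day), >= 0.
#' @param K carrying capacity (cells), > 0. \code{Inf} is allowed and turns
#'   the density factor off.
#' @param beta frequency-dependent benefit strength (dimensionless), >= 0.
#' @param sigma frequency-independent background parameter (dimensionless),
#'   >= 0.
#' @param n neighborhood size shared by both types (cells, >= 1). Sets both
#'   \code{n_C} and \code{n_D}; ignored when those are given explicitly.
#'   Non-integer values are allowed (the compartment model produces real
#'   effective neighborhood sizes).
#' @param n_C,n_D type-specific neighborhood sizes; default to \code{n}.
#'
#' @return An object of class \code{"pgg_params"}: a named list of the
#'   validated parameters.
#'
#' @examples
#' p <- pgg_params(alpha_C = 1, alpha_D = 1, delta_C = 0.05, delta_D = 0.05,
#'                 kappa = 0.1, K = 100, beta = 4, sigma = 0.5, n = 10)
#' p
#' growth_rates(0.5, p)
#' @seealso [growth_rates()], [read_params()], [interior_equilibria()]
#' @export
pgg_params <- function(alpha_C = 1, alpha_D = 1,
                       delta_C = 0.1, delta_D = 0.1,
                       kappa = 0.5, K = 1000,
                       beta = 0, sigma = 0,
                       n = 10, n_C = n, n_D = n) {
  p <- list(alpha_C = alpha_C, alpha_D = alpha_D,
            delta_C = delta_C, delta_D = delta_D,
            kappa = kappa, K = K, beta = beta, sigma = sigma,
            n_C = n_C, n_D = n_D)
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v))
      stop("parameter '", nm, "' must be a single non-missing number")
  }
  if (p$alpha_C <= 0 || p$alpha_D <= 0)
    stop("baseline birth rates alpha_C, alpha_D must be positive")
  if (p$delta_C < 0 || p$delta_D < 0) stop("death rates must be nonnegative")
  if (p$kappa < 0) stop("kappa must be nonnegative")
  if (p$K <= 0) stop("K must be positive")
  if (p$beta < 0 || p$sigma < 0) stop("beta and sigma must be nonnegative")
  if (p$n_C < 1 || p$n_D < 1) stop("neighborhood sizes must be >= 1")
  structure(p, class = "pgg_params")
}

#' @export
print.pgg_params <- function(x, ...) {
  cat("Nonlinear public goods game parameters\n")
  cat(sprintf("  birth rates   alpha_C = %g, alpha_D = %g (per day)\n",
              x$alpha_C, x$alpha_D))
  cat(sprintf("  death rates   delta_C = %g, delta_D = %g (per day)\n",
              x$delta_C, x$delta_D))
  cat(sprintf("  cost          kappa   = %g (per day)\n", x$kappa))
  cat(sprintf("  capacity      K       = %g cells\n", x$K))
  cat(sprintf("  benefit       beta    = %g, sigma = %g", x$beta, x$sigma))
  if (x$beta > 0)
    cat(sprintf("  (inflection at N = %.4g)", x$sigma / x$beta))
  cat("\n")
  if (x$n_C == x$n_D) {
    cat(sprintf("  neighborhood  n = %g cells\n", x$n_C))
  } else {
    cat(sprintf("  neighborhood  n_C = %g, n_D = %g cells\n", x$n_C, x$n_D))
  }
  invisible(x)
}

#' Modify a parameter set
#'
#' Returns a copy of \code{params} with the named fields replaced and the
#' result revalidated. \code{n} sets both \code{n_C} and \code{n_D}.
#'
#' @param params a [pgg_params()] object.
#' @param ... named parameter replacements.
#' @return A new \code{pgg_params} object.
#' @examples
#' p <- pgg_params(beta = 5, sigma = 2)
#' update_params(p, n = 22, kappa = 0.25)
#' @export
update_params <- function(params, ...) {
  stopifnot(inherits(params, "pgg_params"))
  repl <- list(...)
  if ("n" %in% names(repl)) {
    params$n_C <- params$n_D <- repl$n
    repl$n <- NULL
  }
  bad <- setdiff(names(repl), names(params))
  if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
  params[names(repl)] <- repl
  do.call(pgg_params, unclass(params))
}

#' Read and write parameter configuration files
#'
#' Parameter sets round-trip through flat key--value YAML or JSON blocks
#' with keys \code{alpha_C, alpha_D, delta_C, delta_D, kappa, K, beta,
#' sigma} and either \code{n} (sets both neighborhoods) or \code{n_C} /
#' \code{n_D}.
#'
#' @param path file path; format is chosen by extension (\code{.json} for
#'   JSON, anything else is parsed as YAML).
#' @return \code{read_params} returns a \code{pgg_params} object;
#'   \code{write_params} returns \code{path} invisibly.
#' @examples
#' f <- tempfile(fileext = ".yaml")
#' write_params(pgg_params(beta = 2, sigma = 3), f)
#' read_params(f)
#' @export
read_params <- function(path) {
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  do.call(pgg_params, lapply(vals, as.numeric))
}

#' @rdname read_params
#' @param params a [pgg_params()] object to serialize.
#' @export
write_params <- function(params, path) {
  stopifnot(inherits(params, "pgg_params"))
  vals <- unclass(params)
  if (vals$n_C == vals$n_D) {
    vals$n <- vals$n_C
    vals$n_C <- vals$n_D <- NULL
  }
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(vals, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(vals, path)
  }
  invisible(path)
}
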
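#' Predicted frequency change for a candidate parameter pair
#'
#' Model surface used by the likelihood: the change in cooperator
#' fraction over one assay, \eqn{\Delta y = y(T) - y_0}, from the reduced
#' frequency equation at candidate benefit parameters \code{(beta,
#' sigma)} and neighborhood size \code{n}, with all remaining parameters
#' fixed.
#'
#' @param beta,sigma candidate benefit parameters (>= 0).
#' @param n neighborhood size used for both types.
#' @param y0 initial cooperator fraction(s), vectorized.
#' @param duration assay duration (days).
#' @param fixed list of fixed parameters: \code{alpha} (baseline rate,
#'   both types), \code{kappa}, \code{delta_C}, \code{delta_D},
#'   \code{density_mode} (\code{"exponential_regime"} or
#'   \code{"full_logistic"}), and for the latter \code{Y0} and \code{K}.
#' @return Predicted \eqn{\Delta y}, same length as \code{y0}.
#' @examples
#' predict_delta_y(3.67, 1.87, n = 22, y0 = c(0.1, 0.5, 0.784),
#'                 duration = 4)
#' @export
predict_delta_y <- function(beta, sigma, n, y0, duration = 4,
                            fixed = list()) {
  fx <- fit_fixed_defaults(fixed)
  params <- pgg_params(alpha_C = fx$alpha, alpha_D = fx$alpha,
                       delta_C = fx$delta_C, delta_D = fx$delta_D,
                       kappa = fx$kappa, K = fx$K, beta = beta,
                       sigma = sigma, n = n)
  frequency_change(params, y0, duration, density_mode = fx$density_mode,
                   Y0 = fx$Y0)
}

fit_fixed_defaults <- function(fixed) {
  defaults <- list(alpha = 1, kappa = 0.25, delta_C = 0.1, delta_D = 0.1,
                   density_mode = "exponential_regime", K = Inf, Y0 = NULL)
  bad <- setdiff(names(fixed), names(defaults))
  if (length(bad)) stop("unknown fixed parameter(s): ",
                        paste(bad, collapse = ", "))
  defaults[names(fixed)] <- fixed
  if (defaults$density_mode == "full_logistic" && is.null(defaults$Y0))
    stop("full_logistic density mode requires fixed$Y0")
  defaults
}

#' Maximum-likelihood fit of the benefit parameters
#'
#' Estimates \code{(beta, sigma)} from a frequency-change experiment by
#' maximizing the likelihood of the observed \eqn{\Delta y} under
#' independent Gaussian observation noise with a common unknown scale.
#' Profiling out the noise variance makes this equivalent to least
#' squares on the model surface [predict_delta_y()]; the reported
#' negative log-likelihood and noise scale use the profiled MLE
#' \eqn{\hat s^2 = \mathrm{RSS}/m}. Optimization is multi-start: the RSS
#' is evaluated on a coarse grid over the search box, the best starts are
#' refined with bounded quasi-Newton (L-BFGS-B), and the best refined
#' optimum is returned. Estimates landing on a search bound are flagged
#' in \code{boundary}.
#'
#' @param data a data frame with columns \code{y0} and \code{delta_y}
#'   (and optionally \code{duration_days}, which must then be constant),
#'   e.g. one condition slice of [read_frequency_data()] or
#'   [simulate_frequency_change()] output. At least 3 distinct \code{y0}
#'   values are required.
#' @param n neighborhood size at which to fit.
#' @param fixed fixed-parameter list, see [predict_delta_y()]. Defaults:
#'   \eqn{\alpha = 1}/day, \eqn{\kappa = 0.25}, equal deaths, density
#'   factor off.
#' @param duration assay duration (days) if not a data column.
#' @param bounds list with \code{beta} and \code{sigma} ranges (defaults
#'   \eqn{\beta \in [0, 20]}, \eqn{\sigma \in [0, 10]}).
#' @param n_starts starts per axis of the coarse grid (default 8, i.e. an
#'   8 x 8 grid); the best 5 grid points are refined.
#' @return An object of class \code{"pgg_fit"} with components
#'   \code{coefficients} (named \code{beta}, \code{sigma}), \code{nll},
#'   \code{sigma_noise}, \code{n}, \code{fixed}, \code{duration},
#'   \code{data}, \code{fitted}, \code{residuals}, \code{boundary},
#'   \code{convergence} (per-start log), \code{bounds}.
#' @examples
#' d <- simulate_frequency_change(freq_change_design(noise_sd = 0), seed = 1)
#' fit <- pgg_fit(d, n = 22)
#' coef(fit)
#' @seealso [fit_across_n()], [equilibria_from_fit()]
#' @export
pgg_fit <- function(data, n, fixed = list(), duration = NULL,
                    bounds = list(beta = c(0, 20), sigma = c(0, 10)),
                    n_starts = 8) {
  if (!all(c("y0", "delta_y") %in% names(data)))
    stop("data needs columns y0 and delta_y")
  y0 <- data$y0; dy <- data$delta_y
  if (any(y0 < 0 | y0 > 1) || any(y0 + dy < -1e-9 | y0 + dy > 1 + 1e-9))
    stop("y0 and y0 + delta_y must lie in [0, 1]")
  if (length(unique(y0)) < 3)
    stop("at least 3 distinct y0 values are needed to identify (beta, sigma)")
  if (is.null(duration)) {
    if ("duration_days" %in% names(data)) {
      duration <- unique(data$duration_days)
      if (length(duration) != 1)
        stop("duration_days must be constant within one fit")
    } else duration <- 4
  }
  if (stats::var(dy) == 0 && length(unique(y0)) == 1)
    stop("degenerate data: constant delta_y at a single y0")
  fx <- fit_fixed_defaults(fixed)
  m <- length(dy)
  uy <- unique(y0); iy <- match(y0, uy)  # predict once per design point
  rss <- function(th) {
    th <- pmax(th, 0)  # finite-difference gradient probes can dip below 0
    pred <- predict_delta_y(th[1], th[2], n, uy, duration, fx)[iy]
    sum((dy - pred)^2)
  }
  bgrid <- seq(bounds$beta[1], bounds$beta[2], length.out = n_starts)
  sgrid <- seq(bounds$sigma[1], bounds$sigma[2], length.out = n_starts)
  starts <- expand.grid(beta = bgrid, sigma = sgrid)
  starts$rss <- apply(starts, 1, rss)
  starts <- starts[order(starts$rss), ]
  log <- list(); best <- NULL
  for (i in seq_len(min(5L, nrow(starts)))) {
    opt <- stats::optim(c(starts$beta[i], starts$sigma[i]), rss,
                        method = "L-BFGS-B",
                        lower = c(bounds$beta[1], bounds$sigma[1]),
                        upper = c(bounds$beta[2], bounds$sigma[2]),
                        control = list(factr = 1e7))
    log[[i]] <- data.frame(start_beta = starts$beta[i],
                           start_sigma = starts$sigma[i],
                           beta = opt$par[1], sigma = opt$par[2],
                           rss = opt$value, converged = opt$convergence == 0)
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  log <- do.call(rbind, log)
  if (!any(log$converged))
    stop("optimizer failed to converge from every start; per-start log:\n",
         paste(utils::capture.output(print(log)), collapse = "\n"))
  th <- best$par
  tol <- 1e-6 * c(diff(bounds$beta), diff(bounds$sigma))
  boundary <- c(beta = th[1] <= bounds$beta[1] + tol[1] ||
                  th[1] >= bounds$beta[2] - tol[1],
                sigma = th[2] <= bounds$sigma[1] + tol[2] ||
                  th[2] >= bounds$sigma[2] - tol[2])
  s2 <- best$value / m
  nll <- m / 2 * (log(2 * pi * max(s2, .Machine$double.eps)) + 1)
  fitted <- predict_delta_y(th[1], th[2], n, y0, duration, fx)
  structure(list(coefficients = c(beta = th[1], sigma = th[2]),
                 nll = nll, rss = best$value,
                 sigma_noise = sqrt(s2), n = n, fixed = fx,
                 duration = duration, data = data, fitted = fitted,
                 residuals = dy - fitted, boundary = boundary,
                 convergence = log, bounds = bounds),
            class = "pgg_fit")
}

#' @export
print.pgg_fit <- function(x, ...) {
  cat(sprintf("Sigmoidal public-goods benefit fit (n = %g, %d observations)\n",
              x$n, length(x$residuals)))
  cat(sprintf("  beta  = %.4f%s\n", x$coefficients[["beta"]],
              if (x$boundary[["beta"]]) "  [at search bound]" else ""))
  cat(sprintf("  sigma = %.4f%s\n", x$coefficients[["sigma"]],
              if (x$boundary[["sigma"]]) "  [at search bound]" else ""))
  cat(sprintf("  residual noise scale %.4g, NLL %.4g\n",
              x$sigma_noise, x$nll))
  invisible(x)
}

#' @export
coef.pgg_fit <- function(object, ...) object$coefficients

#' @export
residuals.pgg_fit <- function(object, ...) object$residuals

#' @export
summary.pgg_fit <- function(object, ...) {
  cf <- object$coefficients
  eq <- equilibria_from_fit(cf[["beta"]], cf[["sigma"]], n_ref = object$n,
                            fixed = object$fixed)
  structure(list(fit = object, equilibria = eq), class = "summary.pgg_fit")
}

#' @export
print.summary.pgg_fit <- function(x, ...) {
  print(x$fit)
  cat("Implied interior equilibria at the fitted parameters:\n")
  if (nrow(x$equilibria) == 0) cat("  none\n") else
    print.data.frame(x$equilibria[c("y_star", "stability")],
                     row.names = FALSE)
  invisible(x)
}

#' @export
predict.pgg_fit <- function(object, newdata = NULL, ...) {
  y0 <- if (is.null(newdata)) object$data$y0 else newdata$y0
  cf <- object$coefficients
  predict_delta_y(cf[["beta"]], cf[["sigma"]], object$n, y0,
                  object$duration, object$fixed)
}

#' Simulate replicate datasets from a fitted model
#'
#' Draws new observations \eqn{\Delta y = \hat{\Delta y}(y_0) +
#' \varepsilon} with \eqn{\varepsilon \sim N(0, \hat s^2)} at the fitted
#' parameters, at the original design points.
#'
#' @param object a [pgg_fit()] result.
#' @param nsim number of simulated datasets.
#' @param seed optional seed.
#' @param ... unused.
#' @return A data frame with \code{nsim} columns of simulated
#'   \code{delta_y}, rows aligned with \code{object$data}.
#' @export
simulate.pgg_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  mu <- object$fitted
  out <- as.data.frame(replicate(
    nsim, mu + stats::rnorm(length(mu), 0, object$sigma_noise)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' @export
plot.pgg_fit <- function(x, ...) {
  ord <- order(x$data$y0)
  graphics::plot(x$data$y0, x$data$delta_y, xlab = "initial cooperator fraction",
                 ylab = expression(Delta * y), ...)
  yy <- seq(0.001, 0.999, length.out = 200)
  graphics::lines(yy, predict(x, newdata = data.frame(y0 = yy)),
                  col = "steelblue")
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}

#' Fit across a range of neighborhood sizes
#'
#' The interaction range of a diffusible good is rarely known, so the fit
#' is repeated for every \code{n} in a plausible range (default 4--40
#' cells, mean 22) and the per-condition medians of the estimates are
#' reported with interquartile ranges. Failures at individual \code{n}
#' are recorded and excluded from the aggregates.
#'
#' @param data frequency-change table with columns \code{y0},
#'   \code{delta_y}, optionally \code{condition} (fit per condition) and
#'   \code{duration_days}.
#' @param n_values neighborhood sizes to fit at (default \code{4:40}).
#' @param fixed,bounds,duration passed to [pgg_fit()].
#' @return An object of class \code{"pgg_fit_profile"}: list with
#'   \code{fits} (long data frame: condition, n, beta_hat, sigma_hat,
#'   nll, boundary flags, converged), \code{medians} (per condition:
#'   median and IQR of both estimates, number of failures), and the call
#'   settings.
#' @examples
#' d <- simulate_frequency_change(freq_change_design(noise_sd = 0), seed = 1)
#' pr <- fit_across_n(d, n_values = c(11, 22, 33))
#' pr$medians
#' @export
fit_across_n <- function(data, n_values = 4:40, fixed = list(),
                         bounds = list(beta = c(0, 20), sigma = c(0, 10)),
                         duration = NULL) {
  if (!length(n_values)) stop("n_values must be nonempty")
  conds <- if ("condition" %in% names(data)) unique(data$condition)
           else "all"
  rows <- list()
  for (cond in conds) {
    slice <- if ("condition" %in% names(data))
      data[data$condition == cond, ] else data
    for (n in n_values) {
      f <- tryCatch(pgg_fit(slice, n, fixed, duration, bounds),
                    error = function(e) e)
      rows[[length(rows) + 1L]] <- if (inherits(f, "error")) {
        data.frame(condition = cond, n = n, beta_hat = NA_real_,
                   sigma_hat = NA_real_, nll = NA_real_,
                   beta_at_bound = NA, sigma_at_bound = NA,
                   converged = FALSE, error = conditionMessage(f))
      } else {
        data.frame(condition = cond, n = n,
                   beta_hat = f$coefficients[["beta"]],
                   sigma_hat = f$coefficients[["sigma"]], nll = f$nll,
                   beta_at_bound = f$boundary[["beta"]],
                   sigma_at_bound = f$boundary[["sigma"]],
                   converged = TRUE, error = "")
      }
    }
  }
  fits <- do.call(rbind, rows)
  med <- do.call(rbind, lapply(conds, function(cond) {
    ok <- fits$condition == cond & fits$converged
    data.frame(condition = cond,
               beta_median = stats::median(fits$beta_hat[ok]),
               beta_iqr = stats::IQR(fits$beta_hat[ok]),
               sigma_median = stats::median(fits$sigma_hat[ok]),
               sigma_iqr = stats::IQR(fits$sigma_hat[ok]),
               n_fitted = sum(ok),
               n_failed = sum(fits$condition == cond & !fits$converged))
  }))
  structure(list(fits = fits, medians = med, n_values = n_values,
                 fixed = fit_fixed_defaults(fixed), bounds = bounds),
            class = "pgg_fit_profile")
}

#' @export
print.pgg_fit_profile <- function(x, ...) {
  cat(sprintf("Benefit-parameter fits across %d neighborhood sizes (n in [%g, %g], mean %.3g)\n",
              length(x$n_values), min(x$n_values), max(x$n_values),
              mean(x$n_values)))
  print(x$medians, row.names = FALSE)
  invisible(x)
}

#' Write fit results to JSON and long-format CSV
#'
#' @param profile a [fit_across_n()] result.
#' @param csv_path long-format CSV of per-n fits; optional.
#' @param json_path JSON report (per-n fits plus medians); optional.
#' @return \code{profile}, invisibly.
#' @export
write_fit_report <- function(profile, csv_path = NULL, json_path = NULL) {
  stopifnot(inherits(profile, "pgg_fit_profile"))
  if (!is.null(csv_path))
    utils::write.csv(profile$fits, csv_path, row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(list(fits = profile$fits,
                              medians = profile$medians,
                              fixed = profile$fixed),
                         json_path, auto_unbox = TRUE, digits = NA,
                         dataframe = "columns")
  invisible(profile)
}

#' Interior equilibria implied by fitted benefit parameters
#'
#' Convenience bridge from estimates (e.g. per-condition medians) to the
#' equilibrium structure: evaluates [interior_equilibria()] at the given
#' \code{(beta, sigma)}, a reference neighborhood size, and the fit's
#' fixed parameters.
#'
#' @param beta,sigma benefit parameter values (e.g. medians from
#'   [fit_across_n()]).
#' @param n_ref reference neighborhood size (default 22, the mean of the
#'   default 4--40 fitting range).
#' @param fixed fixed-parameter list as in [predict_delta_y()].
#' @return An [interior_equilibria()] data frame.
#' @examples
#' equilibria_from_fit(3.67, 1.87, n_ref = 22)
#' @export
equilibria_from_fit <- function(beta, sigma, n_ref = 22, fixed = list()) {
  fx <- fit_fixed_defaults(fixed)
  params <- pgg_params(alpha_C = fx$alpha, alpha_D = fx$alpha,
                       delta_C = fx$delta_C, delta_D = fx$delta_D,
                       kappa = fx$kappa,
                       K = if (is.finite(fx$K)) fx$K else 1000,
                       beta = beta, sigma = sigma, n = n_ref)
  interior_equilibria(params)
}
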
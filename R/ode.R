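#' Right-hand side of the coupled logistic system
#'
#' Instantaneous rates of change of the cooperator and defector densities
#' \deqn{\dot x_C = r_C(y)\,(1 - Y/K)\,x_C - \delta_C x_C, \qquad
#'       \dot x_D = r_D(y)\,(1 - Y/K)\,x_D - \delta_D x_D,}
#' where \eqn{Y = x_C + x_D}, \eqn{y = x_C/Y}, and the global density
#' factor \eqn{E_K = 1 - Y/K} multiplies the births only. At the empty
#' state both rates are zero; when one type is absent the cooperator
#' fraction takes the boundary convention \eqn{y = 1} (no defectors) or
#' \eqn{y = 0} (no cooperators).
#'
#' @param state numeric vector \code{c(x_C, x_D)}, both >= 0.
#' @param params a [pgg_params()] object.
#' @return Numeric vector \code{c(dx_C, dx_D)} (cells/day).
#' @examples
#' p <- pgg_params(alpha_D = 1, delta_D = 0.1, K = 1000, beta = 0)
#' ode_rhs(c(0, 900), p)  # all-defector logistic fixed point
#' @export
ode_rhs <- function(state, params) {
  stopifnot(inherits(params, "pgg_params"))
  xC <- state[[1]]; xD <- state[[2]]
  Y <- xC + xD
  if (Y <= 0) return(c(0, 0))
  y <- cooperator_fraction(xC, xD)
  r <- growth_rates(y, params, "both")
  EK <- 1 - Y / params$K
  c(r$r_C * EK * xC - params$delta_C * xC,
    r$r_D * EK * xD - params$delta_D * xD)
}

# boundary convention: y = 1 when defectors absent, 0 when cooperators
# absent; callers guarantee Y > 0
cooperator_fraction <- function(xC, xD) {
  Y <- xC + xD
  ifelse(Y > 0, xC / Y, NA_real_)
}

#' Integrate the mean-field dynamics
#'
#' Solves the coupled logistic system (see [ode_rhs()]) with
#' \code{deSolve::ode} (lsoda) and returns the sampled trajectory.
#'
#' @param params a [pgg_params()] object.
#' @param init numeric \code{c(x_C, x_D)}, nonnegative initial densities.
#' @param t_end final time (days), > 0.
#' @param times optional explicit output time grid (days, increasing,
#'   starting at 0); default 201 equally spaced points on \[0, t_end\].
#' @param rtol,atol relative / absolute solver tolerances.
#' @return A \code{pgg_trajectory}: a data frame with columns \code{time},
#'   \code{x_C}, \code{x_D}, \code{y}, \code{Y} and the parameter set in
#'   \code{attr(, "params")}.
#' @examples
#' p <- pgg_params(alpha_D = 1, delta_D = 0.1, delta_C = 0.1, K = 1000)
#' tr <- pgg_ode(p, init = c(0, 10), t_end = 100)
#' tail(tr, 2)  # defectors approach K (1 - delta/alpha) = 900
#' @export
pgg_ode <- function(params, init, t_end = NULL, times = NULL,
                    rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(params, "pgg_params"))
  if (length(init) != 2L || any(init < 0))
    stop("init must be two nonnegative densities c(x_C, x_D)")
  if (is.null(times)) {
    if (is.null(t_end) || t_end <= 0) stop("t_end must be positive")
    times <- seq(0, t_end, length.out = 201L)
  }
  if (is.unsorted(times, strictly = TRUE))
    stop("times must be strictly increasing")
  rhs <- function(t, state, p) list(ode_rhs(pmax(state, 0), p))
  sol <- deSolve::ode(y = c(xC = init[[1]], xD = init[[2]]), times = times,
                      func = rhs, parms = params, method = "lsoda",
                      rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1] < 0)
    stop("ODE integration failed: ", paste(
      utils::capture.output(deSolve::diagnostics(sol)), collapse = "\n"))
  out <- as.data.frame(sol)
  names(out) <- c("time", "x_C", "x_D")
  # lsoda can undershoot zero by ~atol; clip for downstream consumers
  out$x_C <- pmax(out$x_C, 0)
  out$x_D <- pmax(out$x_D, 0)
  out$Y <- out$x_C + out$x_D
  out$y <- ifelse(out$Y > 0, out$x_C / out$Y, NA_real_)
  structure(out[c("time", "x_C", "x_D", "y", "Y")],
            params = params, class = c("pgg_trajectory", "data.frame"))
}

#' @export
print.pgg_trajectory <- function(x, ...) {
  cat(sprintf("Mean-field trajectory: %d time points on [%g, %g] days\n",
              nrow(x), min(x$time), max(x$time)))
  fin <- x[nrow(x), ]
  cat(sprintf("  final state: x_C = %.3f, x_D = %.3f (y = %s)\n",
              fin$x_C, fin$x_D,
              if (is.na(fin$y)) "extinct" else sprintf("%.4f", fin$y)))
  invisible(x)
}

#' @export
plot.pgg_trajectory <- function(x, ...) {
  graphics::matplot(x$time, cbind(x$x_C, x$x_D), type = "l", lty = 1,
                    col = c("forestgreen", "firebrick"),
                    xlab = "time (days)", ylab = "abundance", ...)
  graphics::legend("topright", c("cooperators", "defectors"), lty = 1,
                   col = c("forestgreen", "firebrick"), bty = "n")
  invisible(x)
}

# fixed-step classical RK4, vectorized over parallel initial conditions;
# used for the reduced frequency equation and the compartment selection
# step where the dynamics are smooth and bounded
rk4_integrate <- function(deriv, state, t_len, n_steps) {
  h <- t_len / n_steps
  for (i in seq_len(n_steps)) {
    k1 <- deriv(state)
    k2 <- deriv(state + h / 2 * k1)
    k3 <- deriv(state + h / 2 * k2)
    k4 <- deriv(state + h * k3)
    state <- state + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  state
}

#' Change in cooperator fraction over a fixed interval
#'
#' Integrates the reduced cooperator-fraction equation
#' \deqn{\dot y = y(1-y)\,[E_K\,(r_C(y) - r_D(y)) - (\delta_C - \delta_D)]}
#' obtained from the coupled logistic system by the quotient rule, and
#' returns \eqn{\Delta y = y(\mathrm{duration}) - y_0}. In
#' \code{density_mode = "exponential_regime"} (default, appropriate for
#' short assays far from confluence) the density factor is fixed at
#' \eqn{E_K = 1}; in \code{"full_logistic"} it is coupled with
#' \eqn{\dot Y = Y[E_K(y r_C + (1-y) r_D) - y\delta_C - (1-y)\delta_D]}
#' and an initial total \code{Y0} is required.
#'
#' @param params a [pgg_params()] object.
#' @param y0 initial cooperator fraction(s) in \[0, 1\] (vectorized).
#' @param duration assay duration (days), > 0.
#' @param density_mode \code{"exponential_regime"} or
#'   \code{"full_logistic"}.
#' @param Y0 initial total population (cells), required for
#'   \code{"full_logistic"}.
#' @param n_steps RK4 steps (default resolves the fastest rates at
#'   >= 25 steps/day).
#' @return \eqn{\Delta y}, same length as \code{y0}. Monomorphic states
#'   (\code{y0} of 0 or 1) are absorbing and return 0.
#' @examples
#' p <- pgg_params(alpha_C = 1, alpha_D = 1, delta_C = 0.1, delta_D = 0.1,
#'                 kappa = 0.25, beta = 3.67, sigma = 1.87, n = 22)
#' frequency_change(p, y0 = c(0.1, 0.5, 0.9), duration = 4)
#' @export
frequency_change <- function(params, y0, duration,
                             density_mode = c("exponential_regime",
                                              "full_logistic"),
                             Y0 = NULL, n_steps = NULL) {
  stopifnot(inherits(params, "pgg_params"))
  density_mode <- match.arg(density_mode)
  if (any(y0 < 0 | y0 > 1)) stop("y0 must lie in [0, 1]")
  if (duration <= 0) stop("duration must be positive")
  if (is.null(n_steps)) n_steps <- max(40L, ceiling(duration * 10))
  # inlined rate kernel: this sits in the innermost loop of the ML fit
  aC <- params$alpha_C; aD <- params$alpha_D; kap <- params$kappa
  dC <- params$delta_C; dD <- params$delta_D; dd <- dC - dD
  nC <- params$n_C; nD <- params$n_D
  b <- params$beta; s <- params$sigma; es <- 1 + exp(s)
  rC <- function(y) aC * es / (1 + exp(s - b * (1 + (nC - 1) * y) / nC)) - kap
  rD <- function(y) aD * es / (1 + exp(s - b * (nD - 1) * y / nD))
  if (density_mode == "exponential_regime") {
    deriv <- function(y) {
      y <- pmin.int(pmax.int(y, 0), 1)
      y * (1 - y) * (rC(y) - rD(y) - dd)
    }
    yT <- rk4_integrate(deriv, y0, duration, n_steps)
  } else {
    if (is.null(Y0)) stop("full_logistic mode requires Y0")
    m <- length(y0)
    deriv <- function(state) {
      y <- pmin.int(pmax.int(state[seq_len(m)], 0), 1)
      Y <- pmax.int(state[m + seq_len(m)], 0)
      rc <- rC(y); rd <- rD(y)
      EK <- 1 - Y / params$K
      c(y * (1 - y) * (EK * (rc - rd) - dd),
        Y * (EK * (y * rc + (1 - y) * rd) - y * dC - (1 - y) * dD))
    }
    yT <- rk4_integrate(deriv, c(y0, rep(Y0, m)), duration,
                        n_steps)[seq_along(y0)]
  }
  pmin(pmax(yT, 0), 1) - y0
}

#' Invasion of a resident monomorphic population
#'
#' Initializes the resident type at its single-strategy logistic
#' equilibrium (\eqn{Y = K(1 - \delta/r)} with \eqn{r} the resident's
#' intrinsic rate at its own monomorphic frequency), adds a small inoculum
#' of the other type, integrates the mean-field dynamics, and classifies
#' the outcome.
#'
#' @param params a [pgg_params()] object.
#' @param resident resident strategy, \code{"C"} or \code{"D"}; the other
#'   type invades.
#' @param inoculum invader abundance added at time 0 (default 10 cells).
#' @param t_end integration horizon (days); default \code{500 /
#'   max(alpha)}, long relative to all rates.
#' @return A list of class \code{"pgg_invasion"} with the
#'   \code{trajectory} (a [pgg_ode()] result), the invader's final
#'   frequency, and a \code{verdict}: \code{"invades"} (invader fixes),
#'   \code{"repelled"}, or \code{"coexists"} (interior and settled).
#' @examples
#' p <- pgg_params(delta_C = 0.1, delta_D = 0.1, kappa = 0.5,
#'                 K = 1000, beta = 5, sigma = 2, n_C = 5, n_D = 30)
#' invasion_experiment(p, resident = "D")$verdict
#' @export
invasion_experiment <- function(params, resident = c("D", "C"),
                                inoculum = 10, t_end = NULL) {
  stopifnot(inherits(params, "pgg_params"))
  resident <- match.arg(resident)
  if (is.null(t_end))
    t_end <- 500 / max(params$alpha_C, params$alpha_D)
  if (resident == "D") {
    r_res <- params$alpha_D
    if (r_res <= params$delta_D)
      stop("resident defector population is not viable (alpha_D <= delta_D)")
    Yres <- params$K * (1 - params$delta_D / r_res)
    init <- c(inoculum, Yres)
  } else {
    r_res <- growth_rates(1, params, "C")
    if (r_res <= params$delta_C)
      stop("resident cooperator population is not viable (r_C(1) <= delta_C)")
    Yres <- params$K * (1 - params$delta_C / r_res)
    init <- c(Yres, inoculum)
  }
  tr <- pgg_ode(params, init, t_end = t_end)
  fin <- tr[nrow(tr), ]
  inv_freq <- if (resident == "D") fin$y else 1 - fin$y
  if (is.na(inv_freq)) inv_freq <- 0
  dy <- ode_rhs(c(fin$x_C, fin$x_D), params)
  settled <- fin$Y <= 0 ||
    abs(dy[1] * fin$x_D - dy[2] * fin$x_C) / max(fin$Y^2, 1) < 1e-6
  if (!settled) {  # not yet settled: extend the horizon once
    tr <- pgg_ode(params, c(fin$x_C, fin$x_D), t_end = 4 * t_end)
    fin <- tr[nrow(tr), ]
    inv_freq <- if (resident == "D") fin$y else 1 - fin$y
    if (is.na(inv_freq)) inv_freq <- 0
  }
  verdict <- if (inv_freq > 0.99) "invades"
             else if (inv_freq < 0.01) "repelled"
             else "coexists"
  structure(list(trajectory = tr, invader = setdiff(c("C", "D"), resident),
                 invader_frequency = inv_freq, verdict = verdict),
            class = "pgg_invasion")
}

#' @export
print.pgg_invasion <- function(x, ...) {
  cat(sprintf("Invasion experiment: %s invading -> %s (final invader frequency %.4f)\n",
              x$invader, x$verdict, x$invader_frequency))
  invisible(x)
}

#' Write a trajectory to CSV with a JSON metadata sidecar
#'
#' @param trajectory a \code{pgg_trajectory} (from [pgg_ode()]) or any data
#'   frame with columns \code{time, x_C, x_D, y, Y}.
#' @param path output CSV path; metadata (parameters and any extra fields
#'   passed via \code{...}) goes to \code{<path>.json}.
#' @param ... extra metadata fields (e.g. \code{seed}).
#' @return \code{path}, invisibly.
#' @export
write_trajectory <- function(trajectory, path, ...) {
  utils::write.csv(as.data.frame(trajectory)[c("time", "x_C", "x_D", "y", "Y")],
                   path, row.names = FALSE)
  meta <- c(list(params = unclass(attr(trajectory, "params"))), list(...))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
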
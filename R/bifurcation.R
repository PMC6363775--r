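#' Bifurcation sweep over neighborhood size or benefit strength
#'
#' Recomputes all interior equilibria and the monomorphic stabilities
#' along a sweep of a control parameter (\code{n}, applied to both types,
#' or \code{beta}) and detects bifurcation events between consecutive
#' control values:
#' \itemize{
#'   \item \code{saddle_node}: the interior root count changes by 2 (a
#'     stable and an unstable branch coalesce and annihilate) while the
#'     monomorphic stabilities are unchanged;
#'   \item \code{transcritical}: the root count changes by 1 and a
#'     boundary state's invasibility flips (an interior branch passes
#'     through a monomorphic state, exchanging stability with it).
#' }
#' Critical values are reported as interval midpoints at the sweep's
#' resolution.
#'
#' @param params a [pgg_params()] object (fixed parameters).
#' @param control \code{"n"} or \code{"beta"}.
#' @param values sorted vector of control values.
#' @return An object of class \code{"pgg_bifurcation"}: list with
#'   \code{branches} (data frame: control value, \code{y_star},
#'   \code{stability}, \code{degenerate}), \code{boundaries} (data frame:
#'   control value, invasibility pair and monomorphic stabilities), and
#'   \code{events} (data frame: \code{type}, \code{critical}, interval).
#' @examples
#' p <- pgg_params(delta_C = 0.1, delta_D = 0.1, kappa = 0.5, K = 1000,
#'                 sigma = 2, beta = 5)
#' bf <- bifurcation_sweep(p, "n", seq(4, 40, by = 1))
#' bf$events
#' @export
bifurcation_sweep <- function(params, control = c("n", "beta"), values) {
  stopifnot(inherits(params, "pgg_params"))
  control <- match.arg(control)
  if (is.unsorted(values)) stop("control values must be sorted")
  at <- function(v) {
    if (control == "n") update_params(params, n = v)
    else update_params(params, beta = v)
  }
  branches <- list(); bounds <- list()
  for (v in values) {
    pv <- at(v)
    eq <- interior_equilibria(pv)
    if (nrow(eq))
      branches[[length(branches) + 1L]] <-
        data.frame(control = v, y_star = eq$y_star,
                   stability = eq$stability, degenerate = eq$degenerate)
    bs <- boundary_states(pv)
    bounds[[length(bounds) + 1L]] <- data.frame(
      control = v,
      C_invades_D = attr(bs, "C_invades_D"),
      D_invades_C = attr(bs, "D_invades_C"),
      n_interior = sum(!eq$degenerate))
  }
  branches <- if (length(branches)) do.call(rbind, branches)
              else data.frame(control = numeric(0), y_star = numeric(0),
                              stability = character(0),
                              degenerate = logical(0))
  bounds <- do.call(rbind, bounds)
  events <- list()
  for (k in seq_len(nrow(bounds) - 1L)) {
    a <- bounds[k, ]; b <- bounds[k + 1L, ]
    dcount <- b$n_interior - a$n_interior
    flip <- (a$C_invades_D != b$C_invades_D) ||
            (a$D_invades_C != b$D_invades_C)
    type <- if (abs(dcount) == 2 && !flip) "saddle_node"
            else if (flip) "transcritical"
            else NA_character_
    if (!is.na(type))
      events[[length(events) + 1L]] <- data.frame(
        type = type, critical = (a$control + b$control) / 2,
        lower = a$control, upper = b$control)
  }
  events <- if (length(events)) do.call(rbind, events)
            else data.frame(type = character(0), critical = numeric(0),
                            lower = numeric(0), upper = numeric(0))
  structure(list(control = control, values = values, branches = branches,
                 boundaries = bounds, events = events, params = params),
            class = "pgg_bifurcation")
}

#' @export
print.pgg_bifurcation <- function(x, ...) {
  cat(sprintf("Bifurcation sweep over %s in [%g, %g] (%d values)\n",
              x$control, min(x$values), max(x$values), length(x$values)))
  if (nrow(x$events) == 0) cat("  no bifurcation events detected\n")
  else for (i in seq_len(nrow(x$events)))
    cat(sprintf("  %s near %s = %g (between %g and %g)\n",
                x$events$type[i], x$control, x$events$critical[i],
                x$events$lower[i], x$events$upper[i]))
  invisible(x)
}

#' @export
plot.pgg_bifurcation <- function(x, ...) {
  graphics::plot(x$branches$control, x$branches$y_star, ylim = c(0, 1),
                 pch = ifelse(x$branches$stability == "stable", 19, 1),
                 xlab = x$control, ylab = "equilibrium cooperator fraction",
                 ...)
  invisible(x)
}

#' Deterministic hysteresis sweep
#'
#' Sweeps a control parameter forward and then backward, at each step
#' integrating the mean-field dynamics from the previous step's final
#' state (the attained attractor) topped up with a small perturbation of
#' whichever type has fallen below the perturbation size -- mirroring a
#' rare-migrant seeding. Inside a bistable window the two sweep
#' directions settle on different attractors.
#'
#' @param params a [pgg_params()] object.
#' @param control \code{"n"} or \code{"beta"}.
#' @param values sorted control values; the backward sweep uses
#'   \code{rev(values)}.
#' @param init initial state \code{c(x_C, x_D)} seeding the first forward
#'   step; default: the all-defector logistic equilibrium.
#' @param perturbation abundance floor of the missing type added at each
#'   step (default 1 individual-equivalent; 0 makes monomorphic states
#'   absorbing).
#' @param t_step integration time per control value (days); default
#'   \code{300 / max(alpha)}.
#' @return An object of class \code{"pgg_hysteresis"}: data frame with
#'   columns \code{control}, \code{y_forward}, \code{y_backward}, plus a
#'   \code{window} attribute giving the control range where the branches
#'   disagree by more than 0.05 (or \code{NULL}).
#' @examples
#' p <- pgg_params(delta_C = 0.1, delta_D = 0.1, kappa = 0.5, K = 1000,
#'                 sigma = 3, beta = 2)
#' hysteresis_sweep(p, "n", seq(2, 24, by = 2))
#' @export
hysteresis_sweep <- function(params, control = c("n", "beta"), values,
                             init = NULL, perturbation = 1,
                             t_step = NULL) {
  stopifnot(inherits(params, "pgg_params"))
  control <- match.arg(control)
  if (is.unsorted(values)) stop("control values must be sorted")
  if (is.null(t_step)) t_step <- 300 / max(params$alpha_C, params$alpha_D)
  if (is.null(init)) {
    if (params$alpha_D <= params$delta_D)
      stop("default init needs a viable defector population; supply init")
    init <- c(0, params$K * (1 - params$delta_D / params$alpha_D))
  }
  run_branch <- function(vals) {
    state <- init
    yfin <- numeric(length(vals))
    for (k in seq_along(vals)) {
      pv <- if (control == "n") update_params(params, n = vals[k])
            else update_params(params, beta = vals[k])
      seeded <- pmax(state, 0)
      low <- seeded < perturbation
      seeded[low] <- seeded[low] + perturbation
      tr <- pgg_ode(pv, seeded, t_end = t_step)
      state <- as.numeric(tr[nrow(tr), c("x_C", "x_D")])
      yfin[k] <- if (sum(state) > 0) state[1] / sum(state) else NA_real_
    }
    yfin
  }
  fwd <- run_branch(values)
  bwd <- rev(run_branch(rev(values)))
  out <- data.frame(control = values, y_forward = fwd, y_backward = bwd)
  differ <- which(abs(fwd - bwd) > 0.05)
  window <- if (length(differ)) range(values[differ]) else NULL
  structure(out, window = window, control = control,
            class = c("pgg_hysteresis", "data.frame"))
}

#' @export
print.pgg_hysteresis <- function(x, ...) {
  w <- attr(x, "window")
  cat(sprintf("Hysteresis sweep over %s (%d values): ", attr(x, "control"),
              nrow(x)))
  if (is.null(w)) cat("branches agree everywhere\n")
  else cat(sprintf("branches differ for %s in [%g, %g]\n",
                   attr(x, "control"), w[1], w[2]))
  invisible(x)
}

#' Write a bifurcation diagram to CSV / JSON
#'
#' @param bif a [bifurcation_sweep()] result.
#' @param csv_path long-format CSV of the equilibrium branches; optional.
#' @param json_path structured JSON (branches, boundary stabilities,
#'   events, parameters); optional.
#' @return \code{bif}, invisibly.
#' @export
write_bifurcation_report <- function(bif, csv_path = NULL, json_path = NULL) {
  stopifnot(inherits(bif, "pgg_bifurcation"))
  if (!is.null(csv_path))
    utils::write.csv(bif$branches, csv_path, row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(list(control = bif$control, branches = bif$branches,
                              boundaries = bif$boundaries,
                              events = bif$events,
                              params = unclass(bif$params)),
                         json_path, auto_unbox = TRUE, digits = NA,
                         dataframe = "columns")
  invisible(bif)
}
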
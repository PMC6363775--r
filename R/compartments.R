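#' Create a compartmentalized population state
#'
#' @param counts_C,counts_D integer vectors of per-compartment cooperator
#'   and defector counts (equal length = number of compartments).
#' @return An object of class \code{"pgg_compartments"}.
#' @examples
#' st <- compartment_state(c(10, 0, 5), c(5, 20, 0))
#' st
#' @export
compartment_state <- function(counts_C, counts_D) {
  if (length(counts_C) != length(counts_D))
    stop("counts_C and counts_D must have equal length")
  if (any(counts_C < 0) || any(counts_D < 0))
    stop("counts must be nonnegative")
  structure(list(C = as.numeric(counts_C), D = as.numeric(counts_D),
                 N = length(counts_C)),
            class = "pgg_compartments")
}

#' @export
print.pgg_compartments <- function(x, ...) {
  cat(sprintf("Compartmentalized population: %d compartments, totals C = %g, D = %g\n",
              x$N, sum(x$C), sum(x$D)))
  invisible(x)
}

#' Multinomial remixing of all individuals across compartments
#'
#' Pools every individual and reassigns each one independently to a
#' uniformly random compartment (multinomial sampling), preserving type
#' identity; both type totals are conserved exactly. Compartments may end
#' up empty.
#'
#' @param state a [compartment_state()].
#' @return A new \code{pgg_compartments} with the same totals.
#' @examples
#' set.seed(1)
#' mix_compartments(compartment_state(rep(10, 5), rep(10, 5)))
#' @export
mix_compartments <- function(state) {
  stopifnot(inherits(state, "pgg_compartments"))
  N <- state$N
  prob <- rep(1 / N, N)
  Ctot <- sum(state$C); Dtot <- sum(state$D)
  compartment_state(
    if (Ctot > 0) as.numeric(stats::rmultinom(1, Ctot, prob)) else numeric(N),
    if (Dtot > 0) as.numeric(stats::rmultinom(1, Dtot, prob)) else numeric(N))
}

#' Within-compartment selection step
#'
#' Evolves every compartment for \code{T_s} days under the coupled
#' logistic dynamics with its *local* cooperator fraction \eqn{y_i} and a
#' neighborhood size equal to its current occupancy \eqn{n_i = C_i + D_i}
#' (floored at 1 for rate evaluation, so a lone producer keeps its full
#' self-benefit and a lone free-rider gets none). The density factor is
#' global by default -- \eqn{E_K = 1 - Y_{tot}/K} with a single
#' system-wide capacity -- or per-compartment
#' (\eqn{E_{K,i} = 1 - (C_i + D_i)/(K/N)}) via \code{capacity_mode}.
#' The continuous within-step masses are returned to integers by
#' expectation-preserving stochastic rounding.
#'
#' @param state a [compartment_state()].
#' @param params a [pgg_params()] object (its neighborhood fields are
#'   ignored; occupancy takes their place).
#' @param T_s selection time between mixes (days).
#' @param capacity_mode \code{"global"} (default) or
#'   \code{"per_compartment"}.
#' @param n_steps RK4 steps for the selection interval (default >= 10
#'   steps/day).
#' @param stochastic_round logical; set \code{FALSE} to keep continuous
#'   masses (used by deterministic checks).
#' @return A new \code{pgg_compartments}.
#' @export
select_within <- function(state, params, T_s,
                          capacity_mode = c("global", "per_compartment"),
                          n_steps = NULL, stochastic_round = TRUE) {
  stopifnot(inherits(state, "pgg_compartments"),
            inherits(params, "pgg_params"))
  capacity_mode <- match.arg(capacity_mode)
  if (T_s <= 0) stop("T_s must be positive")
  if (is.null(n_steps)) n_steps <- max(20L, ceiling(T_s * 10))
  out <- .compartment_rk4_cpp(state$C, state$D, unclass(params),
                              T_s, as.integer(n_steps),
                              capacity_mode == "global")
  cc <- out[, 1]; dd <- out[, 2]
  if (stochastic_round) {
    cc <- stochastic_round(cc); dd <- stochastic_round(dd)
  }
  compartment_state(cc, dd)
}

# expectation-preserving integerization: floor plus a Bernoulli trial on
# the fractional part
stochastic_round <- function(x) {
  fl <- floor(x)
  fl + (stats::runif(length(x)) < (x - fl))
}

#' Alternating mix--select cycles
#'
#' Runs the quasi-spatial protocol: starting from pooled totals, repeat
#' [mix_compartments()] followed by [select_within()] for
#' \code{n_cycles}, tracking the global counts after every cycle. The
#' long-run cooperator fraction is the mean over the last 20\% of cycles
#' (extinct cycles excluded).
#'
#' @param params a [pgg_params()] object.
#' @param N number of compartments (>= 1).
#' @param init_totals global initial counts \code{c(C, D)}.
#' @param T_s selection time per cycle (days); default \code{10 /
#'   max(alpha)}.
#' @param n_cycles number of mix--select cycles (default 200).
#' @param seed optional integer seed.
#' @param capacity_mode passed to [select_within()].
#' @return An object of class \code{"pgg_mixing"}: list with
#'   \code{trajectory} (data frame: cycle, C, D, y), the long-run
#'   cooperator fraction \code{y_steady}, a \code{label} from
#'   [classify_outcome()] on the final rounded counts, and the
#'   configuration.
#' @examples
#' p <- pgg_params(delta_C = 0.1, delta_D = 0.1, kappa = 0.5, K = 1000,
#'                 sigma = 3, beta = 2)
#' run_mixing_cycles(p, N = 300, init_totals = c(50, 50),
#'                   n_cycles = 30, seed = 1)
#' @export
run_mixing_cycles <- function(params, N, init_totals, T_s = NULL,
                              n_cycles = 200, seed = NULL,
                              capacity_mode = "global") {
  stopifnot(inherits(params, "pgg_params"), N >= 1, n_cycles >= 1)
  if (is.null(T_s)) T_s <- 10 / max(params$alpha_C, params$alpha_D)
  if (!is.null(seed)) set.seed(seed)
  state <- compartment_state(c(init_totals[1], numeric(N - 1)),
                             c(init_totals[2], numeric(N - 1)))
  traj <- data.frame(cycle = 0:n_cycles, C = NA_real_, D = NA_real_)
  traj$C[1] <- init_totals[1]; traj$D[1] <- init_totals[2]
  for (k in seq_len(n_cycles)) {
    state <- mix_compartments(state)
    state <- select_within(state, params, T_s,
                           capacity_mode = capacity_mode)
    traj$C[k + 1] <- sum(state$C); traj$D[k + 1] <- sum(state$D)
    if (traj$C[k + 1] + traj$D[k + 1] == 0) {
      traj <- traj[seq_len(k + 1), ]
      break
    }
  }
  Y <- traj$C + traj$D
  traj$y <- ifelse(Y > 0, traj$C / Y, NA_real_)
  tail_idx <- seq.int(max(1, ceiling(0.8 * nrow(traj))), nrow(traj))
  y_steady <- mean(traj$y[tail_idx], na.rm = TRUE)
  fin <- c(traj$C[nrow(traj)], traj$D[nrow(traj)])
  structure(list(trajectory = traj, y_steady = y_steady,
                 label = classify_outcome(fin), final = fin,
                 params = params, N = N, T_s = T_s, n_cycles = n_cycles,
                 seed = seed, capacity_mode = capacity_mode),
            class = "pgg_mixing")
}

#' @export
print.pgg_mixing <- function(x, ...) {
  cat(sprintf("Mix-select protocol: N = %d compartments, %d cycles of T_s = %g days\n",
              x$N, x$n_cycles, x$T_s))
  cat(sprintf("  long-run cooperator fraction %.4f (%s)\n",
              x$y_steady, x$label))
  invisible(x)
}

#' Sweep the number of compartments, forward and backward
#'
#' Computes the long-run cooperator fraction as a function of the number
#' of compartments \code{N}. With \code{reinitialize = TRUE} every
#' \code{N} starts from \code{init_totals}; with \code{FALSE} each step
#' inherits the previous step's final pooled counts (topped up with one
#' individual of a missing type so absorbing monomorphic states can
#' respond), and a backward sweep is run the same way -- disagreement
#' between the branches marks hysteresis.
#'
#' @param params a [pgg_params()] object.
#' @param N_values sorted vector of compartment counts.
#' @param init_totals global initial counts \code{c(C, D)}.
#' @param reinitialize logical (default \code{TRUE}).
#' @param replicates replicate runs per \code{N} (default 1; replicate
#'   \code{r} uses child seed \code{seed + 1000 (r-1)}).
#' @param T_s,n_cycles,capacity_mode protocol settings, as in
#'   [run_mixing_cycles()].
#' @param seed root seed.
#' @return An object of class \code{"pgg_Nsweep"}: data frame with
#'   columns \code{N}, \code{replicate}, \code{direction}
#'   (\code{"forward"}/\code{"backward"}; forward only when
#'   reinitializing), \code{y_steady}, \code{label}.
#' @export
sweep_compartments <- function(params, N_values, init_totals,
                               reinitialize = TRUE, replicates = 1,
                               T_s = NULL, n_cycles = 200, seed = 1,
                               capacity_mode = "global") {
  stopifnot(inherits(params, "pgg_params"))
  if (is.unsorted(N_values)) stop("N_values must be sorted")
  rows <- list()
  add <- function(N, rep, dir, run) rows[[length(rows) + 1L]] <<-
    data.frame(N = N, replicate = rep, direction = dir,
               y_steady = run$y_steady, label = run$label,
               final_C = run$final[1], final_D = run$final[2])
  if (reinitialize) {
    for (r in seq_len(replicates))
      for (i in seq_along(N_values))
        add(N_values[i], r, "forward",
            run_mixing_cycles(params, N_values[i], init_totals, T_s,
                              n_cycles, seed + 1000L * (r - 1L) + i,
                              capacity_mode))
  } else {
    for (r in seq_len(replicates)) {
      for (dir in c("forward", "backward")) {
        vals <- if (dir == "forward") N_values else rev(N_values)
        totals <- init_totals
        for (i in seq_along(vals)) {
          totals <- pmax(totals, 1)  # seed a lost type with one migrant
          run <- run_mixing_cycles(params, vals[i], totals, T_s, n_cycles,
                                   seed + 1000L * (r - 1L) +
                                     i + 500L * (dir == "backward"),
                                   capacity_mode)
          totals <- run$final
          add(vals[i], r, dir, run)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$direction, out$replicate, out$N), ]
  rownames(out) <- NULL
  structure(out, params = params, reinitialize = reinitialize,
            class = c("pgg_Nsweep", "data.frame"))
}

#' @export
print.pgg_Nsweep <- function(x, ...) {
  cat(sprintf("Compartment sweep over %d N values (%s)\n",
              length(unique(x$N)),
              if (attr(x, "reinitialize")) "re-initialized"
              else "state-carrying forward/backward"))
  agg <- stats::aggregate(y_steady ~ direction + N, data = x, FUN = mean)
  print(utils::head(agg[order(agg$direction, agg$N), ], 20),
        row.names = FALSE)
  invisible(x)
}

#' Write a compartment sweep to CSV with a config echo
#'
#' @param sweep a [sweep_compartments()] result.
#' @param csv_path output CSV path; the configuration echo goes to
#'   \code{<csv_path>.json}.
#' @return \code{csv_path}, invisibly.
#' @export
write_sweep_report <- function(sweep, csv_path) {
  utils::write.csv(as.data.frame(sweep), csv_path, row.names = FALSE)
  jsonlite::write_json(list(params = unclass(attr(sweep, "params")),
                            reinitialize = attr(sweep, "reinitialize")),
                       paste0(csv_path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(csv_path)
}

#' Critical compartment number, by replicated simulation
#'
#' Estimates the smallest \code{N} above which the long-run state of the
#' mix--select protocol is all-cooperator, by bisection on \code{N} with
#' a majority rule over replicate runs at each probe.
#'
#' @param params a [pgg_params()] object.
#' @param N_range integer vector \code{c(low, high)} bracketing the
#'   transition.
#' @param init_totals,T_s,n_cycles,capacity_mode protocol settings.
#' @param replicates replicates per probed \code{N} (default 10).
#' @param seed root seed.
#' @return A list of class \code{"pgg_ncrit"} with \code{N_crit}
#'   (\code{NA} if no transition inside the range), the probe log, and
#'   the configuration.
#' @export
ncrit_numeric <- function(params, N_range, init_totals = c(50, 50),
                          T_s = NULL, n_cycles = 200, replicates = 10,
                          seed = 1, capacity_mode = "global") {
  stopifnot(inherits(params, "pgg_params"), length(N_range) == 2)
  allC_at <- function(N) {
    lab <- vapply(seq_len(replicates), function(r) {
      run_mixing_cycles(params, N, init_totals, T_s, n_cycles,
                        seed + 97L * N + r, capacity_mode)$label
    }, character(1))
    mean(lab == "all_C") > 0.5
  }
  lo <- ceiling(N_range[1]); hi <- floor(N_range[2])
  probes <- list()
  note <- function(N, res) probes[[length(probes) + 1L]] <<-
    data.frame(N = N, majority_all_C = res)
  r_lo <- allC_at(lo); note(lo, r_lo)
  r_hi <- allC_at(hi); note(hi, r_hi)
  if (r_lo || !r_hi) {
    return(structure(list(N_crit = NA_integer_,
                          probes = do.call(rbind, probes),
                          params = params, reason = if (r_lo)
                            "already all_C at lower bound"
                          else "no all_C transition up to upper bound"),
                     class = "pgg_ncrit"))
  }
  while (hi - lo > 1L) {
    mid <- (lo + hi) %/% 2L
    r_mid <- allC_at(mid); note(mid, r_mid)
    if (r_mid) hi <- mid else lo <- mid
  }
  structure(list(N_crit = hi, probes = do.call(rbind, probes),
                 params = params, reason = "transition bracketed"),
            class = "pgg_ncrit")
}

#' Critical compartment number, mean-field prediction
#'
#' Replaces the fluctuating occupancies by their expectation \eqn{Y/N}
#' and asks when all-cooperator becomes the long-run state. Two
#' conditions must hold, both improving as compartments shrink:
#' \enumerate{
#'   \item the all-defector resident (at \eqn{Y^*_D = K(1 -
#'     \delta_D/\alpha_D)}, effective neighborhood \eqn{n = Y^*_D/N}) is
#'     invadable by a rare cooperator, \eqn{r_C(y \to 0; n)/\delta_C >
#'     r_D(0)/\delta_D} -- the self-benefit \eqn{N_C = 1/n} grows as
#'     compartments shrink;
#'   \item the all-cooperator state (at \eqn{Y^*_C}, effective
#'     neighborhood \eqn{Y^*_C/N}) is *not* invadable by a rare
#'     defector, \eqn{r_D(1; n)/\delta_D < r_C(1)/\delta_C}.
#' }
#' The prediction is the smallest integer \code{N} satisfying both. The
#' second condition is what makes the prediction rise toward \eqn{Y^*}
#' for very strong frequency dependence (large \eqn{\beta}): free-riders
#' profit from an almost-full producer neighborhood unless compartments
#' hold barely more than one cell, giving the characteristic
#' non-monotonic \eqn{N_{crit}(\beta)}.
#'
#' @param params a [pgg_params()] object (neighborhood fields ignored).
#' @param N_max largest \code{N} considered (default
#'   \code{ceiling(K)}: about one cell per compartment).
#' @return The predicted critical \code{N} (integer), or \code{NA} if the
#'   conditions fail for every \code{N} up to \code{N_max}.
#' @examples
#' p <- pgg_params(delta_C = 0.1, delta_D = 0.1, kappa = 0.5, K = 1000,
#'                 sigma = 3, beta = 2)
#' ncrit_meanfield(p)
#' @export
ncrit_meanfield <- function(params, N_max = NULL) {
  stopifnot(inherits(params, "pgg_params"))
  if (params$alpha_D <= params$delta_D)
    stop("all-defector resident is not viable (alpha_D <= delta_D)")
  YD <- params$K * (1 - params$delta_D / params$alpha_D)
  rC1 <- params$alpha_C *
    sigmoid_benefit(1, params$beta, params$sigma) - params$kappa
  YC <- if (rC1 > params$delta_C)
    params$K * (1 - params$delta_C / rC1) else NA_real_
  if (is.na(YC)) return(NA_integer_)  # all-C not even viable
  if (is.null(N_max)) N_max <- max(1L, ceiling(params$K))
  rD0 <- params$alpha_D
  for (N in seq_len(N_max)) {
    n_inv <- max(YD / N, 1)
    rC0 <- params$alpha_C *
      sigmoid_benefit(1 / n_inv, params$beta, params$sigma) - params$kappa
    allD_invadable <- rC0 * params$delta_D - params$delta_C * rD0 > 0
    n_res <- max(YC / N, 1)
    rD1 <- params$alpha_D *
      sigmoid_benefit((n_res - 1) / n_res, params$beta, params$sigma)
    allC_stable <- rD1 * params$delta_C - params$delta_D * rC1 < 0
    if (allD_invadable && allC_stable) return(N)
  }
  NA_integer_
}

#' @export
print.pgg_ncrit <- function(x, ...) {
  if (is.na(x$N_crit))
    cat("Critical compartment number: not found (", x$reason, ")\n",
        sep = "")
  else
    cat(sprintf("Critical compartment number: N_crit = %d (%d probes)\n",
                x$N_crit, nrow(x$probes)))
  invisible(x)
}
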
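#' Exact stochastic simulation of the individual-based model
#'
#' Samples one path of the continuous-time Markov jump process underlying
#' the mean-field model: per-capita birth propensities
#' \eqn{\max(0, r_i(y) E_K)} and constant death rates \eqn{\delta_i} for
#' each type \eqn{i \in \{C, D\}}, with the density factor
#' \eqn{E_K = 1 - (C+D)/K}. Propensities are recomputed after every event
#' (direct Gillespie method), so the path is statistically exact. The
#' state (0, 0) is absorbing.
#'
#' In \code{rate_mode = "sampled_neighborhood"} the producer fraction seen
#' by a focal cell is not the mean-field expectation but a fresh
#' hypergeometric draw of its \eqn{n - 1} neighbors from the current
#' population at every event (truncated when fewer individuals remain);
#' for large populations this perturbs the dynamics only negligibly.
#'
#' @param params a [pgg_params()] object. \code{K = Inf} freezes
#'   \eqn{E_K = 1}.
#' @param init integer initial counts \code{c(C, D)}.
#' @param t_max simulation horizon (days).
#' @param record output time grid (days); default 201 equally spaced
#'   points on \[0, t_max\]. The state recorded at time t is the state
#'   immediately before the first event after t.
#' @param seed optional integer seed (\code{set.seed} is called); runs
#'   with identical configuration and seed produce identical event
#'   sequences.
#' @param rate_mode \code{"mean_field"} (default) or
#'   \code{"sampled_neighborhood"}.
#' @return A \code{pgg_ibm_trajectory}: data frame with columns
#'   \code{time, x_C, x_D, y, Y} (integer counts), with attributes
#'   \code{final} (final counts), \code{n_events} and \code{params}.
#' @examples
#' p <- pgg_params(alpha_D = 1, delta_C = 0.1, delta_D = 0.1, K = 1000)
#' tr <- pgg_gillespie(p, init = c(0, 100), t_max = 50, seed = 1)
#' tail(tr, 2)
#' @export
pgg_gillespie <- function(params, init, t_max,
                          record = NULL, seed = NULL,
                          rate_mode = c("mean_field",
                                        "sampled_neighborhood")) {
  stopifnot(inherits(params, "pgg_params"))
  rate_mode <- match.arg(rate_mode)
  if (length(init) != 2L || any(init < 0) || any(init != round(init)))
    stop("init must be two nonnegative integer counts c(C, D)")
  if (t_max <= 0) stop("t_max must be positive")
  if (is.null(record)) record <- seq(0, t_max, length.out = 201L)
  if (!is.null(seed)) set.seed(seed)
  res <- .gillespie_cpp(as.integer(init[1]), as.integer(init[2]),
                        as.numeric(t_max), as.numeric(record),
                        unclass(params),
                        rate_mode == "sampled_neighborhood")
  Y <- res$x_C + res$x_D
  out <- data.frame(time = record, x_C = res$x_C, x_D = res$x_D,
                    y = ifelse(Y > 0, res$x_C / Y, NA_real_), Y = Y)
  structure(out, final = c(C = res$final_C, D = res$final_D),
            n_events = res$n_events, params = params, seed = seed,
            rate_mode = rate_mode,
            class = c("pgg_ibm_trajectory", "data.frame"))
}

#' Classify the final state of a stochastic run
#'
#' @param final integer counts \code{c(C, D)} at the end of a run.
#' @param coexistence_min minimum count of each type to call coexistence
#'   (default 1).
#' @return One of \code{"all_C"}, \code{"all_D"}, \code{"coexistence"},
#'   \code{"extinct"}.
#' @examples
#' classify_outcome(c(0, 850))    # "all_D"
#' classify_outcome(c(300, 400))  # "coexistence"
#' @export
classify_outcome <- function(final, coexistence_min = 1) {
  C <- final[[1]]; D <- final[[2]]
  if (C == 0 && D == 0) "extinct"
  else if (C == 0) "all_D"
  else if (D == 0) "all_C"
  else if (C >= coexistence_min && D >= coexistence_min) "coexistence"
  else "coexistence"  # both positive but below threshold: still mixed
}

#' Ensemble of independent stochastic runs
#'
#' Runs \code{n_runs} independent Gillespie simulations (child seeds
#' derived from \code{seed} by run index), classifies each final state,
#' and aggregates outcome frequencies (with binomial standard errors) and
#' the ensemble mean trajectory (with per-time standard errors of the
#' mean).
#'
#' @inheritParams pgg_gillespie
#' @param n_runs number of replicates (>= 1).
#' @param seed root seed; run \code{k} uses \code{seed + k - 1}.
#' @param coexistence_min threshold for [classify_outcome()].
#' @return An object of class \code{"pgg_ensemble"}: list with
#'   \code{labels} (per-run), \code{finals} (n_runs x 2 matrix),
#'   \code{frequencies} and \code{se} (named vectors over the four
#'   labels), \code{mean_trajectory} (data frame: time, mean and SE of
#'   both types), \code{n_runs}, and the configuration.
#' @examples
#' p <- pgg_params(delta_C = 0.1, delta_D = 0.1, kappa = 0.5, K = 200,
#'                 sigma = 2, beta = 5, n = 15)
#' en <- pgg_ensemble(p, init = c(18, 2), t_max = 30, n_runs = 20, seed = 1)
#' en$frequencies
#' @export
pgg_ensemble <- function(params, init, t_max, n_runs, seed = 1,
                         record = NULL, coexistence_min = 1,
                         rate_mode = c("mean_field",
                                       "sampled_neighborhood")) {
  stopifnot(inherits(params, "pgg_params"), n_runs >= 1)
  rate_mode <- match.arg(rate_mode)
  if (is.null(record)) record <- seq(0, t_max, length.out = 101L)
  nr <- length(record)
  sumC <- sumD <- sqC <- sqD <- numeric(nr)
  finals <- matrix(0L, n_runs, 2, dimnames = list(NULL, c("C", "D")))
  labels <- character(n_runs)
  for (k in seq_len(n_runs)) {
    tr <- pgg_gillespie(params, init, t_max, record = record,
                        seed = seed + k - 1L, rate_mode = rate_mode)
    finals[k, ] <- attr(tr, "final")
    labels[k] <- classify_outcome(finals[k, ], coexistence_min)
    sumC <- sumC + tr$x_C; sumD <- sumD + tr$x_D
    sqC <- sqC + tr$x_C^2; sqD <- sqD + tr$x_D^2
  }
  lv <- c("all_C", "all_D", "coexistence", "extinct")
  freq <- table(factor(labels, levels = lv)) / n_runs
  freq_se <- sqrt(freq * (1 - freq) / n_runs)
  mC <- sumC / n_runs; mD <- sumD / n_runs
  sdC <- sqrt(pmax(sqC / n_runs - mC^2, 0) * n_runs / max(n_runs - 1, 1))
  sdD <- sqrt(pmax(sqD / n_runs - mD^2, 0) * n_runs / max(n_runs - 1, 1))
  mt <- data.frame(time = record, mean_C = mC, mean_D = mD,
                   se_C = sdC / sqrt(n_runs), se_D = sdD / sqrt(n_runs))
  structure(list(labels = labels, finals = finals,
                 frequencies = stats::setNames(as.numeric(freq), lv),
                 se = stats::setNames(as.numeric(freq_se), lv),
                 mean_trajectory = mt, n_runs = n_runs, params = params,
                 init = init, t_max = t_max, seed = seed,
                 rate_mode = rate_mode,
                 coexistence_min = coexistence_min),
            class = "pgg_ensemble")
}

#' @export
print.pgg_ensemble <- function(x, ...) {
  cat(sprintf("Stochastic ensemble: %d runs to t = %g days (seed %s, %s rates)\n",
              x$n_runs, x$t_max, x$seed, x$rate_mode))
  f <- x$frequencies
  for (nm in names(f))
    cat(sprintf("  %-12s %5.1f%%  (SE %.1f%%)\n", nm, 100 * f[[nm]],
                100 * x$se[[nm]]))
  invisible(x)
}

#' Write an ensemble summary to JSON
#'
#' Emits label frequencies with standard errors plus a configuration echo
#' sufficient to reproduce the ensemble (parameters, initial counts,
#' horizon, seed, rate mode).
#'
#' @param ensemble a [pgg_ensemble()] result.
#' @param path output JSON path.
#' @return \code{path}, invisibly.
#' @export
write_ensemble_report <- function(ensemble, path) {
  stopifnot(inherits(ensemble, "pgg_ensemble"))
  jsonlite::write_json(
    list(frequencies = as.list(ensemble$frequencies),
         standard_errors = as.list(ensemble$se),
         n_runs = ensemble$n_runs,
         config = list(params = unclass(ensemble$params),
                       init = ensemble$init, t_max = ensemble$t_max,
                       seed = ensemble$seed,
                       rate_mode = ensemble$rate_mode,
                       coexistence_min = ensemble$coexistence_min)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
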
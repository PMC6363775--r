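#' Design of a synthetic frequency-change experiment
#'
#' Describes a cell-competition assay layout: initial cooperator
#' fractions, replication, assay duration, one or more conditions each
#' with its own true benefit parameters, the neighborhood-size truth
#' (fixed or drawn per record), and the additive observation noise on
#' \eqn{\Delta y}. Defaults emulate a 4-day co-culture competition:
#' a 9-point grid of seeding fractions, 3 replicates, noise SD 0.02, and
#' a single condition at the benefit parameters estimated for sparse
#' background nutrients (\eqn{\beta = 3.67}, \eqn{\sigma = 1.87}) with a
#' fixed true neighborhood of 22 cells.
#'
#' @param y0_levels initial cooperator fractions, all in (0, 1).
#' @param replicates replicates per level per condition.
#' @param duration assay duration (days).
#' @param conditions data frame with columns \code{condition},
#'   \code{beta}, \code{sigma} (one row per condition).
#' @param n_truth either a single neighborhood size used for all records
#'   or the string \code{"uniform"} to draw each record's n uniformly
#'   from \code{n_range}.
#' @param n_range integer range for \code{n_truth = "uniform"} (default
#'   4--40).
#' @param noise_sd Gaussian observation noise SD on \eqn{\Delta y}
#'   (>= 0).
#' @return A list of class \code{"pgg_design"}.
#' @export
freq_change_design <- function(y0_levels = seq(0.1, 0.9, by = 0.1),
                               replicates = 3, duration = 4,
                               conditions = data.frame(
                                 condition = "5pct_serum",
                                 beta = 3.67, sigma = 1.87),
                               n_truth = 22, n_range = c(4, 40),
                               noise_sd = 0.02) {
  if (any(y0_levels <= 0 | y0_levels >= 1))
    stop("y0 levels must lie strictly inside (0, 1)")
  if (noise_sd < 0) stop("noise_sd must be nonnegative")
  if (!all(c("condition", "beta", "sigma") %in% names(conditions)))
    stop("conditions needs columns condition, beta, sigma")
  structure(list(y0_levels = y0_levels, replicates = replicates,
                 duration = duration, conditions = conditions,
                 n_truth = n_truth, n_range = n_range,
                 noise_sd = noise_sd),
            class = "pgg_design")
}

#' Generate a synthetic frequency-change dataset
#'
#' Evaluates the model surface [predict_delta_y()] at the design's true
#' parameters for every (condition, y0, replicate) cell and adds
#' independent Gaussian noise. With \code{noise_sd = 0} the data lie
#' exactly on the surface, so fitting recovers the truth (round-trip
#' identity). Output is reproducible given \code{seed}.
#'
#' @param design a [freq_change_design()].
#' @param fixed fixed-parameter list, see [predict_delta_y()].
#' @param seed integer seed.
#' @return A data frame with columns \code{condition, y0, delta_y,
#'   duration_days, replicate} (and \code{n_true} when n is drawn), with
#'   the design and truth attached as attributes.
#' @examples
#' d <- simulate_frequency_change(freq_change_design(), seed = 42)
#' head(d)
#' @export
simulate_frequency_change <- function(design = freq_change_design(),
                                      fixed = list(), seed = 1) {
  stopifnot(inherits(design, "pgg_design"))
  set.seed(seed)
  draw_n <- identical(design$n_truth, "uniform")
  rows <- list()
  for (ci in seq_len(nrow(design$conditions))) {
    cond <- design$conditions[ci, ]
    for (y0 in design$y0_levels) {
      for (rep in seq_len(design$replicates)) {
        n <- if (draw_n)
          sample(seq(design$n_range[1], design$n_range[2]), 1)
        else design$n_truth
        mu <- predict_delta_y(cond$beta, cond$sigma, n, y0,
                              design$duration, fixed)
        dy <- mu + stats::rnorm(1, 0, design$noise_sd)
        dy <- min(max(dy, -y0), 1 - y0)  # keep y0 + delta_y in [0, 1]
        rows[[length(rows) + 1L]] <- data.frame(
          condition = cond$condition, y0 = y0, delta_y = dy,
          duration_days = design$duration, replicate = rep, n_true = n)
      }
    }
  }
  out <- do.call(rbind, rows)
  if (!draw_n) out$n_true <- NULL
  structure(out, design = design, seed = seed,
            class = c("pgg_freq_data", "data.frame"))
}

#' Read and write frequency-change datasets
#'
#' CSV dialect with header \code{condition,y0,delta_y,duration_days,
#' replicate} (extra columns are kept).
#'
#' @param path CSV file path.
#' @return \code{read_frequency_data} returns the validated data frame;
#'   \code{write_frequency_data} returns \code{path} invisibly.
#' @export
read_frequency_data <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("condition", "y0", "delta_y", "duration_days", "replicate")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("dataset is missing column(s): ",
                         paste(miss, collapse = ", "))
  if (any(d$y0 < 0 | d$y0 > 1) ||
      any(d$y0 + d$delta_y < -1e-9 | d$y0 + d$delta_y > 1 + 1e-9))
    stop("y0 and y0 + delta_y must lie in [0, 1]")
  if (any(d$duration_days <= 0)) stop("duration_days must be positive")
  d
}

#' @rdname read_frequency_data
#' @param data a frequency-change data frame.
#' @export
write_frequency_data <- function(data, path) {
  utils::write.csv(as.data.frame(data), path, row.names = FALSE)
  invisible(path)
}

#' Named simulation scenarios
#'
#' Parameter bundles for the model's characteristic regimes, usable as
#' ready-made configurations for the stochastic, deterministic and
#' compartment simulators. Available scenarios:
#' \describe{
#'   \item{\code{coexistence_ibm}}{\eqn{\beta > \sigma} (5 vs 2), n = 15,
#'     K = 1000: stochastic runs mostly reach stable coexistence.}
#'   \item{\code{bistable_ibm}}{\eqn{\beta < \sigma} (2 vs 3), n = 15,
#'     K = 1000: alternative stable states; occasional stochastic
#'     branching to coexistence.}
#'   \item{\code{saddle_node_sweep}}{\eqn{\beta > \sigma} (5 vs 2):
#'     sweeping n annihilates the interior equilibrium pair.}
#'   \item{\code{transcritical_sweep}}{\eqn{\beta < \sigma} (2 vs 3):
#'     sweeping n exchanges stability with the monomorphic states.}
#'   \item{\code{defector_invasion}}{resident defectors at
#'     \eqn{K(1-\delta/\alpha)} invaded by 10 cooperators; type-specific
#'     neighborhoods (\eqn{n_C = 5}, \eqn{n_D = 30}).}
#'   \item{\code{mixing_transcritical}}{compartment protocol in the
#'     \eqn{\beta < \sigma} regime: sharp all-D to all-C transition in
#'     N.}
#'   \item{\code{mixing_saddle}}{compartment protocol in the
#'     \eqn{\beta > \sigma} regime: coexistence window before all-C.}
#' }
#'
#' @param name scenario name.
#' @return A list with \code{params} (a [pgg_params()]), \code{init}
#'   (initial counts), and where relevant \code{t_max} or protocol
#'   fields (\code{T_s}).
#' @examples
#' sc <- pgg_scenario("coexistence_ibm")
#' sc$params
#' @export
pgg_scenario <- function(name = c("coexistence_ibm", "bistable_ibm",
                                  "saddle_node_sweep",
                                  "transcritical_sweep",
                                  "defector_invasion",
                                  "mixing_transcritical",
                                  "mixing_saddle")) {
  name <- match.arg(name)
  base <- pgg_params(alpha_C = 1, alpha_D = 1, delta_C = 0.1,
                     delta_D = 0.1, kappa = 0.5, K = 1000)
  switch(name,
    coexistence_ibm = list(
      params = update_params(base, sigma = 2, beta = 5, n = 15),
      init = c(90, 10), t_max = 200),
    bistable_ibm = list(
      params = update_params(base, sigma = 3, beta = 2, n = 15),
      init = c(90, 10), t_max = 200),
    saddle_node_sweep = list(
      params = update_params(base, sigma = 2, beta = 5),
      init = c(90, 10), sweep = seq(2, 40, by = 1)),
    transcritical_sweep = list(
      params = update_params(base, sigma = 3, beta = 2),
      init = c(90, 10), sweep = seq(2, 24, by = 1)),
    defector_invasion = list(
      params = update_params(base, sigma = 2, beta = 5, n_C = 5, n_D = 30),
      init = c(10, base$K * (1 - base$delta_D / base$alpha_D)),
      t_max = 500),
    mixing_transcritical = list(
      params = update_params(base, sigma = 3, beta = 2),
      init = c(50, 50), T_s = 10),
    mixing_saddle = list(
      params = update_params(base, sigma = 2, beta = 5),
      init = c(50, 50), T_s = 10))
}
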
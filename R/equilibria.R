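# Interior equilibria solve delta_D * r_C(y) - delta_C * r_D(y) = 0: the
# polymorphic condition r_C/r_D = delta_C/delta_D in cross-multiplied form,
# valid also where r_D could vanish.
interior_condition <- function(y, params) {
  r <- growth_rates(y, params, "both")
  params$delta_D * r$r_C - params$delta_C * r$r_D
}

#' Interior (polymorphic) equilibria and their stability
#'
#' Finds all roots of the polymorphic condition \eqn{\delta_D r_C(y) =
#' \delta_C r_D(y)} on (0, 1) by bracketing sign changes on a dense grid
#' and refining by bisection, then attaches the equilibrium total
#' population \eqn{Y^* = K(1 - \delta_C / r_C(y^*))} and a stability label
#' from the eigenvalues of the Jacobian of the coupled logistic system.
#' For the sigmoidal benefit family at most two interior equilibria exist;
#' an empty result is valid (e.g. always for \eqn{\beta = 0}).
#'
#' Tangential (degenerate) contacts, where the condition touches zero
#' without changing sign -- the saddle-node point itself -- are reported
#' with \code{degenerate = TRUE}.
#'
#' @param params a [pgg_params()] object.
#' @param grid_n number of grid points used for bracketing (default 4096).
#' @param tol bisection tolerance on \eqn{y^*}.
#' @return A data frame of class \code{"pgg_equilibria"} with columns
#'   \code{y_star}, \code{Y_star}, \code{kind}, \code{stability}
#'   (\code{"stable"} if all eigenvalues are negative, \code{"marginal"}
#'   if one is numerically zero, else \code{"unstable"} -- for an interior
#'   point the total-population direction is always attracting, so a 2D
#'   saddle is repelling in the frequency direction),
#'   \code{eig1}, \code{eig2} (real parts, per day)
#'   and \code{degenerate}. Zero rows when no interior equilibrium exists.
#'   When \eqn{Y^* \le 0} (the polymorphic frequency is not demographically
#'   viable) \code{Y_star} is \code{NA} and stability refers to the
#'   frequency equation alone.
#' @examples
#' p <- pgg_params(alpha_C = 1, alpha_D = 1, delta_C = 0.1, delta_D = 0.1,
#'                 kappa = 0.25, beta = 3.67, sigma = 1.87, n = 22)
#' interior_equilibria(p)  # unstable ~0.235 and stable ~0.784
#' @export
interior_equilibria <- function(params, grid_n = 4096L, tol = 1e-10) {
  stopifnot(inherits(params, "pgg_params"))
  g <- seq(0, 1, length.out = grid_n + 1L)
  g[1] <- 1e-12; g[length(g)] <- 1 - 1e-12
  fg <- interior_condition(g, params)
  roots <- numeric(0); degen <- logical(0)
  idx <- which(fg[-length(fg)] * fg[-1] < 0)
  for (i in idx) {
    r <- stats::uniroot(interior_condition, c(g[i], g[i + 1]),
                        params = params, tol = tol)$root
    roots <- c(roots, r); degen <- c(degen, FALSE)
  }
  # tangency: interior local minimum of |f| essentially at zero, no sign flip
  af <- abs(fg)
  loc <- which(diff(sign(diff(af))) > 0) + 1L
  for (i in loc) {
    if (af[i] < 1e-8 && !any(abs(g[i] - roots) < 1e-4)) {
      roots <- c(roots, g[i]); degen <- c(degen, TRUE)
    }
  }
  if (length(roots)) {
    o <- order(roots); roots <- roots[o]; degen <- degen[o]
    keep <- c(TRUE, diff(roots) > 1e-6)
    roots <- roots[keep]; degen <- degen[keep]
  }
  res <- lapply(seq_along(roots), function(k) {
    y <- roots[k]
    rC <- growth_rates(y, params, "C")
    Ys <- if (rC > params$delta_C) params$K * (1 - params$delta_C / rC)
          else NA_real_
    if (!is.na(Ys)) {
      ev <- jacobian_eigen(c(y * Ys, (1 - y) * Ys), params)
      # interior points: the total-population direction is attracting, so a
      # 2D saddle is an equilibrium the frequency dynamics flee -> unstable
      stab <- if (max(abs(ev)) < 1e-8) "marginal"
              else if (max(ev) < 0) "stable" else "unstable"
    } else {
      # no positive-density counterpart: classify the frequency flow only
      h <- 1e-6
      slope <- (interior_condition(min(y + h, 1), params) -
                  interior_condition(max(y - h, 0), params)) / (2 * h)
      ev <- c(sign(slope), NA_real_)
      stab <- if (slope > 0) "unstable" else "stable"
    }
    data.frame(y_star = y, Y_star = Ys, kind = "interior", stability = stab,
               eig1 = ev[1], eig2 = ev[2], degenerate = degen[k])
  })
  out <- if (length(res)) do.call(rbind, res)
         else data.frame(y_star = numeric(0), Y_star = numeric(0),
                         kind = character(0), stability = character(0),
                         eig1 = numeric(0), eig2 = numeric(0),
                         degenerate = logical(0))
  structure(out, params = params,
            class = c("pgg_equilibria", "data.frame"))
}

# real parts of the eigenvalues of the Jacobian of the coupled logistic
# system at a state, via central finite differences (step 1e-6 relative)
jacobian_eigen <- function(state, params) {
  J <- matrix(0, 2, 2)
  for (j in 1:2) {
    h <- 1e-6 * max(1, abs(state[j]))
    up <- dn <- state
    up[j] <- up[j] + h; dn[j] <- max(dn[j] - h, 0)
    J[, j] <- (ode_rhs(up, params) - ode_rhs(dn, params)) / (up[j] - dn[j])
  }
  sort(Re(eigen(J, only.values = TRUE)$values), decreasing = TRUE)
}

stability_label <- function(ev, tol = 1e-8) {
  if (any(abs(ev) < tol, na.rm = TRUE)) return("marginal")
  neg <- sum(ev < 0, na.rm = TRUE)
  if (neg == sum(!is.na(ev))) "stable"
  else if (neg == 0) "unstable"
  else "saddle"
}

#' Monomorphic and extinction equilibria with stability
#'
#' The all-defector state sits at \eqn{(0, K(1-\delta_D/\alpha_D))} and
#' exists iff \eqn{\alpha_D > \delta_D}; the all-cooperator state at
#' \eqn{Y = K(1-\delta_C/r_C(1))} iff \eqn{r_C(1) > \delta_C}. Stability
#' combines demographic stability along the resident direction with
#' resistance to invasion by the rare other type: cooperators invade
#' all-D iff \eqn{r_C(0)/\delta_C > r_D(0)/\delta_D} and defectors invade
#' all-C iff \eqn{r_D(1)/\delta_D > r_C(1)/\delta_C} (evaluated in
#' cross-multiplied form so zero death rates are handled).
#'
#' @param params a [pgg_params()] object.
#' @return A data frame of class \code{"pgg_equilibria"} with one row per
#'   existing boundary state (\code{kind} in \code{all_C}, \code{all_D},
#'   \code{extinction}), plus logical attributes \code{C_invades_D} and
#'   \code{D_invades_C}.
#' @examples
#' p <- pgg_params(delta_C = 0.05, delta_D = 0.05, kappa = 0.1, K = 100,
#'                 beta = 2, sigma = 2, n = 5)
#' boundary_states(p)   # all-C stable, all-D invadable
#' @export
boundary_states <- function(params) {
  stopifnot(inherits(params, "pgg_params"))
  rC0 <- growth_rates(0, params, "C"); rD0 <- growth_rates(0, params, "D")
  rC1 <- growth_rates(1, params, "C"); rD1 <- growth_rates(1, params, "D")
  C_invades_D <- rC0 * params$delta_D - params$delta_C * rD0 > 0
  D_invades_C <- rD1 * params$delta_C - params$delta_D * rC1 > 0
  rows <- list()
  if (rD0 > params$delta_D) {
    Ys <- params$K * (1 - params$delta_D / rD0)
    ev <- jacobian_eigen(c(0, Ys), params)
    rows$all_D <- data.frame(y_star = 0, Y_star = Ys, kind = "all_D",
                             stability = if (C_invades_D) "saddle"
                                         else stability_label(ev),
                             eig1 = ev[1], eig2 = ev[2], degenerate = FALSE)
  }
  if (rC1 > params$delta_C) {
    Ys <- params$K * (1 - params$delta_C / rC1)
    ev <- jacobian_eigen(c(Ys, 0), params)
    rows$all_C <- data.frame(y_star = 1, Y_star = Ys, kind = "all_C",
                             stability = if (D_invades_C) "saddle"
                                         else stability_label(ev),
                             eig1 = ev[1], eig2 = ev[2], degenerate = FALSE)
  }
  # origin: linearized along each axis (a lone C sees y = 1, a lone D y = 0)
  evo <- c(rC1 - params$delta_C, rD0 - params$delta_D)
  rows$ext <- data.frame(y_star = NA_real_, Y_star = 0, kind = "extinction",
                         stability = stability_label(sort(evo,
                                                          decreasing = TRUE)),
                         eig1 = max(evo), eig2 = min(evo), degenerate = FALSE)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, params = params, C_invades_D = C_invades_D,
            D_invades_C = D_invades_C,
            class = c("pgg_equilibria", "data.frame"))
}

#' @export
print.pgg_equilibria <- function(x, ...) {
  if (nrow(x) == 0) {
    cat("No interior equilibria.\n")
    return(invisible(x))
  }
  cat("Equilibria of the coupled logistic public-goods system:\n")
  print.data.frame(cbind(x[c("kind", "stability")],
                         y_star = round(x$y_star, 5),
                         Y_star = round(x$Y_star, 3)), row.names = FALSE)
  invisible(x)
}

#' Classify the long-run dynamical regime
#'
#' Uses the mutual-invasibility pair at the two monomorphic states:
#' both invade -> \code{coexistence}; only cooperators invade ->
#' \code{C_dominance}; only defectors -> \code{D_dominance}; neither ->
#' \code{bistability}. When neither monomorphic state is demographically
#' viable the class is \code{extinction}. The invasibility verdict is
#' cross-checked against interior-equilibrium stability (coexistence needs
#' a stable interior point, bistability an unstable one); a disagreement
#' raises a warning rather than silently picking one.
#'
#' @param params a [pgg_params()] object.
#' @return A single string: one of \code{"C_dominance"},
#'   \code{"D_dominance"}, \code{"bistability"}, \code{"coexistence"},
#'   \code{"extinction"}.
#' @examples
#' base <- pgg_params(delta_C = 0.05, delta_D = 0.05, kappa = 0.1, K = 100)
#' classify_dynamics(update_params(base, sigma = 0.5, beta = 4, n = 10))
#' @export
classify_dynamics <- function(params) {
  stopifnot(inherits(params, "pgg_params"))
  rC1 <- growth_rates(1, params, "C")
  D_viable <- params$alpha_D > params$delta_D
  C_viable <- rC1 > params$delta_C
  if (!D_viable && !C_viable) return("extinction")
  bs <- boundary_states(params)
  ci <- attr(bs, "C_invades_D"); di <- attr(bs, "D_invades_C")
  cls <- if (ci && di) "coexistence"
         else if (ci) "C_dominance"
         else if (di) "D_dominance"
         else "bistability"
  eq <- interior_equilibria(params)
  ok <- switch(cls,
    coexistence = any(eq$stability == "stable"),
    bistability = any(eq$stability == "unstable") || !C_viable,
    C_dominance = !any(eq$stability == "stable"),
    D_dominance = !any(eq$stability == "stable"))
  if (!isTRUE(ok))
    warning("invasibility class '", cls,
            "' disagrees with interior-equilibrium stability pattern")
  cls
}

#' Phase diagram over the benefit parameters
#'
#' Evaluates [classify_dynamics()] on a \code{beta} x \code{sigma} grid at
#' otherwise fixed parameters.
#'
#' @param params_base a [pgg_params()] object supplying the fixed
#'   parameters.
#' @param beta_grid,sigma_grid numeric vectors of benefit parameter values.
#' @return An object of class \code{"pgg_phase"}: list with the grids, the
#'   class matrix (\code{beta} rows x \code{sigma} columns), a long-format
#'   data frame \code{table}, and the base parameters.
#' @examples
#' base <- pgg_params(delta_C = 0.05, delta_D = 0.05, kappa = 0.1,
#'                    K = 100, n = 5)
#' ph <- phase_diagram(base, beta_grid = c(0.25, 2, 4),
#'                     sigma_grid = c(0.5, 1, 2))
#' ph$classes
#' @export
phase_diagram <- function(params_base, beta_grid, sigma_grid) {
  stopifnot(inherits(params_base, "pgg_params"),
            length(beta_grid) >= 1, length(sigma_grid) >= 1)
  cls <- matrix(NA_character_, length(beta_grid), length(sigma_grid),
                dimnames = list(beta = signif(beta_grid, 6),
                                sigma = signif(sigma_grid, 6)))
  for (i in seq_along(beta_grid))
    for (j in seq_along(sigma_grid))
      cls[i, j] <- suppressWarnings(classify_dynamics(
        update_params(params_base, beta = beta_grid[i],
                      sigma = sigma_grid[j])))
  tab <- data.frame(beta = rep(beta_grid, times = length(sigma_grid)),
                    sigma = rep(sigma_grid, each = length(beta_grid)),
                    class = as.vector(cls))
  structure(list(beta = beta_grid, sigma = sigma_grid, classes = cls,
                 table = tab, params = params_base),
            class = "pgg_phase")
}

#' @export
print.pgg_phase <- function(x, ...) {
  cat(sprintf("Phase diagram: %d beta x %d sigma grid (n_C = %g, n_D = %g)\n",
              length(x$beta), length(x$sigma), x$params$n_C, x$params$n_D))
  print(table(class = x$table$class))
  invisible(x)
}

#' @export
plot.pgg_phase <- function(x, ...) {
  lv <- c("D_dominance", "bistability", "coexistence", "C_dominance",
          "extinction")
  z <- matrix(match(x$classes, lv), nrow(x$classes), ncol(x$classes))
  graphics::image(x$beta, x$sigma, z, col = grDevices::hcl.colors(5, "Zissou 1"),
                  zlim = c(1, 5), xlab = expression(beta),
                  ylab = expression(sigma), ...)
  invisible(x)
}

#' Write a phase diagram to CSV / JSON
#'
#' @param phase a [phase_diagram()] result.
#' @param csv_path long-format CSV (columns beta, sigma, class); optional.
#' @param json_path structured JSON report; optional.
#' @return \code{phase}, invisibly.
#' @export
write_phase_report <- function(phase, csv_path = NULL, json_path = NULL) {
  stopifnot(inherits(phase, "pgg_phase"))
  if (!is.null(csv_path))
    utils::write.csv(phase$table, csv_path, row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(list(beta = phase$beta, sigma = phase$sigma,
                              classes = phase$classes,
                              params = unclass(phase$params)),
                         json_path, auto_unbox = TRUE, digits = NA,
                         matrix = "rowmajor")
  invisible(phase)
}
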
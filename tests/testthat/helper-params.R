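# shared fixtures, built in code

# benefit parameters estimated for the sparse-nutrient condition, with the
# standard fixed rates (alpha = 1/day, kappa = 0.25 alpha, equal deaths)
serum5_params <- function(n = 22, K = 1000) {
  pgg_params(alpha_C = 1, alpha_D = 1, delta_C = 0.1, delta_D = 0.1,
             kappa = 0.25, K = K, beta = 3.67, sigma = 1.87, n = n)
}

# base used by the phase-diagram examples (alpha = 1, delta = 0.05,
# kappa = 0.1, K = 100)
phase_base <- function(...) {
  update_params(pgg_params(alpha_C = 1, alpha_D = 1, delta_C = 0.05,
                           delta_D = 0.05, kappa = 0.1, K = 100), ...)
}

# independent dense-grid root counter for the polymorphic condition
# delta_D r_C - delta_C r_D = 0 (counts strict sign changes only)
count_interior_roots <- function(params, grid_n = 2048) {
  g <- seq(1e-9, 1 - 1e-9, length.out = grid_n)
  r <- growth_rates(g, params, "both")
  f <- params$delta_D * r$r_C - params$delta_C * r$r_D
  sum(f[-length(f)] * f[-1] < 0)
}
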
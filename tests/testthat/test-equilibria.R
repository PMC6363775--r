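test_that("fitted sparse-nutrient parameters give the two printed equilibria", {
  eq <- interior_equilibria(serum5_params())
  expect_equal(nrow(eq), 2)
  expect_equal(eq$stability, c("unstable", "stable"))
  expect_equal(eq$y_star[1], 0.235, tolerance = 0.005)
  expect_equal(eq$y_star[2], 0.784, tolerance = 0.005)
  # equilibrium total population from the density-balance condition
  rC <- growth_rates(eq$y_star, serum5_params(), "C")
  expect_equal(eq$Y_star, 1000 * (1 - 0.1 / rC), tolerance = 1e-6)
})

test_that("no frequency dependence means no interior equilibrium", {
  eq <- interior_equilibria(pgg_params(beta = 0, sigma = 2, kappa = 0.3))
  expect_equal(nrow(eq), 0)
})

test_that("sigmoidal benefits admit at most two interior equilibria", {
  set.seed(41)
  counts <- integer(400)
  for (i in seq_along(counts)) {
    p <- pgg_params(alpha_C = 1, alpha_D = 1, delta_C = 0.1, delta_D = 0.1,
                    kappa = stats::runif(1, 0, 1),
                    beta = stats::runif(1, 0, 10),
                    sigma = stats::runif(1, 0, 10),
                    n = stats::runif(1, 2, 50), K = 1000)
    counts[i] <- nrow(interior_equilibria(p))
  }
  expect_true(all(counts <= 2))
  # both root counts are realized somewhere in the draw
  expect_true(any(counts == 2))
})

test_that("a two-root pair is always one unstable below one stable above", {
  set.seed(99)
  found <- 0
  while (found < 10) {
    p <- pgg_params(alpha_C = 1, alpha_D = 1, delta_C = 0.1, delta_D = 0.1,
                    kappa = stats::runif(1, 0.1, 0.8),
                    beta = stats::runif(1, 2, 8),
                    sigma = stats::runif(1, 0, 3),
                    n = stats::runif(1, 2, 30), K = 1000)
    eq <- interior_equilibria(p)
    if (nrow(eq) == 2 && !any(eq$degenerate)) {
      expect_equal(eq$stability, c("unstable", "stable"))
      found <- found + 1
    }
  }
})

test_that("uniformly steeper producer returns permit at most one root", {
  # when delta_D r_C'(y) > delta_C r_D'(y) everywhere the condition is
  # strictly increasing, so at most one interior equilibrium can exist
  set.seed(7)
  g <- seq(1e-6, 1 - 1e-6, length.out = 512)
  checked <- 0
  for (i in 1:400) {
    p <- pgg_params(alpha_C = stats::runif(1, 0.5, 2), alpha_D = 1,
                    delta_C = 0.1, delta_D = 0.1,
                    kappa = stats::runif(1, 0, 0.5),
                    beta = stats::runif(1, 0, 6),
                    sigma = stats::runif(1, 0, 6),
                    n = stats::runif(1, 2, 40), K = 1000)
    f <- p$delta_D * growth_rates(g, p, "C") -
      p$delta_C * growth_rates(g, p, "D")
    if (all(diff(f) > 0)) {
      checked <- checked + 1
      expect_lte(nrow(interior_equilibria(p)), 1)
    }
  }
  expect_gt(checked, 10)
})

test_that("with equal baseline rates the all-C state has the largest Y*", {
  for (pp in list(serum5_params(),
                  phase_base(sigma = 0.5, beta = 4, n = 10),
                  pgg_params(delta_C = 0.1, delta_D = 0.1, kappa = 0.5,
                             K = 1000, sigma = 2, beta = 5, n = 8))) {
    eq <- interior_equilibria(pp)
    bs <- boundary_states(pp)
    YC <- bs$Y_star[bs$kind == "all_C"]
    if (nrow(eq) && length(YC))
      expect_true(all(YC >= eq$Y_star - 1e-6))
  }
})

test_that("boundary states exist and are labeled per invasibility", {
  # producer-dominance example: all-C stable, all-D invadable
  bs <- boundary_states(phase_base(sigma = 2, beta = 2, n = 5))
  expect_equal(bs$stability[bs$kind == "all_C"], "stable")
  expect_equal(bs$stability[bs$kind == "all_D"], "saddle")
  expect_true(attr(bs, "C_invades_D")); expect_false(attr(bs, "D_invades_C"))
  # exorbitant cost: only the all-D state is evolutionarily stable
  bs2 <- boundary_states(phase_base(sigma = 2, beta = 2, n = 5, kappa = 50))
  expect_equal(bs2$stability[bs2$kind == "all_D"], "stable")
  expect_false("all_C" %in% bs2$kind)
  # neither type viable: extinction is the only stable state
  bs3 <- boundary_states(pgg_params(alpha_C = 0.4, alpha_D = 0.4,
                                    delta_C = 0.6, delta_D = 0.6,
                                    kappa = 0.2, beta = 0.1, sigma = 5))
  expect_equal(bs3$kind, "extinction")
  expect_equal(bs3$stability, "stable")
})

test_that("the four benchmark parameter sets classify as published", {
  expect_equal(classify_dynamics(phase_base(sigma = 2, beta = 2, n = 5)),
               "C_dominance")
  expect_equal(classify_dynamics(phase_base(sigma = 1, beta = 0.25, n = 5)),
               "D_dominance")
  expect_equal(classify_dynamics(phase_base(sigma = 1.5, beta = 1, n = 10)),
               "bistability")
  expect_equal(classify_dynamics(phase_base(sigma = 0.5, beta = 4, n = 10)),
               "coexistence")
  expect_equal(classify_dynamics(pgg_params(alpha_C = 0.3, alpha_D = 0.3,
                                            delta_C = 0.5, delta_D = 0.5,
                                            kappa = 0.1, beta = 0.1)),
               "extinction")
})

test_that("invasibility verdicts agree with direct invasion integration", {
  # oracle: drop one rare invader into the resident monomorphic
  # equilibrium and integrate; its abundance must grow iff the boundary
  # analysis says the state is invadable. Near-marginal draws (growth
  # factor within [1/2, 2] over the horizon) carry no sign information at
  # finite time and are not counted.
  set.seed(11)
  tested <- 0
  for (i in 1:40) {
    p <- pgg_params(alpha_C = 1, alpha_D = 1, delta_C = 0.05, delta_D = 0.05,
                    kappa = stats::runif(1, 0, 0.4),
                    beta = stats::runif(1, 0, 6),
                    sigma = stats::runif(1, 0, 4),
                    n = stats::runif(1, 2, 30), K = 100)
    bs <- boundary_states(p)
    if (p$alpha_D > p$delta_D) {
      YD <- p$K * (1 - p$delta_D / p$alpha_D)
      tr <- pgg_ode(p, c(1, YD), t_end = 600)
      g <- tr$x_C[nrow(tr)]
      if (g > 2 || g < 0.5) {
        tested <- tested + 1
        expect_equal(attr(bs, "C_invades_D"), g > 1)
      }
    }
    rC1 <- growth_rates(1, p, "C")
    if (rC1 > p$delta_C) {
      YC <- p$K * (1 - p$delta_C / rC1)
      tr <- pgg_ode(p, c(YC, 1), t_end = 600)
      g <- tr$x_D[nrow(tr)]
      if (g > 2 || g < 0.5) {
        tested <- tested + 1
        expect_equal(attr(bs, "D_invades_C"), g > 1)
      }
    }
  }
  expect_gt(tested, 30)
})

test_that("interior stability labels agree with perturbed integration", {
  set.seed(29)
  checked <- 0
  while (checked < 8) {
    p <- pgg_params(alpha_C = 1, alpha_D = 1, delta_C = 0.1, delta_D = 0.1,
                    kappa = stats::runif(1, 0.1, 0.8),
                    beta = stats::runif(1, 2, 8),
                    sigma = stats::runif(1, 0, 3),
                    n = stats::runif(1, 2, 30), K = 1000)
    eq <- interior_equilibria(p)
    if (nrow(eq) != 2 || any(eq$degenerate)) next
    for (k in 1:2) {
      y0 <- eq$y_star[k]; Y0 <- eq$Y_star[k]
      for (dy0 in c(-0.02, 0.02)) {
        y1 <- y0 + dy0
        if (y1 <= 0 || y1 >= 1) next
        tr <- pgg_ode(p, c(y1 * Y0, (1 - y1) * Y0), t_end = 2000)
        moved <- tr$y[nrow(tr)] - y0
        if (abs(moved) < abs(dy0) / 2 || abs(moved) > abs(dy0) * 2) {
          checked <- checked + 1
          expect_equal(eq$stability[k] == "stable",
                       abs(moved) < abs(dy0))
        }
      }
    }
  }
})

test_that("phase diagrams shrink the producer-favoring region as n grows", {
  bg <- seq(0.5, 5, by = 1.5); sg <- seq(0.5, 3, by = 1.25)
  ph5 <- phase_diagram(phase_base(n = 5), bg, sg)
  ph10 <- phase_diagram(phase_base(n = 10), bg, sg)
  favor5 <- ph5$classes %in% c("C_dominance", "coexistence")
  favor10 <- ph10$classes %in% c("C_dominance", "coexistence")
  # raising n never converts defector dominance into producer dominance
  expect_true(all(!(ph5$classes == "D_dominance" &
                      ph10$classes == "C_dominance")))
  expect_lte(sum(favor10), sum(favor5))
  # beta = 0 column is all defector dominance (alpha_C - kappa < alpha_D)
  ph0 <- phase_diagram(phase_base(n = 5), 0, sg)
  expect_true(all(ph0$classes == "D_dominance"))
  # single-point grid equals the scalar classifier
  ph1 <- phase_diagram(phase_base(n = 10), 4, 0.5)
  expect_equal(as.vector(ph1$classes),
               classify_dynamics(phase_base(n = 10, beta = 4, sigma = 0.5)))
})
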
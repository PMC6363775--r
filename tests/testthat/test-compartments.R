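test_that("mixing conserves both type totals exactly", {
  set.seed(8)
  st <- compartment_state(rep(10, 20), rep(15, 20))
  for (i in 1:50) {
    st <- mix_compartments(st)
    expect_equal(sum(st$C), 200)
    expect_equal(sum(st$D), 300)
    expect_true(all(st$C >= 0 & st$D >= 0))
  }
  # single compartment: identity
  one <- mix_compartments(compartment_state(7, 9))
  expect_equal(c(one$C, one$D), c(7, 9))
})

test_that("post-mix occupancies are multinomial-uniform", {
  set.seed(15)
  N <- 10; Y <- 120
  reps <- 2000
  counts <- matrix(0, reps, N)
  st0 <- compartment_state(c(Y, rep(0, N - 1)), rep(0, N))
  for (i in seq_len(reps)) counts[i, ] <- mix_compartments(st0)$C
  # mean occupancy Y/N within 3 SE
  se <- sqrt(Y * (1 / N) * (1 - 1 / N) / reps)
  expect_true(all(abs(colMeans(counts) - Y / N) < 3 * se))
  # chi-square goodness of fit of pooled compartment counts against
  # uniform assignment
  tot <- colSums(counts)
  chisq <- sum((tot - mean(tot))^2 / mean(tot))
  expect_gt(stats::pchisq(chisq, df = N - 1, lower.tail = FALSE), 0.05)
})

test_that("selection respects empty compartments and lone individuals", {
  p <- pgg_params(delta_C = 0.1, delta_D = 0.1, kappa = 0.5, K = 1000,
                  sigma = 2, beta = 5)
  st <- compartment_state(c(0, 1, 0), c(0, 0, 40))
  out <- select_within(st, p, T_s = 1, stochastic_round = FALSE)
  expect_equal(out$C[1] + out$D[1], 0)  # empty stays empty
  # a lone producer gets its full self-benefit: matches the scalar ODE
  # with N_C = 1 exactly (occupancy ~1 over a short step)
  expect_gt(out$C[2], 1)
  # a defector-only compartment has no benefit: bare logistic growth
  rdir <- (p$alpha_D * 1 - p$delta_D)  # N_D = 0 benefit factor is 1
  expect_equal(out$D[3] > 40, rdir * (1 - 41 / 1000) > 0)
})

test_that("stochastic rounding preserves totals in expectation", {
  set.seed(4)
  p <- pgg_params(delta_C = 0.1, delta_D = 0.1, kappa = 0.5, K = 1000,
                  sigma = 3, beta = 2)
  st <- compartment_state(rep(3, 30), rep(4, 30))
  outs <- replicate(300, sum(select_within(st, p, T_s = 0.5)$C))
  ref <- sum(select_within(st, p, T_s = 0.5, stochastic_round = FALSE)$C)
  expect_lt(abs(mean(outs) - ref), 3 * stats::sd(outs) / sqrt(300))
  # integers out
  expect_true(all(outs == round(outs)))
})

test_that("a single compartment reproduces the well-mixed large-n verdict", {
  # with one compartment the occupancy is the whole population, so the
  # effective neighborhood is huge and defectors must win
  p <- pgg_params(delta_C = 0.1, delta_D = 0.1, kappa = 0.5, K = 1000,
                  sigma = 2, beta = 5)
  run <- run_mixing_cycles(p, N = 1, init_totals = c(50, 50),
                           n_cycles = 60, seed = 2)
  expect_equal(run$label, "all_D")
  tr <- pgg_ode(update_params(p, n = 900), c(50, 50), t_end = 600)
  expect_lt(tr$y[nrow(tr)], 0.01)
})

test_that("many compartments flip the state to all-C; few keep all-D", {
  sc <- pgg_scenario("mixing_transcritical")
  lo <- run_mixing_cycles(sc$params, N = 5, sc$init, T_s = 10,
                          n_cycles = 80, seed = 3)
  hi <- run_mixing_cycles(sc$params, N = 300, sc$init, T_s = 10,
                          n_cycles = 80, seed = 3)
  expect_equal(lo$label, "all_D")
  expect_equal(hi$label, "all_C")
})

test_that("compartment sweeps record both directions and serialize", {
  sc <- pgg_scenario("mixing_transcritical")
  sw <- sweep_compartments(sc$params, c(5, 60, 300), sc$init,
                           reinitialize = FALSE, n_cycles = 40, seed = 5)
  expect_setequal(unique(sw$direction), c("forward", "backward"))
  expect_equal(nrow(sw), 6)
  csv <- tempfile(fileext = ".csv")
  write_sweep_report(sw, csv)
  expect_equal(nrow(utils::read.csv(csv)), 6)
  cfg <- jsonlite::read_json(paste0(csv, ".json"), simplifyVector = TRUE)
  expect_false(cfg$reinitialize)
})

test_that("mean-field N_crit matches a brute-force scan of both bounds", {
  p <- pgg_params(delta_C = 0.1, delta_D = 0.1, kappa = 0.5, K = 1000,
                  sigma = 3, beta = 2)
  got <- ncrit_meanfield(p)
  # independent scan: rare C invades all-D AND rare D fails against all-C
  YD <- 1000 * (1 - 0.1 / 1)
  rC1 <- (1 + exp(3)) / (1 + exp(3 - 2)) - 0.5
  YC <- 1000 * (1 - 0.1 / rC1)
  ok <- vapply(1:1000, function(N) {
    n_inv <- max(YD / N, 1)
    rC0 <- (1 + exp(3)) / (1 + exp(3 - 2 / n_inv)) - 0.5
    n_res <- max(YC / N, 1)
    rD1 <- (1 + exp(3)) / (1 + exp(3 - 2 * (n_res - 1) / n_res))
    (rC0 > 1) && (rD1 < rC1)
  }, logical(1))
  expect_equal(got, which(ok)[1])
  # no benefit: cooperators can never invade
  expect_true(is.na(ncrit_meanfield(update_params(p, beta = 0))))
  expect_error(ncrit_meanfield(pgg_params(alpha_D = 0.5, delta_D = 0.6)),
               "not viable")
})

test_that("mean-field N_crit tracks the simulated trend over beta", {
  base <- pgg_params(delta_C = 0.1, delta_D = 0.1, kappa = 0.5, K = 1000,
                     sigma = 1)
  betas <- c(2, 3, 4)
  nc_num <- nc_mf <- numeric(3)
  for (i in seq_along(betas)) {
    p <- update_params(base, beta = betas[i])
    nc_mf[i] <- ncrit_meanfield(p)
    est <- ncrit_numeric(p, N_range = c(20, 500), init_totals = c(50, 50),
                         n_cycles = 60, replicates = 3, seed = 10 + i)
    nc_num[i] <- est$N_crit
  }
  expect_true(all(is.finite(nc_num)))
  expect_true(all(is.finite(nc_mf)))
  # most pairwise orderings agree between the two estimators
  pairs <- utils::combn(3, 2)
  concord <- vapply(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    sign(nc_mf[j] - nc_mf[i]) == sign(nc_num[j] - nc_num[i])
  }, logical(1))
  expect_gte(sum(concord), 2)
  # the non-monotonic tail: very strong frequency dependence needs *more*
  # compartments again in both estimators
  p6 <- update_params(base, beta = 6)
  expect_gt(ncrit_meanfield(p6), nc_mf[2])
  est6 <- ncrit_numeric(p6, N_range = c(20, 500), init_totals = c(50, 50),
                        n_cycles = 60, replicates = 3, seed = 44)
  expect_true(is.na(est6$N_crit) || est6$N_crit > nc_num[2])
  # a transition out of range is reported as not-found, not as a number
  far <- update_params(base, beta = 1.2)
  est_far <- ncrit_numeric(far, N_range = c(2, 100), init_totals = c(50, 50),
                           n_cycles = 40, replicates = 3, seed = 4)
  expect_true(is.na(est_far$N_crit))
})
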
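test_that("predicted frequency change is anchored by the rest points", {
  expect_equal(predict_delta_y(3.67, 1.87, 22, c(0, 1), 4), c(0, 0))
  # the stable equilibrium is a rest point of the reduced dynamics
  eq <- interior_equilibria(serum5_params())
  dy <- predict_delta_y(3.67, 1.87, 22, eq$y_star[eq$stability == "stable"], 4)
  expect_lt(abs(dy), 1e-6)
  # without benefit, costly producers always lose ground
  expect_true(all(predict_delta_y(0, 1, 22, seq(0.1, 0.9, 0.2), 4) < 0))
})

test_that("noiseless data are fitted back to the generating truth", {
  d <- simulate_frequency_change(freq_change_design(noise_sd = 0), seed = 1)
  f <- pgg_fit(d, n = 22)
  expect_equal(unname(coef(f)), c(3.67, 1.87), tolerance = 1e-3)
  expect_lt(f$sigma_noise, 1e-4)
  expect_false(any(f$boundary))
  # fitted values reproduce the observations
  expect_lt(max(abs(residuals(f))), 1e-6)
})

test_that("the optimum beats a fine grid of the profiled likelihood", {
  d <- simulate_frequency_change(
    freq_change_design(y0_levels = seq(0.15, 0.85, by = 0.14),
                       replicates = 2, noise_sd = 0.02), seed = 3)
  f <- pgg_fit(d, n = 22)
  cf <- coef(f)
  grid <- expand.grid(beta = seq(max(0, cf[1] - 0.5), cf[1] + 0.5, by = 0.05),
                      sigma = seq(max(0, cf[2] - 0.5), cf[2] + 0.5, by = 0.05))
  rss_grid <- vapply(seq_len(nrow(grid)), function(i) {
    pred <- predict_delta_y(grid$beta[i], grid$sigma[i], 22, d$y0, 4)
    sum((d$delta_y - pred)^2)
  }, numeric(1))
  expect_lte(f$rss, min(rss_grid) + 1e-10)
})

test_that("local refinement never worsens the objective of its start", {
  d <- simulate_frequency_change(freq_change_design(), seed = 11)
  f <- pgg_fit(d, n = 22)
  start_rss <- vapply(seq_len(nrow(f$convergence)), function(i) {
    pred <- predict_delta_y(f$convergence$start_beta[i],
                            f$convergence$start_sigma[i], 22, d$y0, 4)
    sum((d$delta_y - pred)^2)
  }, numeric(1))
  expect_true(all(f$convergence$rss <= start_rss + 1e-12))
})

test_that("estimates pinned at a search bound are flagged", {
  d <- simulate_frequency_change(freq_change_design(noise_sd = 0), seed = 1)
  f <- pgg_fit(d, n = 22, bounds = list(beta = c(0, 3), sigma = c(0, 10)))
  expect_true(f$boundary[["beta"]])
})

test_that("degenerate designs are rejected", {
  expect_error(pgg_fit(data.frame(y0 = c(0.2, 0.2, 0.5),
                                  delta_y = c(0, 0, 0.1)), n = 22),
               "3 distinct")
  expect_error(pgg_fit(data.frame(y0 = c(0.2, 0.5), delta_y = c(2, 0)),
                       n = 22), "\\[0, 1\\]")
})

test_that("noisy data recover the truth within reasonable error", {
  set.seed(1)
  hits <- 0
  for (s in 1:10) {
    d <- simulate_frequency_change(freq_change_design(), seed = 800 + s)
    cf <- coef(pgg_fit(d, n = 22))
    hits <- hits + (abs(cf[["beta"]] - 3.67) / 3.67 < 0.15 &&
                      abs(cf[["sigma"]] - 1.87) / 1.87 < 0.15)
  }
  expect_gte(hits, 8)
})

test_that("estimator error shrinks as replication grows", {
  err_for <- function(reps, seeds) {
    mean(vapply(seeds, function(s) {
      d <- simulate_frequency_change(
        freq_change_design(replicates = reps), seed = s)
      cf <- coef(pgg_fit(d, n = 22))
      abs(cf[["beta"]] - 3.67) / 3.67 + abs(cf[["sigma"]] - 1.87) / 1.87
    }, numeric(1)))
  }
  seeds <- 300 + 1:10
  expect_gt(err_for(3, seeds), err_for(30, seeds))
})

test_that("fits across the n-range aggregate into stable medians", {
  d <- simulate_frequency_change(freq_change_design(noise_sd = 0), seed = 1)
  pr <- fit_across_n(d, n_values = c(16, 22, 28))
  expect_equal(nrow(pr$fits), 3)
  expect_true(all(pr$fits$converged))
  # the generating n = 22 sits in the range; its fit is exact and the
  # medians stay near the truth
  expect_equal(pr$medians$beta_median, 3.67, tolerance = 0.25)
  expect_equal(pr$medians$sigma_median, 1.87, tolerance = 0.25)
  # the conventional full range is centered on n = 22
  expect_equal(mean(4:40), 22)
  csv <- tempfile(fileext = ".csv"); js <- tempfile(fileext = ".json")
  write_fit_report(pr, csv, js)
  expect_equal(nrow(utils::read.csv(csv)), 3)
  expect_equal(jsonlite::read_json(js,
                 simplifyVector = TRUE)$medians$n_failed, 0)
})

test_that("per-record neighborhood heterogeneity still brackets the truth", {
  d <- simulate_frequency_change(
    freq_change_design(n_truth = "uniform"), seed = 17)
  pr <- fit_across_n(d, n_values = seq(4, 40, by = 6))
  expect_equal(pr$medians$beta_median, 3.67, tolerance = 0.2 * 3.67)
  expect_equal(pr$medians$sigma_median, 1.87, tolerance = 0.2 * 1.87)
})

test_that("fitted medians imply the published equilibrium pair", {
  eq <- equilibria_from_fit(3.67, 1.87, n_ref = 22)
  expect_equal(nrow(eq), 2)
  expect_equal(eq$y_star[eq$stability == "unstable"], 0.235,
               tolerance = 0.005 / 0.235)
  expect_equal(eq$y_star[eq$stability == "stable"], 0.784,
               tolerance = 0.005 / 0.784)
  # no frequency dependence, no interior equilibria
  expect_equal(nrow(equilibria_from_fit(0, 1.87, 22)), 0)
})

test_that("model methods behave like a standard fitted-model object", {
  d <- simulate_frequency_change(freq_change_design(), seed = 23)
  f <- pgg_fit(d, n = 22)
  expect_named(coef(f), c("beta", "sigma"))
  expect_equal(length(residuals(f)), nrow(d))
  pred <- predict(f, newdata = data.frame(y0 = c(0.3, 0.6)))
  expect_equal(length(pred), 2)
  sims <- simulate(f, nsim = 3, seed = 1)
  expect_equal(dim(sims), c(nrow(d), 3))
  s <- summary(f)
  expect_s3_class(s$equilibria, "pgg_equilibria")
  expect_output(print(f), "beta")
})
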
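test_that("candidate enumeration respects the collinearity exclusion", {
  full <- enumerate_models()
  expect_length(full, 36)
  labels <- vapply(full, function(s) format(s), character(1))
  expect_false(anyDuplicated(labels) > 0)
  shares_pair <- vapply(full, function(s) {
    all(c("size", "infection") %in% s$psi_terms) ||
      all(c("size", "infection") %in% s$p_terms)
  }, logical(1))
  expect_false(any(shares_pair))

  expect_length(enumerate_models(exclusion = list()), 64)
  expect_length(enumerate_models("size", exclusion = list()), 4)
  expect_error(enumerate_models("size", exclusion = list(c("size", "height"))),
               "unknown covariate")
  expect_error(enumerate_models(c("size", "size")), "unique")
})

test_that("AICc follows the small-sample closed form", {
  expect_equal(aicc(10, 0, 50), 10)
  expect_equal(aicc(100, 3, 20), 100 + 6 + 24 / 16)
  expect_error(aicc(100, 6, 7), "domain error")
  # strictly decreasing in n at fixed -2l and K, bounded below by AIC
  ns <- c(10, 30, 100, 1000)
  vals <- aicc(100, 4, ns)
  expect_true(all(diff(vals) < 0))
  expect_true(all(vals > 100 + 8))
})

test_that("Akaike weights follow the exponential form and its invariances", {
  expect_equal(akaike_weights(c(100, 100)), c(0.5, 0.5))
  w <- akaike_weights(c(100, 102))
  expect_equal(w, c(1, exp(-1)) / (1 + exp(-1)), tolerance = 1e-12)
  expect_equal(round(w, 4), c(0.7311, 0.2689))
  # shift invariance
  x <- c(312.4, 310.1, 315.9)
  expect_equal(akaike_weights(x), akaike_weights(x + 57.3))
  expect_equal(sum(akaike_weights(rnorm(10, 300, 5))), 1, tolerance = 1e-10)
  expect_error(akaike_weights(c(1, NaN)), "domain error")
})

test_that("a single-model selection gets all the weight", {
  ds <- simulate_dataset(sim_config(seed = 6))
  sel <- run_selection(ds, list(occu_spec()))
  expect_equal(nrow(sel$table), 1)
  expect_equal(sel$table$weight, 1)
  expect_equal(sel$table$delta_aicc, 0)
})

test_that("selection tables are sorted with coherent deltas and weights", {
  ds <- simulate_dataset(sim_config(seed = 6))
  sel <- run_selection(ds)
  tab <- sel$table
  expect_equal(nrow(tab), 36)
  expect_equal(tab$delta_aicc[1], 0)
  expect_true(all(diff(tab$aicc) >= 0))
  expect_true(all(diff(tab$delta_aicc) >= 0))
  expect_equal(sum(tab$weight[tab$converged]), 1, tolerance = 1e-10)
  # fits travel with their rows
  expect_equal(vapply(sel$fits, `[[`, numeric(1), "aicc"), tab$aicc)
  # AICc identity on every row
  expect_equal(tab$aicc,
               tab$neg2_loglik + 2 * tab$K + 2 * tab$K * (tab$K + 1) /
                 (ds$n_sites - tab$K - 1))
})

test_that("model selection identifies a strong simulated occupancy covariate", {
  # one informative replicate at large n: psi depends only on neighbor
  cfg <- sim_config(populations = list(c(1000, 3)),
                    beta_psi = c(-0.5, 0, 1.5, 0),
                    beta_p = c(1.3, 0, 0, 0), seed = 91)
  ds <- simulate_dataset(cfg)
  sel <- run_selection(ds)
  expect_true("neighbor" %in% best_model(sel)$spec$psi_terms)
})

test_that("model-averaged predictions are convex combinations of member predictions", {
  ds <- simulate_dataset(sim_config(seed = 36))
  sel <- run_selection(ds, list(occu_spec(), occu_spec("neighbor", "neighbor"),
                                occu_spec("size", "size")))
  grid <- expand.grid(size = c(2, 5, 9), neighbor = c(0, 1), infection = 0)
  avg <- model_average_predictions(sel, grid)
  members <- vapply(sel$fits, function(f) predict(f, grid)$psi,
                    numeric(nrow(grid)))
  expect_true(all(avg$psi >= apply(members, 1, min) - 1e-12))
  expect_true(all(avg$psi <= apply(members, 1, max) + 1e-12))
  # a one-model table averages to itself
  sel1 <- run_selection(ds, list(occu_spec("size", "neighbor")))
  avg1 <- model_average_predictions(sel1, grid)
  expect_equal(avg1$psi, predict(sel1$fits[[1]], grid)$psi)
  # delta2 averaging restricts the set but stays a convex combination
  avg2 <- model_average_predictions(sel, grid, avg_set = "delta2")
  expect_true(all(avg2$psi >= apply(members, 1, min) - 1e-12))
})
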
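test_that("single-history probabilities match hand calculation", {
  expect_equal(history_probability(c(0, 1, 0), psi = 1, p = 0.5), 0.125)
  expect_equal(history_probability(c(0, 0, 0), psi = 0.3, p = 0.5),
               0.3 * 0.125 + 0.7)
  expect_equal(history_probability(c(1, NA, 0), psi = 0.6, p = 0.4),
               0.6 * 0.4 * 0.6)
  # per-occasion detection probabilities
  expect_equal(history_probability(c(1, 0, 1), psi = 0.8, p = c(0.2, 0.5, 0.9)),
               0.8 * 0.2 * 0.5 * 0.9)
  expect_error(history_probability(c(0, 1), psi = 1.2, p = 0.5), "domain error")
  expect_error(history_probability(c(NA, NA), psi = 0.5, p = 0.5),
               "no surveyed occasion")
})

test_that("history probabilities sum to one over all possible histories", {
  for (T in 1:3) {
    histories <- as.matrix(expand.grid(rep(list(0:1), T)))
    for (psi in c(0, 0.2, 0.5, 0.8, 1)) {
      for (p in c(0, 0.3, 0.7, 1)) {
        total <- sum(apply(histories, 1, history_probability, psi = psi, p = p))
        expect_equal(total, 1, tolerance = 1e-12)
      }
    }
  }
})

test_that("the likelihood equals explicit latent-state enumeration", {
  set.seed(401)
  spec <- occu_spec(c("size", "neighbor"), c("size", "neighbor"))
  for (rep in 1:25) {
    ds <- random_dataset(n = 20)
    bp <- rnorm(3, 0, 0.5)
    bd <- rnorm(3, 0, 0.5)
    expect_equal(occu_nll(ds, spec, bp, bd), oracle_nll(ds, spec, bp, bd),
                 tolerance = 1e-10)
  }
})

test_that("the analytic gradient matches numerical differentiation", {
  set.seed(402)
  ds <- random_dataset(n = 30)
  spec <- occu_spec(c("size", "neighbor"), c("neighbor", "infection"))
  xpsi <- occuseed:::design_matrix(ds$records, spec$psi_terms)
  xp <- occuseed:::design_matrix(ds$records, spec$p_terms)
  cnt <- occuseed:::history_counts(ds)
  theta <- rnorm(6, 0, 0.3)
  g <- occuseed:::nll_grad(theta, xpsi, xp, cnt$d, cnt$q)
  g_num <- pracma::grad(function(th)
    occuseed:::nll_theta(th, xpsi, xp, cnt$d, cnt$q), theta)
  expect_equal(g, g_num, tolerance = 1e-6)
})

test_that("a single intercept-only host reproduces the closed-form likelihood", {
  ds <- toy_dataset("010")
  spec <- occu_spec()
  expect_equal(occu_nll(ds, spec, beta_psi = 50, beta_p = 0), -log(0.125),
               tolerance = 1e-8)
  # p = 1 with a non-detection after a detection has probability zero
  ds2 <- toy_dataset("010")
  expect_equal(occu_nll(ds2, spec, beta_psi = 0, beta_p = 1000), Inf)
  expect_error(occu_nll(ds, spec, beta_psi = c(0, 0), beta_p = 0), "shape error")
})

test_that("maximum likelihood recovers the intercept-only closed form", {
  # intercept-only psi(.)p(.): the MLE solves a two-parameter problem whose
  # likelihood we can maximize on a fine grid as an independent check
  ds <- simulate_dataset(sim_config(seed = 55))
  fit <- fit_occu(ds, occu_spec())
  expect_true(fit$converged)
  # independent grid search over (psi, p) using only the per-host
  # detection/non-detection counts
  d <- rowSums(ds$y == 1, na.rm = TRUE)
  q <- rowSums(ds$y == 0, na.rm = TRUE)
  grid_nll <- function(psi, p) {
    det <- d > 0
    -(sum(log(psi) + d[det] * log(p) + q[det] * log(1 - p)) +
        sum(log(psi * (1 - p)^q[!det] + (1 - psi))))
  }
  grid <- expand.grid(psi = seq(0.5, 0.998, by = 0.002),
                      p = seq(0.5, 0.998, by = 0.002))
  nll_grid <- mapply(grid_nll, grid$psi, grid$p)
  best <- grid[which.min(nll_grid), ]
  expect_equal(plogis(fit$beta_psi[[1]]), best$psi, tolerance = 4e-3)
  expect_equal(plogis(fit$beta_p[[1]]), best$p, tolerance = 4e-3)
  expect_lte(fit$neg2_loglik, 2 * min(nll_grid) + 1e-6)
})

test_that("the AICc identity holds for fitted models", {
  ds <- simulate_dataset(sim_config(seed = 19))
  for (spec in list(occu_spec(), occu_spec("size", "neighbor"))) {
    fit <- fit_occu(ds, spec)
    K <- length(fit$beta_psi) + length(fit$beta_p)
    expect_equal(fit$K, K)
    expect_equal(fit$aicc,
                 fit$neg2_loglik + 2 * K + 2 * K * (K + 1) / (fit$n_sites - K - 1))
    expect_equal(fit$vcov, t(fit$vcov))
    expect_true(all(diag(fit$vcov) >= 0))
  }
})

test_that("all-detected data drives estimates to the boundary without error", {
  ds <- toy_dataset(rep("111", 30), size = runif(30, 1, 10))
  fit <- fit_occu(ds, occu_spec())
  expect_gt(plogis(fit$beta_psi[[1]]), 0.97)
  expect_gt(plogis(fit$beta_p[[1]]), 0.97)
  expect_false(fit$converged)
})

test_that("the corrected intercept-only occupancy never falls below naive occupancy", {
  for (seed in c(3, 14, 27)) {
    ds <- simulate_dataset(sim_config(seed = seed))
    fit <- fit_occu(ds, occu_spec())
    naive <- mean(rowSums(ds$y == 1, na.rm = TRUE) > 0)
    expect_gte(plogis(fit$beta_psi[[1]]), naive - 1e-8)
  }
})

test_that("predictions back-transform Wald intervals into [0, 1]", {
  ds <- simulate_dataset(sim_config(seed = 44))
  fit <- fit_occu(ds, occu_spec(c("size", "neighbor"), c("size", "neighbor")))
  grid <- expand.grid(size = c(1, 5, 12), neighbor = c(0, 1))
  pred <- predict(fit, grid)
  expect_true(all(pred$psi_lower <= pred$psi & pred$psi <= pred$psi_upper))
  expect_true(all(pred$p_lower <= pred$p & pred$p <= pred$p_upper))
  expect_true(all(pred$psi_lower >= 0 & pred$psi_upper <= 1))
  expect_true(all(pred$p_lower >= 0 & pred$p_upper <= 1))
  expect_error(predict(fit, data.frame(size = 5)), "neighbor")
})

test_that("an intercept estimate of zero predicts one half", {
  fit <- structure(list(
    spec = occu_spec(), beta_psi = c(0), beta_p = c(0),
    vcov = matrix(0, 2, 2), neg2_loglik = 0, K = 2L, aicc = 0,
    converged = TRUE, n_sites = 10, p_fixed = NULL), class = "occu_fit")
  pred <- predict(fit, data.frame(size = 1))
  expect_equal(pred$psi, 0.5)
  expect_equal(pred$p, 0.5)
  # zero variance collapses the interval onto the point estimate
  expect_equal(pred$psi_lower, 0.5)
  expect_equal(pred$psi_upper, 0.5)
})

test_that("model specs enforce the size/infection exclusion unless disabled", {
  expect_error(occu_spec(c("size", "infection")), "collinear")
  expect_silent(occu_spec(c("size", "infection"), allow_collinear = TRUE))
  expect_error(occu_spec("height"), "unknown covariate")
  expect_equal(format(occu_spec(c("size", "neighbor"), character())),
               "psi(size+neighbor) p(.)")
})
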
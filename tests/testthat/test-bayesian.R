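# MAP objective and estimation.

test_that("objective hand values: empty, data term, pure prior", {
  m <- toy_1cpt(CL = 5, V = 20, omega_cl = 0.09, sigma_add = 1,
                sigma_prop = 0)
  cov <- ref_cov_neutral()
  r <- regimen(500, 6, 1, n_doses = 2)
  # eta = 0, no observations: prior quadratic form is 0, empty sum
  expect_identical(neg2_log_posterior(0, m, cov, r, observations(numeric(0),
                                                                 numeric(0))),
                   0)
  # one observation 2 mg/L above an additive-only prediction, sigma_add = 1:
  # (12 - 10)^2 / 1 + log 1 = 4, prior 0 at eta = 0
  t_obs <- 3
  p <- individualize(m, cov, 0)
  pred <- predict_concentration(p, m, r, t_obs)
  obs <- observations(t_obs, pred + 2)
  expect_equal(neg2_log_posterior(0, m, cov, r, obs), 4, tolerance = 1e-12)
  # pure prior: omega = 0.09, eta = 0.3 -> 0.3^2 / 0.09 = 1
  expect_equal(neg2_log_posterior(0.3, m, cov, r,
                                  observations(numeric(0), numeric(0))),
               1, tolerance = 1e-12)
})

test_that("objective decomposes into prior plus additive data terms", {
  m <- toy_1cpt(sigma_add = 0.8, sigma_prop = 0.1)
  cov <- ref_cov_neutral()
  r <- regimen(400, 8, 1, n_doses = 3)
  eta <- 0.21
  o1 <- observations(5, 9.2)
  o2 <- observations(16, 6.4)
  o12 <- observations(c(5, 16), c(9.2, 6.4))
  empty <- observations(numeric(0), numeric(0))
  prior <- neg2_log_posterior(eta, m, cov, r, empty)
  d1 <- neg2_log_posterior(eta, m, cov, r, o1) - prior
  d2 <- neg2_log_posterior(eta, m, cov, r, o2) - prior
  expect_equal(neg2_log_posterior(eta, m, cov, r, o12), prior + d1 + d2,
               tolerance = 1e-12)
})

test_that("degenerate error models and singular priors are rejected", {
  expect_error(residual_error(0, 0), "sigma_add \\+ sigma_prop")
  # proportional-only error with zero predicted concentration
  m <- toy_1cpt(sigma_add = 0, sigma_prop = 0.2)
  r <- regimen(500, 6, 1, n_doses = 2, start_time_h = 5)
  obs <- observations(1, 4)  # before the first dose: prediction 0
  expect_error(neg2_log_posterior(0, m, ref_cov_neutral(), r, obs),
               "variance undefined")
  ms <- toy_1cpt(omega_cl = 0)
  expect_error(neg2_log_posterior(0, ms, ref_cov_neutral(), r, obs),
               "singular")
})

test_that("empty observations return the prior mode eta = 0 exactly", {
  m <- pk_model_vancomycin()
  fit <- map_fit(m, ref_cov(), regimen(210, 6, 1, 4))
  expect_identical(as.numeric(fit$eta_map), c(0, 0))
  expect_identical(unlist(fit$params$values), unlist(m$typical_values))
  expect_equal(fit$n_obs_used, 0L)
})

test_that("an observation matching the prior prediction keeps eta at 0", {
  m <- toy_1cpt(sigma_add = 1, sigma_prop = 0)
  cov <- ref_cov_neutral()
  r <- regimen(500, 6, 1, n_doses = 3)
  pred <- predict_concentration(individualize(m, cov, 0), m, r, 17)
  fit <- map_fit(m, cov, r, observations(17, pred))
  expect_lt(abs(fit$eta_map), 1e-6)
})

test_that("map_fit matches a fine grid search on 1-D toy problems", {
  set.seed(5)
  m <- toy_1cpt(CL = 4, V = 18, omega_cl = 0.2, sigma_add = 0.6,
                sigma_prop = 0.1)
  cov <- ref_cov_neutral()
  r <- regimen(450, 8, 1, n_doses = 3)
  for (rep in 1:5) {
    eta_true <- rnorm(1, 0, sqrt(0.2))
    pred <- predict_concentration(individualize(m, cov, eta_true), m, r, 23)
    y <- max(pred + rnorm(1, 0, 0.6), 0.1)
    obs <- observations(23, y)
    fit <- map_fit(m, cov, r, obs)
    grid <- seq(-1.5, 1.5, by = 1e-4)
    ovals <- vapply(grid, neg2_log_posterior, numeric(1), m, cov, r, obs)
    eta_grid <- grid[which.min(ovals)]
    expect_lt(abs(fit$eta_map - eta_grid), 2e-4)
    expect_lte(fit$objective_value,
               neg2_log_posterior(0, m, cov, r, obs) + 1e-12)
    expect_true(fit$converged)
  }
})

test_that("infinitely noisy data carries no information", {
  m <- toy_1cpt(sigma_add = 1e6, sigma_prop = 0)
  cov <- ref_cov_neutral()
  r <- regimen(500, 6, 1, n_doses = 3)
  fit <- map_fit(m, cov, r, observations(c(5, 17), c(30, 1)))
  prior <- predict_concentration(individualize(m, cov, 0), m, r, c(5, 17))
  post <- predict(fit, c(5, 17), mode = "a_posteriori")
  expect_lt(max(abs(post - prior)), 1e-6)
})

test_that("vanishing residual noise drives the fit through the observation", {
  m <- toy_1cpt(CL = 4, V = 18, omega_cl = 0.5, sigma_add = 1e-4,
                sigma_prop = 0)
  cov <- ref_cov_neutral()
  r <- regimen(450, 8, 1, n_doses = 3)
  truth <- predict_concentration(individualize(m, cov, 0.35), m, r, 23)
  fit <- map_fit(m, cov, r, observations(23, truth))
  expect_lt(abs(predict(fit, 23) - truth), 1e-3)
})

test_that("shrinkage: as omega shrinks the MAP estimate goes to zero", {
  cov <- ref_cov_neutral()
  r <- regimen(500, 6, 1, n_doses = 3)
  obs <- observations(17, 25)  # far from the prior prediction
  eta_prev <- Inf
  for (w in c(0.5, 0.05, 0.005, 1e-6)) {
    m <- toy_1cpt(omega_cl = w)
    fit <- map_fit(m, cov, r, obs)
    expect_lt(abs(fit$eta_map), abs(eta_prev) + 1e-12)
    eta_prev <- fit$eta_map
  }
  expect_lt(abs(eta_prev), 1e-2)
  # with tiny omega the individualized parameters return to typical values
  m <- toy_1cpt(omega_cl = 1e-8)
  fit <- map_fit(m, cov, r, obs)
  expect_equal(fit$params$values$CL, m$typical_values$CL, tolerance = 1e-3)
})

test_that("below-LOQ observations are excluded by default, loq2 opts in", {
  m <- toy_1cpt()
  cov <- ref_cov_neutral()
  r <- regimen(500, 6, 1, n_doses = 3)
  blq <- observations(17, 0, below_loq = TRUE)
  fit <- map_fit(m, cov, r, blq)
  expect_identical(as.numeric(fit$eta_map), 0)
  expect_equal(fit$n_obs_used, 0L)
  fit2 <- map_fit(m, cov, r, blq, map_control(blq = "loq2", loq = 0.5))
  expect_equal(fit2$n_obs_used, 1L)
  expect_false(fit2$eta_map == 0)
})

test_that("a posteriori beats a priori at a held-out time in most replicates", {
  set.seed(77)
  m <- toy_1cpt(CL = 4, V = 18, omega_cl = 0.2, sigma_add = 0.5,
                sigma_prop = 0.1)
  cov <- ref_cov_neutral()
  r <- regimen(450, 8, 1, n_doses = 4)
  t_fit <- 23; t_holdout <- 31
  prior_params <- individualize(m, cov, 0)
  wins <- 0; n_rep <- 500
  for (i in seq_len(n_rep)) {
    eta_true <- rnorm(1, 0, sqrt(0.2))
    true_params <- individualize(m, cov, eta_true)
    pred <- predict_concentration(true_params, m, r, c(t_fit, t_holdout))
    s <- sqrt(0.5^2 + (0.1 * pred[1])^2)
    y <- max(pred[1] + rnorm(1, 0, s), 0.01)
    fit <- map_fit(m, cov, r, observations(t_fit, y))
    e_post <- abs(predict(fit, t_holdout) - pred[2])
    e_prior <- abs(predict_concentration(prior_params, m, r, t_holdout) -
                     pred[2])
    wins <- wins + (e_post <= e_prior)
  }
  expect_gte(wins / n_rep, 0.80)
})

test_that("a posteriori prediction without observations is a contract error", {
  m <- toy_1cpt()
  fit <- map_fit(m, ref_cov_neutral(), regimen(500, 6, 1, 3))
  expect_error(predict(fit, 5, mode = "a_posteriori"), "requires observations")
  expect_equal(predict(fit, 5, mode = "a_priori"),
               predict_concentration(individualize(m, ref_cov_neutral(), 0),
                                     m, regimen(500, 6, 1, 3), 5))
})
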
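# Psychometric function and the grid-Bayes fitting machinery.

test_that("psi has the stated midpoint, asymptotes and closed-form values", {
  expect_equal(psi(0.3, alpha = 0.3, beta = 4, lambda = 0), 0.5)
  expect_equal(psi(0.3 + 1 / 4, alpha = 0.3, beta = 4, lambda = 0),
               pnorm(1), tolerance = 1e-12)
  expect_equal(psi(-1e9, alpha = 0, beta = 2, lambda = 0.07), 0.07)
  expect_equal(psi(1e9, alpha = 0, beta = 2, lambda = 0.07), 1)
  expect_equal(psi(-1e9, 0, 2, 0.07, lapse_convention = "guess"), 0.035)
  expect_equal(psi(1e9, 0, 2, 0.07, lapse_convention = "guess"), 0.965)
  expect_equal(psi(0.2, alpha = 0.2, beta = 3, lambda = 0.06),
               0.06 + 0.94 * 0.5)
  x <- seq(-1, 1, by = 0.05)
  expect_true(all(diff(psi(x, 0, 5, 0.1)) >= 0))
})

test_that("slope recovery is accurate and lambda stays in its prior range", {
  set.seed(301)
  errs <- replicate(100, {
    cc <- sim_counts(sigma = 1 / (5 * sqrt(2)), lambda = 0.02)
    ft <- fit_condition(cc, lambda = 0.02)
    abs(ft$beta - 5) / 5
  })
  expect_lt(median(errs), 0.20)
  # lambda estimates always live in [0, 0.2], even for lapse-heavy data
  set.seed(302)
  obs <- observer_profile(sigma_D = 0.2, sigma_S = 0.25, lapse = 0.35)
  sl <- fit_shared_lapse(sim_session(obs, c("D", "S", "DS")))
  expect_gte(sl$lambda, 0)
  expect_lte(sl$lambda, 0.2)
  # near-lapse-free, steep data: posterior mass stays near zero
  set.seed(303)
  obs0 <- observer_profile(sigma_D = 0.05, sigma_S = 0.05, lapse = 0)
  sl0 <- fit_shared_lapse(sim_session(obs0, c("D", "S", "DS")))
  expect_lte(sl0$lambda, 0.02)
})

test_that("shared-lapse estimation recovers a generative lapse", {
  set.seed(304)
  lam_hat <- replicate(12, {
    obs <- observer_profile(sigma_D = 0.2, sigma_S = 0.25, sigma_A = 0.3,
                            lapse = 0.05)
    fit_shared_lapse(sim_session(obs, c("D", "S", "A", "DS", "DA")))$lambda
  })
  expect_lt(abs(median(lam_hat) - 0.05), 0.03)
})

test_that("conflict fits recover a shifted PSE", {
  set.seed(305)
  obs <- observer_profile(sigma_D = 0.2, sigma_S = 0.3, lapse = 0.02)
  w <- predicted_weight(0.2, 0.3)
  delta <- conflict_delta_true(obs, condition_spec("DS+"))
  err <- replicate(25, {
    tr <- simulate_trials(obs, "DS+", )
    ft <- fit_condition(tr, lambda = 0.02, alpha_free = TRUE)
    ft$alpha - (1 - w) * delta
  })
  expect_lt(abs(median(err)), 0.1 * delta)
})

test_that("degenerate and underpowered inputs are refused or flagged", {
  cc_small <- data.frame(x = c(-0.5, 0.5), k = c(1, 4), n = c(5, 5))
  expect_error(fit_condition(cc_small, lambda = 0.02), "too few")
  # perfectly separable step data: slope at the top of its prior, flagged
  cc_step <- data.frame(x = depth_design()$x,
                        k = ifelse(depth_design()$x > 0, 12, 0), n = 12)
  ft <- fit_condition(cc_step, lambda = 0)
  expect_match(ft$flag, "beta_boundary")
  # all-identical responses warn at the shared-lapse stage
  tr <- simulate_trials(observer_profile(lapse = 1), "D", seed = 1)
  tr2 <- simulate_trials(observer_profile(lapse = 1), "S", seed = 2)
  tr2$condition <- "S"
  expect_warning(fit_shared_lapse(rbind(tr, tr2)), "degenerate")
})

test_that("fits are invariant to row order and interval-order relabelling", {
  set.seed(306)
  obs <- observer_profile(sigma_D = 0.22, sigma_S = 0.3, lapse = 0.03)
  tr <- simulate_trials(obs, "DS", seed = 31)
  f1 <- fit_condition(tr, lambda = 0.03)
  f2 <- fit_condition(tr[sample.int(nrow(tr)), ], lambda = 0.03)
  expect_equal(f1, f2)
  # flipping the recorded interval order together with the raw response
  # leaves the comparison-relative data, hence the fit, unchanged
  tr3 <- tr
  tr3$order <- 3L - tr$order
  tr3$response <- 1L - tr$response
  f3 <- fit_condition(tr3, lambda = 0.03)
  expect_equal(f1, f3)
})

test_that("posterior mode is a local optimum of the Bernoulli likelihood", {
  set.seed(307)
  tr <- simulate_trials(observer_profile(sigma_D = 0.25, sigma_S = 0.3,
                                         lapse = 0.02), "DS+", seed = 41)
  grid <- pf_grid()
  ft <- fit_condition(tr, lambda = 0.02, alpha_free = TRUE, grid = grid,
                      point = "mode")
  cc <- cuecomb:::trial_counts(tr)
  ll0 <- counts_loglik(cc, ft$alpha, ft$beta, ft$lambda)
  ia <- which.min(abs(grid$alpha - ft$alpha))
  ib <- which.min(abs(grid$beta - ft$beta))
  for (da in c(-1L, 1L)) {
    a2 <- grid$alpha[ia + da]
    expect_lte(counts_loglik(cc, a2, ft$beta, ft$lambda), ll0 + 1e-9)
  }
  for (db in c(-1L, 1L)) {
    b2 <- grid$beta[ib + db]
    expect_lte(counts_loglik(cc, ft$alpha, b2, ft$lambda), ll0 + 1e-9)
  }
})

test_that("estimates are stable under grid refinement", {
  set.seed(308)
  tr <- simulate_trials(observer_profile(sigma_D = 0.2, sigma_S = 0.3,
                                         lapse = 0.03), "DS", seed = 51)
  f_coarse <- fit_condition(tr, lambda = 0.03, grid = pf_grid())
  f_fine <- fit_condition(tr, lambda = 0.03,
                          grid = pf_grid(n_beta = 321, n_alpha = 161,
                                         n_lambda = 81))
  expect_lt(abs(f_fine$beta - f_coarse$beta) / f_fine$beta, 0.01)
})

test_that("fixing the lapse at truth beats a per-condition free lapse", {
  set.seed(309)
  res <- t(replicate(40, {
    cc <- sim_counts(sigma = 0.2, lambda = 0.06)
    b_fixed <- fit_condition(cc, lambda = 0.06)$beta
    tb <- cuecomb:::pf_tables(cc$x, pf_grid(), alpha_free = FALSE)
    b_free <- cuecomb:::pf_fit_rows_free_lambda(
      matrix(cc$k, 1), matrix(cc$n - cc$k, 1), tb)$beta
    c(fixed = b_fixed, free = b_free)
  }))
  b_true <- 1 / (0.2 * sqrt(2))
  rmse <- sqrt(colMeans((res - b_true)^2))
  expect_lt(rmse[["fixed"]], rmse[["free"]])
})

test_that("two-stage study fits label their lapse source and PSE constraints", {
  set.seed(310)
  pop <- population_spec(n = 2L)
  st <- simulate_study(pop, list(`2` = c("D", "S", "DS", "DS+")), seed = 61)
  f <- fit_study(st)
  expect_equal(nrow(f), 8L)
  expect_true(all(f$lambda_source == "shared-stage"))
  expect_true(all(f$alpha[f$condition != "DS+"] == 0))
  expect_true(all(f$alpha_fixed == (f$condition != "DS+")))
  # within a participant x session, the lapse is shared across conditions
  for (p in unique(f$participant)) {
    expect_length(unique(f$lambda[f$participant == p]), 1L)
  }
})
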
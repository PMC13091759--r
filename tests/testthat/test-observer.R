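# Generative observer model: closed-form response probabilities, percept
# sampling, trial simulation, and the strategy-specific predictions.

test_that("closed-form response probabilities match the decision model", {
  obs <- observer_profile(sigma_D = 0.2, sigma_S = 0.2, lapse = 0)
  x <- seq(-1, 1, by = 0.25)
  # equal-noise fusion: effective sigma is sigma/sqrt(2) per interval
  p <- response_prob(obs, condition_spec("DS"), x)
  expect_equal(p, pnorm(x / ((0.2 / sqrt(2)) * sqrt(2))), tolerance = 1e-12)
  # single cue
  p1 <- response_prob(obs, condition_spec("D"), x)
  expect_equal(p1, pnorm(x / (0.2 * sqrt(2))), tolerance = 1e-12)
  # lapse conventions move the asymptotes
  obs2 <- observer_profile(sigma_D = 0.2, lapse = 0.1)
  expect_equal(response_prob(obs2, condition_spec("D"), -1e6), 0.1)
  expect_equal(response_prob(obs2, condition_spec("D"), 1e6), 1)
  expect_equal(response_prob(obs2, condition_spec("D"), -1e6,
                             lapse_convention = "guess"), 0.05)
})

test_that("conflict shifts the PSE by (1 - w_D) * delta under fusion", {
  obs <- observer_profile(sigma_D = 0.2, sigma_S = 0.3, lapse = 0)
  w <- predicted_weight(0.2, 0.3)
  delta <- 1.5 * sqrt(2) * 0.3
  expect_equal(conflict_delta_true(obs, condition_spec("DS+")), delta)
  expect_equal(conflict_delta_true(obs, condition_spec("DS-")), -delta)
  # response probability crosses 0.5 exactly at the predicted shift
  expect_equal(response_prob(obs, condition_spec("DS+"), (1 - w) * delta,
                             delta = delta), 0.5, tolerance = 1e-12)
  # equal-reliability observer: shift is delta / 2
  obs_eq <- observer_profile(sigma_D = 0.25, sigma_S = 0.25, lapse = 0)
  d2 <- conflict_delta_true(obs_eq, condition_spec("DS+"))
  expect_equal(response_prob(obs_eq, condition_spec("DS+"), d2 / 2,
                             delta = d2), 0.5, tolerance = 1e-12)
  # disparity-dominant observer: no shift
  obs_dom <- observer_profile(sigma_D = 0.05, sigma_S = 50, lapse = 0)
  d3 <- conflict_delta_true(obs_dom, condition_spec("DS+"))
  expect_equal(response_prob(obs_dom, condition_spec("DS+"), 0, delta = d3),
               0.5, tolerance = 1e-2)
})

test_that("strategies differ as designed under incongruence and switching", {
  # fusing observer: incongruent slope is (2w - 1), so precision drops
  obs <- observer_profile(sigma_D = 0.2, sigma_S = 0.3, lapse = 0)
  w <- predicted_weight(0.2, 0.3)
  se <- optimal_sigma(0.2, 0.3)$sigma_opt
  x <- 0.5
  expect_equal(response_prob(obs, condition_spec("DSi"), x),
               pnorm((2 * w - 1) * x / (se * sqrt(2))), tolerance = 1e-12)
  expect_lt(response_prob(obs, condition_spec("DSi"), x),
            response_prob(obs, condition_spec("DS"), x))
  # best-single-cue observer with disparity best: unchanged by incongruence
  obs_b <- observer_profile(sigma_D = 0.2, sigma_S = 0.3, lapse = 0,
                            strategy = "best-single-cue")
  expect_equal(response_prob(obs_b, condition_spec("DSi"), x),
               response_prob(obs_b, condition_spec("DS"), x))
  expect_equal(response_prob(obs_b, condition_spec("DS"), x),
               pnorm(x / (0.2 * sqrt(2))))
  # switching is a mixture, flatter than the best cue alone
  obs_s <- observer_profile(sigma_D = 0.2, sigma_S = 0.4, lapse = 0,
                            strategy = "switching")
  p1 <- 0.4^2 / (0.2^2 + 0.4^2)
  expect_equal(response_prob(obs_s, condition_spec("DS"), x),
               p1 * pnorm(x / (0.2 * sqrt(2))) +
                 (1 - p1) * pnorm(x / (0.4 * sqrt(2))), tolerance = 1e-12)
  expect_lt(response_prob(obs_s, condition_spec("DS"), x),
            pnorm(x / (0.2 * sqrt(2))))
  # non-binding observer treats the novel pair as best-single-cue
  obs_nb <- observer_profile(sigma_D = 0.2, sigma_A = 0.3, lapse = 0,
                             binds_novel_cue = FALSE)
  expect_equal(response_prob(obs_nb, condition_spec("DA"), x),
               pnorm(x / (0.2 * sqrt(2))))
})

test_that("percept sampling agrees with the closed-form probabilities", {
  set.seed(71)
  obs <- observer_profile(sigma_D = 0.25, sigma_S = 0.35, lapse = 0,
                          strategy = "switching")
  for (lab in c("D", "DS", "DS+", "DSi")) {
    spec <- condition_spec(lab)
    delta <- conflict_delta_true(obs, spec)
    x <- 0.4
    est <- percept_sample(obs, spec, rep(x, 40000), 0, delta)
    p_mc <- mean(est$cmp_est > est$ref_est)
    p_th <- response_prob(obs, spec, x, 0, delta)
    expect_lt(abs(p_mc - p_th), 3 * sqrt(p_th * (1 - p_th) / 40000) + 1e-3)
  }
})

test_that("simulated trial tables have the designed structure", {
  obs <- observer_profile(sigma_D = 0.2, sigma_S = 0.25, lapse = 0.03)
  tr <- simulate_trials(obs, "DS", seed = 5)
  expect_equal(nrow(tr), 175)          # 168 main + 7 easy
  expect_equal(sum(tr$easy), 7)
  expect_equal(sort(unique(tr$comparison_level[!tr$easy])), depth_design()$x)
  expect_setequal(unique(tr$order), c(1L, 2L))
  expect_true(all(tr$response %in% 0:1))
  # reduced repetitions scale the table
  tr5 <- simulate_trials(obs, "D", n_reps = 5, seed = 6)
  expect_equal(sum(!tr5$easy), 70)
  # identical seed reproduces the table exactly
  expect_identical(simulate_trials(obs, "DS", seed = 5), tr)
})

test_that("lapse and noise limits force the stated response patterns", {
  # full lapse: every comparison-relative response is "further"
  obs1 <- observer_profile(sigma_D = 0.2, lapse = 1)
  tr <- simulate_trials(obs1, "D", seed = 11)
  recoded <- ifelse(tr$order == 1L, tr$response, 1L - tr$response)
  expect_true(all(recoded == 1L))
  # vanishing noise, no lapses: responses follow the sign of the comparison
  obs0 <- observer_profile(sigma_D = 1e-6, lapse = 0)
  tr0 <- simulate_trials(obs0, "D", seed = 12)
  rec0 <- ifelse(tr0$order == 1L, tr0$response, 1L - tr0$response)
  expect_equal(rec0, as.integer(tr0$comparison_level > 0))
})

test_that("study simulation respects the population and schedule", {
  pop <- population_spec(n = 4L, sd_within = 0)
  sch <- list(`2` = c("D", "S", "DS"), `4` = c("D", "S", "DS"))
  st <- simulate_study(pop, sch, seed = 21)
  expect_setequal(unique(st$participant), sprintf("P%03d", 1:4))
  expect_setequal(unique(st$session), c(2L, 4L))
  truth <- attr(st, "truth")
  # zero within-observer spread: generative sigma identical across sessions
  for (p in unique(truth$participant)) {
    tp <- truth[truth$participant == p, ]
    expect_equal(tp$sigma_D[1], tp$sigma_D[2])
  }
  # mapping direction counterbalanced
  expect_setequal(unique(truth$mapping_direction), c(-1, 1))
  # per participant x session x condition: 175 rows
  n_rows <- table(st$participant, st$session, st$condition)
  expect_true(all(n_rows == 175))
  expect_identical(simulate_study(pop, sch, seed = 21), st)
})
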
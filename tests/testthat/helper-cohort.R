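# Batched replicate-study machinery for the acceptance checks: simulates a
# cohort's per-level response counts for a set of conditions, fits them with
# the two-stage procedure (batched across participants), and returns fits /
# metrics tables plus the generative truth.

cohort_conditions <- c("D", "S", "DS", "DS+", "DS-", "Du", "DuS+", "DuS-")

# One replicate study: n observers with study-like noise spread.
simulate_cohort_counts <- function(n, strategy = "optimal-averaging",
                                   design = depth_design(),
                                   conditions = cohort_conditions) {
  obs_list <- lapply(seq_len(n), function(i) {
    observer_profile(
      sigma_D = pmax(0.05, rnorm(1, 0.25, 0.04)),
      sigma_S = pmax(0.05, rnorm(1, 0.30, 0.04)),
      lapse = runif(1, 0, 0.06), strategy = strategy)
  })
  x <- design$x
  K <- list()
  for (cn in conditions) {
    spec <- condition_spec(cn)
    P <- t(vapply(obs_list, function(o) {
      response_prob(o, spec, x, 0, conflict_delta_true(o, spec,
                                                       design$conflict_mult))
    }, numeric(length(x))))
    K[[cn]] <- matrix(rbinom(n * length(x), design$n_reps, P), n)
  }
  list(K = K, obs = obs_list, x = x, n_reps = design$n_reps,
       conditions = conditions)
}

fit_cohort <- function(sim, grid = pf_grid()) {
  n <- nrow(sim$K[[1]])
  x <- sim$x
  conditions <- sim$conditions
  s1 <- cuecomb:::pf_stage1_grid(grid)
  afree <- vapply(conditions,
                  function(cn) condition_spec(cn)$alpha_free, logical(1))
  ids <- sprintf("P%03d", seq_len(n))
  blocks <- lapply(unique(afree), function(af) {
    conds <- conditions[afree == af]
    list(K1 = do.call(rbind, sim$K[conds]),
         K0 = sim$n_reps - do.call(rbind, sim$K[conds]),
         tables = cuecomb:::pf_tables(x, s1, alpha_free = af),
         unit = rep(ids, length(conds)))
  })
  lam <- cuecomb:::pf_shared_lambda(blocks)[ids]
  li <- cuecomb:::snap_lambda(lam, grid)
  fits <- list()
  for (cn in conditions) {
    af <- afree[[cn]]
    tb <- cuecomb:::pf_tables(x, grid, alpha_free = af)
    ft <- cuecomb:::pf_fit_rows(sim$K[[cn]], sim$n_reps - sim$K[[cn]],
                                tb, lambda_idx = li)
    sess <- if (grepl("^Du", cn)) 3L else 2L
    fits[[cn]] <- data.frame(
      participant = ids, session = sess, condition = cn,
      alpha = if (af) ft$alpha else 0, beta = ft$beta,
      lambda = grid$lambda[li], sigma = 1 / (ft$beta * sqrt(2)),
      jnd = 1 / ft$beta, alpha_fixed = !af, n_trials = 168L,
      flag = ft$flag, stringsAsFactors = FALSE)
  }
  do.call(rbind, fits)
}

replicate_marker_study <- function(n = 40, strategy = "optimal-averaging") {
  sim <- simulate_cohort_counts(n, strategy)
  compute_metrics(fit_cohort(sim))
}
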
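# Shared helpers: independent oracles and small simulation utilities.

# Exact Wilcoxon signed-rank p-value by exhaustive enumeration of all 2^n
# sign assignments (zeros dropped, Wilcoxon's convention). Two-sided.
enum_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.vector(signs %*% r)
  ev <- n * (n + 1) / 4
  mean(abs(v_all - ev) >= abs(v_obs - ev) - 1e-9)
}

# Bernoulli log-likelihood of a counts table under psi().
counts_loglik <- function(cc, alpha, beta, lambda,
                          lapse_convention = "further") {
  p <- psi(cc$x, alpha, beta, lambda, lapse_convention)
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  sum(cc$k * log(p) + (cc$n - cc$k) * log(1 - p))
}

# Simulate a counts table directly from psi() (single condition, alpha 0).
sim_counts <- function(sigma, lambda, n_reps = 12L,
                       design = depth_design(), alpha = 0) {
  x <- design$x
  p <- psi(x, alpha, 1 / (sigma * sqrt(2)), lambda)
  data.frame(x = x, k = rbinom(length(x), n_reps, p), n = n_reps)
}

# One observer's session of unimodal + bimodal conditions as a trial table.
sim_session <- function(obs, conds, design = depth_design(), session = 2L,
                        participant = "P1") {
  do.call(rbind, lapply(conds, function(cn) {
    simulate_trials(obs, condition_spec(cn), design,
                    participant = participant, session = session)
  }))
}
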
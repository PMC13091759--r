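# Simulation-based power for detecting a group-level cue-combination benefit.
#
# Each simulated experiment draws n observers with a given best-cue sensory
# noise and worst/best noise ratio (lapse uniform up to max_lapse), generates
# 2IFC data for the best-cue, worst-cue and optimally combined conditions,
# fits each condition's psychometric function, and applies the two-tailed
# Wilcoxon signed-rank test of the combined condition's sensory noise against
# the empirical best single cue (the minimum of the two fitted single-cue
# noises, as in the combination index). Power is the fraction of experiments
# with p < alpha and a median difference in the combination direction.
#
# The default fit is the single-stage three-parameter Bayesian fit (PSE,
# slope and lapse all free under uniform priors, marginal posterior means);
# the two-stage shared-lapse fit used by the analysis pipeline is available
# via `fit = "two-stage"`, but note that sharing one lapse across the three
# conditions correlates their estimation errors, which partially cancel in
# the paired test and raise power relative to independent per-condition fits.

# Grid used by the power simulations: resolution at which the fitted-slope
# distribution is converged (finer grids change fitted slopes and their
# spread by under 1%), with an 11-node trapezoid rule for the lapse
# integral, chosen so a 1000-experiment cell runs in minutes.
power_grid_spec <- function() {
  pf_grid(n_beta = 181, beta_range = c(0.05, 200),
          n_alpha = 61, alpha_range = c(-1, 1),
          n_lambda = 11, lambda_range = c(0, 0.2))
}

#' Estimate power for one parameter cell
#'
#' @param n_participants Simulated group size.
#' @param sigma_best Sensory noise of the better single cue (normalized
#'   units).
#' @param noise_ratio Worst/best single-cue noise ratio (>= 1).
#' @param n_sims Simulated experiments (>= 100).
#' @param design A [depth_design()]; the default gives 14 levels x 12
#'   repetitions per condition.
#' @param alpha Significance level of the group test.
#' @param max_lapse Upper end of the uniform per-observer lapse distribution.
#' @param population `"fixed"` (every observer has exactly the cell's
#'   parameters) or `"jittered"` (log-normal spread around the cell value
#'   with coefficient of variation `cv`).
#' @param cv Coefficient of variation for the jittered population.
#' @param fit `"single-stage"` (PSE, slope, lapse free; default) or
#'   `"two-stage"` (session-shared lapse, then slope with lapse fixed).
#' @param alpha_free Let the PSE vary in the fits (default TRUE).
#' @param comparator `"min-fitted"` (empirical best cue; default) or
#'   `"assigned-best"` (the generatively better cue's fit).
#' @param combination `"optimal"` simulates true combiners (bimodal noise at
#'   the maximum-likelihood prediction); `"none"` simulates best-single-cue
#'   followers (no benefit), the null model for type-I calibration.
#' @param seed Seed for the cell (local to this call).
#' @param grid Parameter grids for the fits.
#' @return One-row data frame: the cell parameters, `power`, `mc_se`
#'   (binomial Monte-Carlo standard error) and `n_discarded`.
#' @export
simulate_power_cell <- function(n_participants, sigma_best = 0.2,
                                noise_ratio = 1.5, n_sims = 1000L,
                                design = depth_design(), alpha = 0.05,
                                max_lapse = 0.10,
                                population = c("fixed", "jittered"), cv = 0.3,
                                fit = c("single-stage", "two-stage"),
                                alpha_free = TRUE,
                                comparator = c("min-fitted", "assigned-best"),
                                combination = c("optimal", "none"),
                                seed = NULL, grid = power_grid_spec()) {
  population <- match.arg(population)
  fit <- match.arg(fit)
  comparator <- match.arg(comparator)
  combination <- match.arg(combination)
  if (n_sims < 100L) stop("`n_sims` must be >= 100", call. = FALSE)
  stopifnot_scalar_pos(sigma_best, "sigma_best")
  if (noise_ratio < 1) stop("`noise_ratio` must be >= 1", call. = FALSE)
  n <- as.integer(n_participants)
  x <- design$x
  n_reps <- design$n_reps
  tb <- pf_tables(x, grid, alpha_free = alpha_free)
  tb1 <- if (fit == "two-stage") pf_tables(x, pf_stage1_grid(grid),
                                           alpha_free = FALSE) else NULL
  succ <- 0L; discarded <- 0L
  rows_per_sim <- n * 3L
  chunk_sims <- max(1L, as.integer(floor(600L / rows_per_sim)))
  with_seed(seed, {
    for (s0 in seq(1L, n_sims, by = chunk_sims)) {
      sims <- s0:min(s0 + chunk_sims - 1L, n_sims)
      K1 <- matrix(0L, length(sims) * rows_per_sim, length(x))
      for (j in seq_along(sims)) {
        sb <- if (population == "fixed") rep(sigma_best, n) else {
          sl <- sqrt(log(1 + cv^2))
          sigma_best * exp(stats::rnorm(n, -sl^2 / 2, sl))
        }
        sw <- sb * noise_ratio
        so <- if (combination == "optimal") {
          sqrt(sb^2 * sw^2 / (sb^2 + sw^2))
        } else sb
        lam <- stats::runif(n, 0, max_lapse)
        sig <- cbind(sb, sw, so)
        for (cc in 1:3) {
          P <- lam + (1 - lam) *
            stats::pnorm(outer(1 / (sig[, cc] * sqrt(2)), x))
          K1[(j - 1L) * rows_per_sim + (cc - 1L) * n + seq_len(n), ] <-
            matrix(stats::rbinom(n * length(x), n_reps, P), n)
        }
      }
      K0 <- n_reps - K1
      ft <- if (fit == "single-stage") {
        pf_fit_rows_free_lambda(K1, K0, tb)
      } else {
        unit <- as.vector(vapply(seq_along(sims), function(j) {
          rep(sprintf("s%04d.u%04d", sims[j], seq_len(n)), 3L)
        }, character(rows_per_sim)))
        lam_hat <- pf_shared_lambda(list(list(
          K1 = K1, K0 = K0, tables = tb1, unit = unit)))
        li <- snap_lambda(lam_hat[unit], grid)
        pf_fit_rows(K1, K0, tb, lambda_idx = li)
      }
      for (j in seq_along(sims)) {
        rows <- (j - 1L) * rows_per_sim + seq_len(rows_per_sim)
        beta_j <- ft$beta[rows]
        if (any(!is.finite(beta_j))) { discarded <- discarded + 1L; next }
        shat <- matrix(1 / (beta_j * sqrt(2)), n, 3L)
        best <- if (comparator == "min-fitted") pmin(shat[, 1], shat[, 2])
                else shat[, 1]
        p <- suppressWarnings(
          stats::wilcox.test(shat[, 3], best, paired = TRUE)$p.value)
        if (is.finite(p) && p < alpha &&
            stats::median(shat[, 3] - best) < 0) succ <- succ + 1L
      }
    }
  })
  used <- n_sims - discarded
  power <- succ / used
  data.frame(n_participants = n, sigma_best = sigma_best,
             noise_ratio = noise_ratio, max_lapse = max_lapse,
             n_sims = used, power = power,
             mc_se = sqrt(power * (1 - power) / used),
             n_discarded = discarded)
}

#' Power over a grid of parameter cells
#'
#' Cartesian product of `sigma_best`, `noise_ratio` and `n_participants`,
#' each cell simulated on an independent substream of `seed`.
#'
#' @param sigma_best,noise_ratio,n_participants Vectors of cell parameters.
#' @param seed Master seed; cells use deterministic substreams.
#' @param ... Passed to [simulate_power_cell()].
#' @return A data frame with one row per cell.
#' @export
power_grid <- function(sigma_best = 0.2, noise_ratio = c(1, 1.5, 2, 3),
                       n_participants = c(30, 60), n_sims = 1000L,
                       seed = NULL, ...) {
  cells <- expand.grid(sigma_best = sigma_best, noise_ratio = noise_ratio,
                       n_participants = n_participants)
  out <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    out[[i]] <- simulate_power_cell(
      n_participants = cells$n_participants[i],
      sigma_best = cells$sigma_best[i],
      noise_ratio = cells$noise_ratio[i],
      n_sims = n_sims,
      seed = if (is.null(seed)) NULL else substream_seed(seed, i), ...)
  }
  do.call(rbind, out)
}
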
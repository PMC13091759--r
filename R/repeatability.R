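# Intra-individual repeatability via random-intercept mixed models.
#
# R = sigma_G^2 / (sigma_G^2 + sigma_R^2): the share of total variance due to
# stable between-observer differences. REML point fit via lme4; uncertainty
# via parametric bootstrap; significance via a boundary-corrected likelihood
# ratio test and via permutation of residuals across observers.
#
# For balanced data the REML solution coincides with the one-way ANOVA
# estimators, so bootstrap and permutation refits use the closed form there
# (vectorised over thousands of resamples); unbalanced data fall back to
# lme4 refits.

# One-way ANOVA variance components; R truncated at 0.
# values: vector; group: factor-like.
anova_icc <- function(values, group) {
  group <- as.factor(group)
  k <- tabulate(group)
  means <- tapply(values, group, mean)
  grand <- mean(values)
  ssb <- sum(k * (means - grand)^2)
  ssw <- sum((values - means[group])^2)
  a <- length(k)
  msb <- ssb / (a - 1)
  msw <- ssw / (length(values) - a)
  k0 <- (sum(k) - sum(k^2) / sum(k)) / (a - 1) # = k for balanced designs
  sg2 <- max(0, (msb - msw) / k0)
  list(R = sg2 / (sg2 + msw), sigma_G2 = sg2, sigma_R2 = msw,
       msb = msb, msw = msw)
}

# Closed-form ICC for a balanced matrix of observers x sessions, vectorised
# over many resamples: Y is (n_obs x n_sess x n_rep) given as a list of
# (n_obs x n_sess) matrices, or a single matrix.
balanced_icc_matrix <- function(Y) {
  k <- ncol(Y)
  a <- nrow(Y)
  rm <- rowMeans(Y)
  grand <- mean(Y)
  msb <- k * sum((rm - grand)^2) / (a - 1)
  msw <- sum((Y - rm)^2) / (a * (k - 1))
  sg2 <- max(0, (msb - msw) / k)
  sg2 / (sg2 + msw)
}

#' Repeatability of a per-observer measure across sessions
#'
#' Fits the Gaussian random-intercept model `value ~ 1 + (1 | participant)`
#' by REML and reports `R = sigma_G^2 / (sigma_G^2 + sigma_R^2)` with a
#' parametric-bootstrap confidence interval, a likelihood-ratio test against
#' the no-random-effect model (reference distribution: 50:50 mixture of a
#' point mass at zero and chi-square(1), the boundary correction), and an
#' optional permutation test that shuffles observations across observers.
#'
#' @param data Data frame with columns `participant` and `value` (a `session`
#'   column may be present but does not enter the model).
#' @param n_boot Parametric bootstrap resamples (0 to skip).
#' @param n_perm Permutation resamples (0 to skip).
#' @param seed Optional seed (local to this call).
#' @param log_transform Log-transform the measure first (useful for sigma).
#' @return A `repeatability_result` list: `R`, `sigma_G2`, `sigma_R2`, `ci`,
#'   `d_LRR`, `p_lrt`, `p_perm`, `n_boot`, `n_perm`, `converged`, `boundary`,
#'   and the bootstrap distribution in `boot_R`.
#' @export
fit_repeatability <- function(data, n_boot = 1000L, n_perm = 0L, seed = NULL,
                              log_transform = FALSE) {
  stopifnot(all(c("participant", "value") %in% names(data)))
  data <- data[is.finite(data$value), , drop = FALSE]
  if (log_transform) data$value <- log(data$value)
  tab <- table(data$participant)
  if (length(tab) < 10L) {
    stop("repeatability needs >= 10 observers", call. = FALSE)
  }
  if (mean(tab >= 2L) < 0.8) {
    stop("repeatability needs >= 2 sessions for >= 80% of observers",
         call. = FALSE)
  }
  balanced <- length(unique(tab)) == 1L
  with_seed(seed, {
    fit <- tryCatch(
      lme4::lmer(value ~ 1 + (1 | participant), data = data, REML = TRUE),
      error = function(e) NULL)
    if (is.null(fit)) {
      return(structure(list(R = NA_real_, converged = FALSE),
                       class = "repeatability_result"))
    }
    vc <- as.data.frame(lme4::VarCorr(fit))
    sg2 <- vc$vcov[vc$grp == "participant"]
    sr2 <- vc$vcov[vc$grp == "Residual"]
    R <- sg2 / (sg2 + sr2)
    boundary <- sg2 < 1e-10
    singular <- lme4::isSingular(fit, tol = 1e-5)
    mu <- unname(lme4::fixef(fit)[1])

    # likelihood-ratio test (ML) against the intercept-only model
    # (convergence chatter near the zero-variance boundary is expected)
    fit_ml <- suppressWarnings(stats::update(fit, REML = FALSE))
    ll0 <- stats::logLik(stats::lm(value ~ 1, data = data))
    d_lrr <- max(0, 2 * (as.numeric(stats::logLik(fit_ml)) - as.numeric(ll0)))
    p_lrt <- if (d_lrr == 0) 1 else
      0.5 * stats::pchisq(d_lrr, 1, lower.tail = FALSE)

    refit_R <- function(values) {
      rf <- tryCatch(
        lme4::lmer(value ~ 1 + (1 | participant),
                   data = data.frame(participant = data$participant,
                                     value = values),
                   REML = TRUE),
        error = function(e) NULL)
      if (is.null(rf)) return(NA_real_)
      v <- as.data.frame(lme4::VarCorr(rf))
      v$vcov[v$grp == "participant"] /
        (v$vcov[v$grp == "participant"] + v$vcov[v$grp == "Residual"])
    }

    boot_R <- numeric(0)
    ci <- c(NA_real_, NA_real_)
    if (n_boot > 0L) {
      if (balanced) {
        k <- unname(tab[1]); a <- length(tab)
        boot_R <- vapply(seq_len(n_boot), function(i) {
          Y <- matrix(stats::rnorm(a, mu, sqrt(sg2)), a, k) +
            matrix(stats::rnorm(a * k, 0, sqrt(sr2)), a, k)
          balanced_icc_matrix(Y)
        }, numeric(1))
      } else {
        sim <- stats::simulate(fit, nsim = n_boot)
        boot_R <- vapply(seq_len(n_boot), function(i) refit_R(sim[[i]]),
                         numeric(1))
      }
      boot_R <- boot_R[is.finite(boot_R)]
      ci <- unname(stats::quantile(boot_R, c(0.025, 0.975)))
    }

    p_perm <- NA_real_
    if (n_perm > 0L) {
      perm_R <- vapply(seq_len(n_perm), function(i) {
        v <- sample(data$value)
        if (balanced) {
          Y <- matrix(v[order(data$participant)], length(tab),
                      unname(tab[1]), byrow = TRUE)
          balanced_icc_matrix(Y)
        } else {
          refit_R(v)
        }
      }, numeric(1))
      perm_R <- perm_R[is.finite(perm_R)]
      p_perm <- (1 + sum(perm_R >= R)) / (1 + length(perm_R))
    }

    structure(list(R = R, sigma_G2 = sg2, sigma_R2 = sr2, ci = ci,
                   d_LRR = d_lrr, p_lrt = p_lrt, p_perm = p_perm,
                   n_boot = length(boot_R), n_perm = n_perm,
                   converged = !singular || !boundary,
                   boundary = boundary, boot_R = boot_R),
              class = "repeatability_result")
  })
}

#' @export
print.repeatability_result <- function(x, ...) {
  cat(sprintf("Repeatability R = %.3f (95%% CI %.3f-%.3f)\n",
              x$R, x$ci[1], x$ci[2]))
  cat(sprintf("  sigma_G2 = %.4g, sigma_R2 = %.4g\n", x$sigma_G2, x$sigma_R2))
  cat(sprintf("  LRT d = %.2f, p = %.4g", x$d_LRR, x$p_lrt))
  if (is.finite(x$p_perm)) cat(sprintf("; permutation p = %.4g", x$p_perm))
  cat(sprintf("\n  converged: %s%s\n", x$converged,
              if (isTRUE(x$boundary)) " (variance at zero boundary)" else ""))
  invisible(x)
}
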
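# Derived quantities: sensory noise, JND, cue weights, optimal predictions,
# and the per-participant combination / re-weighting / incongruence indices.

#' Sensory noise from a psychometric slope
#'
#' In a 2IFC comparison two noisy interval estimates are differenced, so the
#' discrimination function's standard deviation `1/beta` is `sqrt(2)` times
#' the single-estimate sensory noise: `sigma = 1 / (beta * sqrt(2))`. The
#' just-noticeable difference is `JND = sigma * sqrt(2) = 1/beta`.
#'
#' @param beta Psychometric slope (positive).
#' @return A list with `sigma` and `jnd`.
#' @export
sigma_from_beta <- function(beta) {
  if (any(!is.finite(beta)) || any(beta <= 0)) {
    stop("`beta` must be positive", call. = FALSE)
  }
  list(sigma = 1 / (beta * sqrt(2)), jnd = 1 / beta)
}

#' Conflict magnitude from the conflicted cue's JND
#'
#' The cross-modal conflict applied to the size or audio cue is `mult` (by
#' default 1.5) of that cue's just-noticeable difference.
#'
#' @param jnd JND of the conflicted (non-disparity) cue.
#' @param mult Conflict size in JND units.
#' @export
conflict_magnitude <- function(jnd, mult = 1.5) {
  if (any(!is.finite(jnd)) || any(jnd <= 0)) {
    stop("`jnd` must be positive", call. = FALSE)
  }
  mult * jnd
}

#' Empirical disparity weight from conflict-induced PSE shifts
#'
#' The mean conflict-induced shift is the signed half-difference of the PSEs
#' under positive and negative conflicts, `mu_PSE = (pse_plus - pse_minus)/2`
#' (any conflict-independent bias cancels), and the disparity weight is
#' `w = 1 - mu_PSE / delta`: no shift means the observer followed disparity
#' fully (w = 1), a full shift means the other cue was followed (w = 0).
#'
#' @param pse_plus,pse_minus Fitted PSEs under the `+` and `-` conflicts.
#' @param delta Conflict magnitude (positive, normalized units).
#' @export
empirical_weight <- function(pse_plus, pse_minus, delta) {
  if (any(delta <= 0)) stop("`delta` must be positive", call. = FALSE)
  mu_pse <- (pse_plus - pse_minus) / 2
  1 - mu_pse / delta
}

#' Reliability-predicted disparity weight
#'
#' Under reliability-weighted averaging each cue's weight is proportional to
#' its inverse variance: `w_D = sigma_other^2 / (sigma_D^2 + sigma_other^2)`.
#'
#' @param sigma_d Sensory noise of the disparity(-like) cue.
#' @param sigma_other Sensory noise of the paired cue.
#' @export
predicted_weight <- function(sigma_d, sigma_other) {
  if (any(sigma_d <= 0) || any(sigma_other <= 0)) {
    stop("sensory noises must be positive", call. = FALSE)
  }
  sigma_other^2 / (sigma_d^2 + sigma_other^2)
}

#' Optimal (maximum-likelihood) bimodal sensory noise
#'
#' `sigma_opt = sqrt(sigma1^2 * sigma2^2 / (sigma1^2 + sigma2^2))`: always
#' below the better single cue, equal to `sigma/sqrt(2)` for equally reliable
#' cues.
#'
#' @param sigma1,sigma2 Single-cue sensory noises.
#' @return A list with `sigma_opt` and the components.
#' @export
optimal_sigma <- function(sigma1, sigma2) {
  if (any(sigma1 <= 0) || any(sigma2 <= 0)) {
    stop("sensory noises must be positive", call. = FALSE)
  }
  list(sigma_opt = sqrt(sigma1^2 * sigma2^2 / (sigma1^2 + sigma2^2)),
       components = c(sigma1, sigma2))
}

# Internal: pull one condition's fit for a participant, preferring a session.
fit_lookup <- function(fits, participant, cond, prefer_session = NULL) {
  f <- fits[fits$participant == participant & fits$condition == cond, ,
            drop = FALSE]
  if (nrow(f) == 0L) return(NULL)
  if (!is.null(prefer_session) && any(f$session == prefer_session)) {
    f <- f[f$session == prefer_session, , drop = FALSE]
  }
  f[order(f$session), , drop = FALSE][1L, , drop = FALSE]
}

#' Marker indices for one participant and cue pair
#'
#' * Combination index `CI = min(sigma_D, sigma_2) - sigma_bimodal`
#'   (positive when the pair is more precise than the best single cue).
#' * Re-weighting index `RI = w_emp(normal) - w_emp(noisy-disparity)`
#'   (positive when disparity is down-weighted once degraded).
#' * Incongruence-sensitivity index `IS = sigma_incongruent -
#'   sigma_congruent` (positive when reversing the learned mapping costs
#'   precision).
#'
#' Missing conditions yield `NA` indices, never zero.
#'
#' @param fits A fits table from [fit_study()].
#' @param participant Participant id.
#' @param cue_pair `"DS"` or `"DA"`.
#' @param conflict_mult Conflict size in JND units used by the study design.
#' @return One-row data frame of sigmas, weights and indices.
#' @export
marker_indices <- function(fits, participant, cue_pair = c("DS", "DA"),
                           conflict_mult = 1.5) {
  cue_pair <- match.arg(cue_pair)
  cue2 <- substr(cue_pair, 2, 2)
  g <- function(cond, prefer = NULL) {
    f <- fit_lookup(fits, participant, cond, prefer)
    if (is.null(f) || nzchar(f$flag)) NULL else f
  }
  sig <- function(f) if (is.null(f)) NA_real_ else f$sigma
  f_d <- g("D", 2); f_2 <- g(cue2, 2); f_bi <- g(cue_pair, 2)
  f_du <- g("Du", 3); f_2n <- g(cue2, 3)
  f_bin <- g(paste0("Du", cue2), 3)
  f_inc <- g(paste0(cue_pair, "i"), 4)
  f_bi4 <- g(cue_pair, 4)
  # empirical weights need both conflict signs and the conflicted cue's JND
  w_emp <- function(pair_label, f_cue2) {
    fp <- g(paste0(pair_label, "+")); fm <- g(paste0(pair_label, "-"))
    if (is.null(fp) || is.null(fm) || is.null(f_cue2)) return(NA_real_)
    empirical_weight(fp$alpha, fm$alpha,
                     conflict_magnitude(f_cue2$jnd, conflict_mult))
  }
  w_emp_normal <- w_emp(cue_pair, f_2)
  w_emp_noisy <- w_emp(paste0("Du", cue2), if (is.null(f_2n)) f_2 else f_2n)
  w_pred_normal <- if (is.null(f_d) || is.null(f_2)) NA_real_ else
    predicted_weight(f_d$sigma, f_2$sigma)
  w_pred_noisy <- if (is.null(f_du)) NA_real_ else {
    f2 <- if (is.null(f_2n)) f_2 else f_2n
    if (is.null(f2)) NA_real_ else predicted_weight(f_du$sigma, f2$sigma)
  }
  sigma_opt <- if (is.null(f_d) || is.null(f_2)) NA_real_ else
    optimal_sigma(f_d$sigma, f_2$sigma)$sigma_opt
  ci <- if (anyNA(c(sig(f_d), sig(f_2), sig(f_bi)))) NA_real_ else
    min(sig(f_d), sig(f_2)) - sig(f_bi)
  ri <- w_emp_normal - w_emp_noisy
  sigma_cong_s4 <- if (!is.null(f_bi4)) sig(f_bi4) else sig(f_bi)
  is_idx <- if (is.null(f_inc) || is.na(sigma_cong_s4)) NA_real_ else
    sig(f_inc) - sigma_cong_s4
  data.frame(
    participant = participant, cue_pair = cue_pair,
    sigma_D = sig(f_d), sigma_2 = sig(f_2), sigma_bi = sig(f_bi),
    sigma_Du = sig(f_du), sigma_bi_noisy = sig(f_bin),
    sigma_inc = if (is.null(f_inc)) NA_real_ else sig(f_inc),
    sigma_opt = sigma_opt,
    w_emp_normal = w_emp_normal, w_emp_noisy = w_emp_noisy,
    w_pred_normal = w_pred_normal, w_pred_noisy = w_pred_noisy,
    CI = ci, RI = ri, IS = is_idx,
    stringsAsFactors = FALSE
  )
}

#' Per-participant metrics table for all cue pairs
#'
#' Applies [marker_indices()] to every participant x cue pair with the
#' relevant conditions present.
#'
#' @inheritParams marker_indices
#' @return A metrics data frame, one row per participant x cue pair.
#' @export
compute_metrics <- function(fits, conflict_mult = 1.5) {
  pairs <- c("DS", "DA")
  have <- function(pair) any(fits$condition %in%
                               c(pair, paste0("Du", substr(pair, 2, 2))))
  rows <- list()
  for (p in unique(fits$participant)) {
    for (pr in pairs) {
      if (!have(pr)) next
      rows[[length(rows) + 1L]] <- marker_indices(fits, p, pr, conflict_mult)
    }
  }
  do.call(rbind, rows)
}
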
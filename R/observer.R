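# Generative observer models and the 2IFC trial simulator.
#
# All simulation happens in normalized depth units (reference = 0, range
# +/- 1). An observer is a set of single-cue sensory noises plus a
# perceptual-decisional strategy; a condition determines which cues are shown
# and whether a conflict or an incongruent mapping is applied. Every
# strategy reduces to a small mixture of Gaussian decision branches, which
# gives closed-form response probabilities (used by the fast simulation paths
# and by tests) alongside the trial-level percept sampler.

#' Generative observer profile
#'
#' @param sigma_D,sigma_S,sigma_A Single-cue sensory noises in normalized
#'   depth units (standard deviation of one interval's internal estimate).
#' @param sigma_Du Sensory noise of the uncertainty-added disparity variant;
#'   defaults to `du_factor * sigma_D`.
#' @param du_factor Multiplicative noise inflation for the noisy-disparity
#'   variant (default 2), used when `sigma_Du` is not given.
#' @param lapse Stimulus-independent response probability, in `[0, 0.2]` for
#'   study-like data.
#' @param strategy `"optimal-averaging"` (reliability-weighted fusion),
#'   `"best-single-cue"`, or `"switching"` (one cue per trial).
#' @param switch_p Probability of using the disparity cue on a switching
#'   trial; default is reliability-proportional
#'   (`sigma_other^2 / (sigma_D^2 + sigma_other^2)`).
#' @param mapping_direction `+1` or `-1`; the learned audio depth-to-pitch
#'   mapping direction (counterbalanced across observers).
#' @param binds_novel_cue If `FALSE` the observer does not fuse the novel
#'   (audio) pairing and falls back to the best single cue there, regardless
#'   of `strategy`.
#' @return An `observer_profile` object.
#' @export
observer_profile <- function(sigma_D = 0.25, sigma_S = 0.3, sigma_A = 0.3,
                             sigma_Du = NULL, du_factor = 2,
                             lapse = 0.03,
                             strategy = c("optimal-averaging",
                                          "best-single-cue", "switching"),
                             switch_p = NULL,
                             mapping_direction = 1,
                             binds_novel_cue = TRUE) {
  strategy <- match.arg(strategy)
  for (s in c(sigma_D, sigma_S, sigma_A)) stopifnot_scalar_pos(s, "sigma")
  if (is.null(sigma_Du)) sigma_Du <- du_factor * sigma_D
  stopifnot_scalar_pos(sigma_Du, "sigma_Du")
  if (lapse < 0 || lapse > 1) stop("`lapse` must be in [0, 1]", call. = FALSE)
  if (!mapping_direction %in% c(-1, 1)) {
    stop("`mapping_direction` must be +1 or -1", call. = FALSE)
  }
  structure(list(sigma_D = sigma_D, sigma_S = sigma_S, sigma_A = sigma_A,
                 sigma_Du = sigma_Du, lapse = lapse, strategy = strategy,
                 switch_p = switch_p, mapping_direction = mapping_direction,
                 binds_novel_cue = isTRUE(binds_novel_cue)),
            class = "observer_profile")
}

# Sensory noise of one cue under a condition's disparity-noise flag.
cue_sigma <- function(obs, cue, disparity_noisy = FALSE) {
  switch(cue,
    "D" = if (disparity_noisy) obs$sigma_Du else obs$sigma_D,
    "S" = obs$sigma_S,
    "A" = obs$sigma_A,
    stop("unknown cue", call. = FALSE))
}

#' True conflict magnitude for an observer under a condition
#'
#' The conflict applied to the reference's non-disparity cue is
#' `conflict_mult` JNDs of that cue (JND = sigma * sqrt(2)), signed by the
#' condition's conflict sign.
#' @param obs An [observer_profile()].
#' @param spec A [condition_spec()].
#' @param conflict_mult Conflict size in JND units (default 1.5).
#' @export
conflict_delta_true <- function(obs, spec, conflict_mult = 1.5) {
  if (spec$conflict_sign == 0L) return(0)
  cue2 <- setdiff(spec$cues, "D")
  spec$conflict_sign * conflict_mult * sqrt(2) *
    cue_sigma(obs, cue2, disparity_noisy = FALSE)
}

# Decision-branch decomposition of an observer under a condition.
# Each branch is used with probability `p` and compares
#   cmp_est = slope * x_cmp + N(0, sigma)   vs
#   ref_est = x_ref + pse + N(0, sigma),
# where `pse` collects the conflict displacement delta weighted into the
# reference percept. Unimodal conditions have a single branch with slope 1.
decision_model <- function(obs, spec, delta = 0) {
  if (length(spec$cues) == 1L) {
    s <- cue_sigma(obs, spec$cues, spec$disparity_noisy)
    return(list(list(p = 1, sigma = s, slope = 1, pse = 0)))
  }
  s1 <- cue_sigma(obs, "D", spec$disparity_noisy)
  cue2 <- setdiff(spec$cues, "D")
  s2 <- cue_sigma(obs, cue2, FALSE)
  strategy <- obs$strategy
  if (cue2 == "A" && !obs$binds_novel_cue) strategy <- "best-single-cue"
  inc <- spec$incongruent
  if (strategy == "optimal-averaging") {
    w1 <- s2^2 / (s1^2 + s2^2)
    se <- sqrt(s1^2 * s2^2 / (s1^2 + s2^2))
    list(list(p = 1, sigma = se,
              slope = if (inc) 2 * w1 - 1 else 1,
              pse = (1 - w1) * delta))
  } else if (strategy == "best-single-cue") {
    if (s1 <= s2) {
      list(list(p = 1, sigma = s1, slope = 1, pse = 0))
    } else {
      list(list(p = 1, sigma = s2, slope = if (inc) -1 else 1, pse = delta))
    }
  } else { # switching
    p1 <- if (is.null(obs$switch_p)) s2^2 / (s1^2 + s2^2) else obs$switch_p
    list(list(p = p1,     sigma = s1, slope = 1, pse = 0),
         list(p = 1 - p1, sigma = s2, slope = if (inc) -1 else 1, pse = delta))
  }
}

#' Probability of judging the comparison "further", before lapses
#'
#' Closed-form response probability of the generative observer: each decision
#' branch compares two noisy interval estimates, so the per-branch probability
#' is a cumulative normal in the percept difference with spread
#' `sigma * sqrt(2)`.
#'
#' @param obs An [observer_profile()].
#' @param spec A [condition_spec()].
#' @param x_cmp Comparison depth(s), normalized units.
#' @param x_ref Reference depth(s) (0 for main trials).
#' @param delta Signed conflict displacement of the reference's second cue.
#' @param lapse_convention `"further"` applies the lapse as a
#'   stimulus-independent "further" response (lower asymptote `lapse`, upper
#'   1); `"guess"` is the symmetric convention (asymptotes `lapse/2` and
#'   `1 - lapse/2`); `"none"` returns the pre-lapse probability.
#' @return Vector of response probabilities.
#' @export
response_prob <- function(obs, spec, x_cmp, x_ref = 0, delta = 0,
                          lapse_convention = c("further", "guess", "none")) {
  lapse_convention <- match.arg(lapse_convention)
  branches <- decision_model(obs, spec, delta)
  p <- 0
  for (b in branches) {
    p <- p + b$p * stats::pnorm((b$slope * x_cmp - x_ref - b$pse) /
                                  (b$sigma * sqrt(2)))
  }
  switch(lapse_convention,
    further = obs$lapse + (1 - obs$lapse) * p,
    guess = obs$lapse / 2 + (1 - obs$lapse) * p,
    none = p)
}

#' Draw internal percept pairs for a set of trials
#'
#' Samples the observer's internal estimates for the reference and comparison
#' intervals of each trial (one decision branch per trial for switching
#' observers). Lapses are applied at the response stage by
#' [simulate_trials()], not here.
#'
#' @inheritParams response_prob
#' @return A data frame with columns `ref_est` and `cmp_est`, one row per
#'   element of `x_cmp`.
#' @export
percept_sample <- function(obs, spec, x_cmp, x_ref = 0, delta = 0) {
  n <- length(x_cmp)
  x_ref <- rep_len(x_ref, n)
  branches <- decision_model(obs, spec, delta)
  if (length(branches) == 1L) {
    idx <- rep(1L, n)
  } else {
    idx <- 1L + (stats::runif(n) >= branches[[1L]]$p)
  }
  sigma <- vapply(branches, `[[`, numeric(1), "sigma")[idx]
  slope <- vapply(branches, `[[`, numeric(1), "slope")[idx]
  pse <- vapply(branches, `[[`, numeric(1), "pse")[idx]
  data.frame(
    ref_est = x_ref + pse + stats::rnorm(n, 0, sigma),
    cmp_est = slope * x_cmp + stats::rnorm(n, 0, sigma)
  )
}

#' Simulate one observer's trials for one condition
#'
#' Generates the method-of-constants block: `n_reps` repetitions of each of
#' the 14 signed comparison levels, plus easy catch trials pairing the two
#' most extreme depths. The recorded `response` is the raw button press
#' ("second interval further", 0/1); `order` records which interval held the
#' reference so that analysis can recode to comparison-relative responses.
#' With probability `lapse` the observer responds "further" (in the
#' comparison-relative frame) irrespective of the stimulus, matching the
#' fitted psychometric function's asymmetric asymptotes; the symmetric
#' guessing convention is available via `lapse_convention = "guess"`.
#'
#' @param obs An [observer_profile()].
#' @param spec A [condition_spec()] (or a condition label string).
#' @param design A [depth_design()].
#' @param n_reps Repetitions per level; defaults to the design's.
#' @param seed Optional seed (local to this call).
#' @param participant,session Identifiers copied into the table.
#' @param lapse_convention See [response_prob()].
#' @return A trial data frame with columns `participant`, `session`,
#'   `condition`, `mapping_direction`, `side`, `comparison_level`,
#'   `conflict_sign`, `order` (1 = reference first), `easy`, `response`.
#' @export
simulate_trials <- function(obs, spec, design = depth_design(),
                            n_reps = NULL, seed = NULL,
                            participant = "P1", session = 1L,
                            lapse_convention = c("further", "guess")) {
  lapse_convention <- match.arg(lapse_convention)
  if (is.character(spec)) spec <- condition_spec(spec)
  with_seed(seed, {
    n_reps <- if (is.null(n_reps)) design$n_reps else as.integer(n_reps)
    x_main <- rep(design$x, n_reps)
    n_main <- length(x_main)
    n_easy <- as.integer(round(design$easy_rate * n_main /
                                 (1 - design$easy_rate)))
    L <- max(design$levels)
    easy_sign <- if (n_easy > 0) sample(c(-1, 1), n_easy, replace = TRUE) else numeric(0)
    x_cmp <- c(x_main, easy_sign * L)
    x_ref <- c(rep(0, n_main), -easy_sign * L)
    easy <- c(rep(FALSE, n_main), rep(TRUE, n_easy))
    delta <- conflict_delta_true(obs, spec, design$conflict_mult)
    est <- percept_sample(obs, spec, x_cmp, x_ref, delta)
    r <- as.integer(est$cmp_est > est$ref_est)
    lapse_trial <- stats::runif(length(x_cmp)) < obs$lapse
    if (any(lapse_trial)) {
      r[lapse_trial] <- if (lapse_convention == "further") 1L else
        stats::rbinom(sum(lapse_trial), 1L, 0.5)
    }
    order <- sample(c(1L, 2L), length(x_cmp), replace = TRUE)
    response <- ifelse(order == 1L, r, 1L - r)
    out <- data.frame(
      participant = participant,
      session = as.integer(session),
      condition = spec$label,
      mapping_direction = obs$mapping_direction,
      side = design$side,
      comparison_level = x_cmp,
      conflict_sign = spec$conflict_sign,
      order = order,
      easy = easy,
      response = as.integer(response),
      stringsAsFactors = FALSE
    )
    out[sample.int(nrow(out)), , drop = FALSE]
  })
}

# Fast equivalent-in-distribution path: per-level "comparison further" counts
# (easy trials omitted; they are excluded from fits anyway). Used by the
# power and replicate-study machinery.
simulate_counts <- function(obs, spec, design = depth_design(),
                            n_reps = NULL, seed = NULL,
                            lapse_convention = c("further", "guess")) {
  lapse_convention <- match.arg(lapse_convention)
  if (is.character(spec)) spec <- condition_spec(spec)
  with_seed(seed, {
    n_reps <- if (is.null(n_reps)) design$n_reps else as.integer(n_reps)
    delta <- conflict_delta_true(obs, spec, design$conflict_mult)
    psi <- response_prob(obs, spec, design$x, 0, delta,
                         lapse_convention = lapse_convention)
    data.frame(x = design$x, k = stats::rbinom(length(design$x), n_reps, psi),
               n = n_reps)
  })
}
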
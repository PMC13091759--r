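# Multi-participant, multi-session study simulation with a between- vs
# within-observer variance structure, for exercising the full pipeline and
# the repeatability analysis.

#' Population specification for a simulated study
#'
#' Per-observer single-cue noises are drawn around the population means with
#' between-observer spread `sd_between`; each session re-perturbs them with
#' within-observer spread `sd_within` (both on the natural scale, floored at
#' `sigma_floor` to stay positive). Lapse rates are uniform on `lapse_range`;
#' strategies and the novel-cue binding belief are sampled per observer; the
#' audio mapping direction is counterbalanced.
#'
#' @param n Number of participants.
#' @param sigma_D,sigma_S,sigma_A Population-mean single-cue noises.
#' @param du_factor Noise inflation of the degraded-disparity variant.
#' @param sd_between,sd_within Between-observer and within-observer
#'   (session-to-session) standard deviations of each noise parameter.
#' @param lapse_range Range of the uniform per-observer lapse distribution.
#' @param strategy_probs Named probabilities over
#'   `c("optimal-averaging", "best-single-cue", "switching")`.
#' @param binds_novel_prob Probability that an observer fuses the novel
#'   (audio) pairing.
#' @param sigma_floor Lower bound applied after Gaussian perturbation.
#' @export
population_spec <- function(n = 20L, sigma_D = 0.25, sigma_S = 0.30,
                            sigma_A = 0.30, du_factor = 2,
                            sd_between = 0.05, sd_within = 0.015,
                            lapse_range = c(0, 0.06),
                            strategy_probs = c("optimal-averaging" = 1),
                            binds_novel_prob = 1, sigma_floor = 0.03) {
  stopifnot(n >= 1L, sigma_floor > 0)
  strategies <- c("optimal-averaging", "best-single-cue", "switching")
  if (is.null(names(strategy_probs)) ||
      !all(names(strategy_probs) %in% strategies)) {
    stop("`strategy_probs` must be named with known strategies", call. = FALSE)
  }
  structure(list(n = as.integer(n), sigma_D = sigma_D, sigma_S = sigma_S,
                 sigma_A = sigma_A, du_factor = du_factor,
                 sd_between = sd_between, sd_within = sd_within,
                 lapse_range = lapse_range,
                 strategy_probs = strategy_probs / sum(strategy_probs),
                 binds_novel_prob = binds_novel_prob,
                 sigma_floor = sigma_floor),
            class = "population_spec")
}

#' Simulate a complete multi-session study
#'
#' Draws a cohort from a [population_spec()] and simulates every condition of
#' every session in `schedule` for every participant, using one master seed
#' with deterministic per-participant substreams.
#'
#' @param pop A [population_spec()].
#' @param schedule Named list: session number -> character vector of
#'   condition labels (default [default_schedule()]).
#' @param design A [depth_design()].
#' @param seed Master seed.
#' @param lapse_convention See [response_prob()].
#' @return A trial table (see [simulate_trials()]); the generative
#'   per-participant truth is attached as `attr(x, "truth")`.
#' @export
simulate_study <- function(pop = population_spec(),
                           schedule = default_schedule(),
                           design = depth_design(), seed = NULL,
                           lapse_convention = c("further", "guess")) {
  lapse_convention <- match.arg(lapse_convention)
  base_seed <- if (is.null(seed)) sample.int(2^30, 1) else seed
  floor_pos <- function(v) pmax(v, pop$sigma_floor)
  strategies <- names(pop$strategy_probs)
  out <- vector("list", 0L)
  truth <- vector("list", 0L)
  for (i in seq_len(pop$n)) {
    pid <- sprintf("P%03d", i)
    with_seed(substream_seed(base_seed, i), {
      base <- c(D = floor_pos(pop$sigma_D + stats::rnorm(1, 0, pop$sd_between)),
                S = floor_pos(pop$sigma_S + stats::rnorm(1, 0, pop$sd_between)),
                A = floor_pos(pop$sigma_A + stats::rnorm(1, 0, pop$sd_between)))
      lapse <- stats::runif(1, pop$lapse_range[1], pop$lapse_range[2])
      strategy <- sample(strategies, 1, prob = pop$strategy_probs)
      binds <- stats::runif(1) < pop$binds_novel_prob
      mapdir <- if (i %% 2L == 0L) -1 else 1
      for (sess in names(schedule)) {
        sd_w <- if (length(schedule) > 1L) pop$sd_within else 0
        ses_sig <- vapply(base, function(v) {
          floor_pos(v + stats::rnorm(1, 0, sd_w))
        }, numeric(1))
        obs <- observer_profile(
          sigma_D = ses_sig[["D"]], sigma_S = ses_sig[["S"]],
          sigma_A = ses_sig[["A"]], du_factor = pop$du_factor,
          lapse = lapse, strategy = strategy,
          mapping_direction = mapdir, binds_novel_cue = binds)
        truth[[length(truth) + 1L]] <- data.frame(
          participant = pid, session = as.integer(sess),
          sigma_D = obs$sigma_D, sigma_S = obs$sigma_S, sigma_A = obs$sigma_A,
          sigma_Du = obs$sigma_Du, lapse = lapse, strategy = strategy,
          mapping_direction = mapdir, binds_novel_cue = binds,
          stringsAsFactors = FALSE)
        for (cn in schedule[[sess]]) {
          out[[length(out) + 1L]] <- simulate_trials(
            obs, condition_spec(cn), design,
            participant = pid, session = as.integer(sess),
            lapse_convention = lapse_convention)
        }
      }
    })
  }
  trials <- do.call(rbind, out)
  rownames(trials) <- NULL
  attr(trials, "truth") <- do.call(rbind, truth)
  trials
}
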
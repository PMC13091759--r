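# User-facing fitting layer: trial tables in, fit tables out.
#
# The two-stage procedure: (1) for each participant x session, a single
# lapse rate is estimated jointly across that session's conditions, with each
# condition's slope (and PSE, for conflict conditions) integrated out;
# (2) each condition is then refitted with the lapse fixed at the stage-1
# value, the PSE fixed at 0 except in conflict conditions (where it may vary
# over [-1, 1]), and the slope summarised by its posterior mean.

# Coarser grid used only for integrating nuisance slopes/PSEs inside the
# stage-1 lapse estimate; the lapse grid itself is kept at full resolution.
pf_stage1_grid <- function(grid = pf_grid()) {
  pf_grid(n_beta = 41, beta_range = c(0.1, 100),
          n_alpha = 17, alpha_range = range(grid$alpha),
          n_lambda = length(grid$lambda), lambda_range = range(grid$lambda))
}

# Recode raw "second interval further" responses to comparison-relative
# responses using the interval order (1 = reference first). Tables without
# an `order` column are taken to be comparison-relative already.
recode_responses <- function(trials) {
  if ("order" %in% names(trials)) {
    ifelse(trials$order == 1L, trials$response, 1L - trials$response)
  } else {
    trials$response
  }
}

# Aggregate one condition's trials to per-level counts.
trial_counts <- function(trials, include_easy = FALSE) {
  if (!include_easy && "easy" %in% names(trials)) {
    trials <- trials[!trials$easy, , drop = FALSE]
  }
  r <- recode_responses(trials)
  x <- sort(unique(trials$comparison_level))
  k <- vapply(x, function(v) sum(r[trials$comparison_level == v]), numeric(1))
  n <- vapply(x, function(v) sum(trials$comparison_level == v), numeric(1))
  data.frame(x = x, k = k, n = n)
}

#' Estimate a shared lapse rate across conditions (stage 1)
#'
#' Fits one lapse rate jointly across all conditions of one participant and
#' session: per condition, the slope (and the PSE, in conflict conditions) is
#' integrated out against its uniform prior, and the shared lapse posterior
#' is the product of the per-condition marginals, summarised by its mean.
#'
#' @param trials Trial table for one participant x session (several
#'   conditions).
#' @param grid A [pf_grid()]; the lapse is estimated at this grid's lambda
#'   resolution.
#' @param include_easy Include easy catch trials (default FALSE).
#' @param lapse_convention See [psi()].
#' @return A list with `lambda` (posterior mean, in the grid's lambda range),
#'   `n_conditions`, and `flag` (`"degenerate"` when every response is
#'   identical).
#' @export
fit_shared_lapse <- function(trials, grid = pf_grid(), include_easy = FALSE,
                             lapse_convention = c("further", "guess")) {
  lapse_convention <- match.arg(lapse_convention)
  conds <- unique(trials$condition)
  counts <- lapply(conds, function(cn) {
    trial_counts(trials[trials$condition == cn, , drop = FALSE], include_easy)
  })
  enough <- vapply(counts, function(cc) nrow(cc) >= 2L, logical(1))
  if (sum(enough) < 2L) {
    stop("shared-lapse fit needs >= 2 conditions with >= 2 levels each",
         call. = FALSE)
  }
  conds <- conds[enough]; counts <- counts[enough]
  s1 <- pf_stage1_grid(grid)
  afree <- vapply(conds, function(cn) condition_spec(cn)$alpha_free, logical(1))
  blocks <- list()
  for (af in unique(afree)) {
    idx <- which(afree == af)
    xs <- counts[[idx[1]]]$x
    same <- vapply(idx, function(i) identical(counts[[i]]$x, xs), logical(1))
    for (grp in split(idx, same)) { # conditions sharing a level grid batch together
      for (i in grp) {
        cc <- counts[[i]]
        tb <- pf_tables(cc$x, s1, alpha_free = af,
                        lapse_convention = lapse_convention)
        blocks[[length(blocks) + 1L]] <-
          list(K1 = matrix(cc$k, 1L), K0 = matrix(cc$n - cc$k, 1L),
               tables = tb, unit = "u")
      }
    }
  }
  lam <- unname(pf_shared_lambda(blocks))
  all_r <- unlist(lapply(counts, function(cc) c(cc$k, cc$n - cc$k)))
  degen <- all(vapply(counts, function(cc) all(cc$k == cc$n), logical(1))) ||
    all(vapply(counts, function(cc) all(cc$k == 0), logical(1)))
  if (degen) {
    warning("degenerate data: all responses identical; lapse at boundary",
            call. = FALSE)
  }
  list(lambda = lam, n_conditions = length(conds),
       flag = if (degen) "degenerate" else "")
}

#' Fit one condition's psychometric function with a fixed lapse (stage 2)
#'
#' Posterior-mean slope (and PSE, if `alpha_free`) under uniform priors, with
#' the lapse fixed at the stage-1 estimate (snapped to the lapse grid).
#' Easy catch trials are excluded by default.
#'
#' @param trials Trial table for one condition (or a data frame of counts
#'   with columns `x`, `k`, `n`).
#' @param lambda Fixed lapse rate (from [fit_shared_lapse()]).
#' @param alpha_free Allow the PSE to vary over the alpha grid (conflict
#'   conditions); when `NULL`, inferred from the condition label.
#' @param grid A [pf_grid()].
#' @param point Posterior summary: `"mean"` (default) or `"mode"`.
#' @param ci Compute 95% credible intervals (default TRUE).
#' @param min_trials Refuse to fit fewer usable trials than this (default 20).
#' @inheritParams fit_shared_lapse
#' @return One-row data frame: `alpha`, `beta`, `lambda`, `sigma`, `jnd`,
#'   `alpha_fixed`, credible bounds, `n_trials`, `flag`.
#' @export
fit_condition <- function(trials, lambda, alpha_free = NULL, grid = pf_grid(),
                          point = c("mean", "mode"), ci = TRUE,
                          min_trials = 20L, include_easy = FALSE,
                          lapse_convention = c("further", "guess")) {
  point <- match.arg(point)
  lapse_convention <- match.arg(lapse_convention)
  if (all(c("x", "k", "n") %in% names(trials))) {
    cc <- trials
  } else {
    if (is.null(alpha_free) && "condition" %in% names(trials)) {
      alpha_free <- condition_spec(trials$condition[1])$alpha_free
    }
    cc <- trial_counts(trials, include_easy)
  }
  if (is.null(alpha_free)) alpha_free <- FALSE
  if (sum(cc$n) < min_trials) {
    stop(sprintf("too few usable trials (%d < %d)", sum(cc$n), min_trials),
         call. = FALSE)
  }
  tb <- pf_tables(cc$x, grid, alpha_free = alpha_free,
                  lapse_convention = lapse_convention)
  li <- snap_lambda(lambda, grid)
  ft <- pf_fit_rows(matrix(cc$k, 1L), matrix(cc$n - cc$k, 1L), tb,
                    lambda_idx = li, point = point, ci = ci)
  degen <- all(cc$k == cc$n) || all(cc$k == 0)
  flag <- paste(c(if (nzchar(ft$flag)) ft$flag, if (degen) "degenerate"),
                collapse = ";")
  data.frame(
    alpha = if (alpha_free) ft$alpha else 0,
    beta = ft$beta,
    lambda = grid$lambda[li],
    sigma = 1 / (ft$beta * sqrt(2)),
    jnd = 1 / ft$beta,
    alpha_fixed = !alpha_free,
    alpha_lo = ft$alpha_lo, alpha_hi = ft$alpha_hi,
    beta_lo = ft$beta_lo, beta_hi = ft$beta_hi,
    n_trials = sum(cc$n),
    flag = flag,
    stringsAsFactors = FALSE
  )
}

#' Fit a whole study: two-stage fits for every participant, session, condition
#'
#' Runs [fit_shared_lapse()] per participant x session and then
#' [fit_condition()] per condition with the session's lapse fixed. Conditions
#' whose label carries a conflict sign get a free PSE.
#'
#' @param trials A trial table (multiple participants/sessions/conditions).
#' @param lapse `"shared"` (two-stage, default), `"free"` (single-stage
#'   three-parameter fit per condition), or `"fixed"` (use `lapse_value`).
#' @param lapse_value Lapse used when `lapse = "fixed"`.
#' @inheritParams fit_condition
#' @return A fits data frame with one row per participant x session x
#'   condition.
#' @export
fit_study <- function(trials, grid = pf_grid(),
                      lapse = c("shared", "free", "fixed"), lapse_value = 0.02,
                      point = c("mean", "mode"), ci = FALSE,
                      min_trials = 20L, include_easy = FALSE,
                      lapse_convention = c("further", "guess")) {
  lapse <- match.arg(lapse)
  point <- match.arg(point)
  lapse_convention <- match.arg(lapse_convention)
  out <- list()
  for (p in unique(trials$participant)) {
    tp <- trials[trials$participant == p, , drop = FALSE]
    for (s in unique(tp$session)) {
      ts <- tp[tp$session == s, , drop = FALSE]
      lam <- switch(lapse,
        fixed = lapse_value,
        free = NA_real_,
        shared = fit_shared_lapse(ts, grid, include_easy,
                                  lapse_convention)$lambda)
      for (cn in unique(ts$condition)) {
        tc <- ts[ts$condition == cn, , drop = FALSE]
        af <- condition_spec(cn)$alpha_free
        row <- if (lapse == "free") {
          cc <- trial_counts(tc, include_easy)
          tb <- pf_tables(cc$x, grid, alpha_free = af,
                          lapse_convention = lapse_convention)
          ft <- pf_fit_rows_free_lambda(matrix(cc$k, 1L),
                                        matrix(cc$n - cc$k, 1L), tb)
          data.frame(alpha = if (af) ft$alpha else 0, beta = ft$beta,
                     lambda = ft$lambda, sigma = 1 / (ft$beta * sqrt(2)),
                     jnd = 1 / ft$beta, alpha_fixed = !af,
                     alpha_lo = NA_real_, alpha_hi = NA_real_,
                     beta_lo = NA_real_, beta_hi = NA_real_,
                     n_trials = sum(cc$n), flag = ft$flag,
                     stringsAsFactors = FALSE)
        } else {
          fit_condition(tc, lam, alpha_free = af, grid = grid, point = point,
                        ci = ci, min_trials = min_trials,
                        include_easy = include_easy,
                        lapse_convention = lapse_convention)
        }
        row <- cbind(data.frame(participant = p, session = as.integer(s),
                                condition = cn, stringsAsFactors = FALSE),
                     row)
        row$lambda_source <- switch(lapse, shared = "shared-stage",
                                    free = "free", fixed = "fixed")
        out[[length(out) + 1L]] <- row
      }
    }
  }
  do.call(rbind, out)
}
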
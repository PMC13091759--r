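# Group-level inference: exclusion rules, the combination / re-weighting /
# incongruence hypothesis tests, cue-pair comparisons with classification
# counts and McNemar's test, and the nuisance-cue control comparison.

# Two-sided outlier fence: |x - median| > mult * IQR. The degenerate
# IQR = 0 case excludes nothing.
iqr_fence <- function(x, mult = 2.5) {
  iqr <- stats::IQR(x, na.rm = TRUE)
  if (!is.finite(iqr) || iqr == 0) return(rep(FALSE, length(x)))
  out <- abs(x - stats::median(x, na.rm = TRUE)) > mult * iqr
  out & !is.na(x)
}

#' Apply the study's exclusion rules
#'
#' * Participants whose session lapse estimates average 0.10 or more are
#'   excluded from all analyses.
#' * Disparity-noise outliers (beyond `median +/- fence_mult * IQR` of the
#'   group) are excluded from all analyses; size- or audio-noise and weight
#'   outliers only from their cue pair.
#' * Participants whose fitted audio slope opposes the trained mapping
#'   direction ("inverse mapping") are excluded from the audio cue pair.
#'
#' @param metrics Metrics table from [compute_metrics()].
#' @param fits Fits table from [fit_study()] (for lapse and audio-mapping
#'   checks); may be `NULL` to skip those rules.
#' @param fence_mult IQR multiplier (default 2.5).
#' @param lapse_cut Across-session lapse threshold (default 0.10).
#' @param inverse_participants Participants flagged by
#'   [detect_inverse_mapping()] (excluded from the DA pair).
#' @return A list: `metrics` (filtered), `report` (data frame naming each
#'   excluded participant, rule and scope).
#' @export
apply_exclusions <- function(metrics, fits = NULL, fence_mult = 2.5,
                             lapse_cut = 0.10,
                             inverse_participants = character(0)) {
  if (length(unique(metrics$participant)) < 4L) {
    stop("exclusion rules need a group of >= 4 participants", call. = FALSE)
  }
  report <- list()
  note <- function(p, rule, scope) {
    report[[length(report) + 1L]] <<- data.frame(
      participant = p, rule = rule, scope = scope, stringsAsFactors = FALSE)
  }
  drop_all <- character(0)
  drop_pair <- list(DS = character(0), DA = character(0))

  if (!is.null(fits)) {
    lam <- stats::aggregate(lambda ~ participant + session, data = fits,
                            FUN = function(v) v[1])
    lam_p <- tapply(lam$lambda, lam$participant, mean)
    for (p in names(lam_p)[lam_p >= lapse_cut]) {
      drop_all <- c(drop_all, p); note(p, "lapse>=0.10 across sessions", "all")
    }
  }
  for (p in unique(inverse_participants)) {
    drop_pair$DA <- c(drop_pair$DA, p); note(p, "inverse mapping", "DA")
  }

  fence_measures <- list(
    list(col = "sigma_D", scope = "all", rule = "disparity noise outlier"),
    list(col = "sigma_2", scope = "pair", rule = "paired-cue noise outlier"),
    list(col = "w_emp_normal", scope = "pair", rule = "weight outlier"),
    list(col = "w_emp_noisy", scope = "pair", rule = "weight outlier")
  )
  for (pr in c("DS", "DA")) {
    m <- metrics[metrics$cue_pair == pr, , drop = FALSE]
    if (nrow(m) == 0L) next
    for (fm in fence_measures) {
      if (!fm$col %in% names(m)) next
      bad <- m$participant[iqr_fence(m[[fm$col]], fence_mult)]
      for (p in bad) {
        if (fm$scope == "all") {
          drop_all <- c(drop_all, p)
          note(p, fm$rule, "all")
        } else {
          drop_pair[[pr]] <- c(drop_pair[[pr]], p)
          note(p, fm$rule, pr)
        }
      }
    }
  }
  keep <- !(metrics$participant %in% unique(drop_all))
  for (pr in c("DS", "DA")) {
    keep <- keep & !(metrics$cue_pair == pr &
                       metrics$participant %in% unique(drop_pair[[pr]]))
  }
  filtered <- metrics[keep, , drop = FALSE]
  if (nrow(filtered) == 0L) {
    stop("all participants excluded; check the input metrics", call. = FALSE)
  }
  report <- if (length(report)) unique(do.call(rbind, report)) else
    data.frame(participant = character(0), rule = character(0),
               scope = character(0))
  list(metrics = filtered, report = report)
}

#' Detect inverse audio-mapping learners from raw trials
#'
#' The sign of the audio psychometric slope is read directly from the
#' audio-only condition: a negative rank correlation between comparison level
#' and the comparison-relative response means depth-to-pitch was learned
#' backwards. (The Bayesian fits constrain the slope to be positive, so the
#' sign must be checked on the raw data.)
#'
#' @param trials A trial table containing condition `"A"`.
#' @return Character vector of participants with an inverse mapping.
#' @export
detect_inverse_mapping <- function(trials) {
  ta <- trials[trials$condition == "A" & !trials$easy, , drop = FALSE]
  if (nrow(ta) == 0L) return(character(0))
  ta$r <- recode_responses(ta)
  out <- character(0)
  for (p in unique(ta$participant)) {
    tp <- ta[ta$participant == p, , drop = FALSE]
    rho <- suppressWarnings(
      stats::cor(tp$comparison_level, tp$r, method = "spearman"))
    if (is.finite(rho) && rho < 0) out <- c(out, p)
  }
  out
}

mk_result <- function(hypothesis, statistic, p, n, direction,
                      stat_name = "V") {
  data.frame(hypothesis = hypothesis, stat = unname(statistic),
             stat_name = stat_name, p = unname(p), n = n,
             direction = direction, stringsAsFactors = FALSE)
}

paired_wilcox <- function(a, b, hypothesis, labels) {
  ok <- stats::complete.cases(a, b)
  a <- a[ok]; b <- b[ok]
  if (length(a) < 6L) stop("paired test needs >= 6 observations", call. = FALSE)
  d <- a - b
  if (all(d == 0)) {
    return(mk_result(hypothesis, 0, 1, length(a), "none"))
  }
  wt <- suppressWarnings(stats::wilcox.test(a, b, paired = TRUE))
  dir <- if (stats::median(d) < 0) labels[1] else labels[2]
  mk_result(hypothesis, wt$statistic, wt$p.value, length(a), dir)
}

#' Cue-combination tests (bimodal vs best single cue, and vs optimal)
#'
#' Two-tailed Wilcoxon signed-rank tests of the bimodal sensory noise against
#' (a) the better single cue and (b) the maximum-likelihood optimal
#' prediction, per cue pair.
#'
#' @param metrics Metrics table (post-exclusion).
#' @param cue_pair `"DS"` or `"DA"`.
#' @return A two-row results data frame.
#' @export
test_combination <- function(metrics, cue_pair = c("DS", "DA")) {
  cue_pair <- match.arg(cue_pair)
  m <- metrics[metrics$cue_pair == cue_pair, , drop = FALSE]
  best <- pmin(m$sigma_D, m$sigma_2)
  rbind(
    paired_wilcox(m$sigma_bi, best,
                  paste0("combination:", cue_pair, ":vs-best"),
                  c("bimodal lower", "bimodal higher")),
    paired_wilcox(m$sigma_bi, m$sigma_opt,
                  paste0("combination:", cue_pair, ":vs-optimal"),
                  c("below optimal", "above optimal"))
  )
}

#' Re-weighting tests (weight drop, drop vs optimal drop, regression)
#'
#' Wilcoxon signed-rank of the empirical disparity weight with vs without
#' added disparity noise; Wilcoxon of the empirical weight drop against the
#' reliability-predicted drop; and the OLS regression/correlation of
#' empirical on predicted weights.
#'
#' @inheritParams test_combination
#' @return A results data frame (three Wilcoxon/regression rows).
#' @export
test_reweighting <- function(metrics, cue_pair = c("DS", "DA")) {
  cue_pair <- match.arg(cue_pair)
  m <- metrics[metrics$cue_pair == cue_pair, , drop = FALSE]
  res <- rbind(
    paired_wilcox(m$w_emp_normal, m$w_emp_noisy,
                  paste0("reweighting:", cue_pair, ":weight-drop"),
                  c("weight rises", "weight drops")),
    paired_wilcox(m$w_emp_normal - m$w_emp_noisy,
                  m$w_pred_normal - m$w_pred_noisy,
                  paste0("reweighting:", cue_pair, ":vs-optimal-drop"),
                  c("smaller than optimal", "larger than optimal"))
  )
  ok <- stats::complete.cases(m$w_emp_normal, m$w_pred_normal)
  if (sum(ok) >= 3L) {
    fit <- stats::lm(w_emp_normal ~ w_pred_normal, data = m[ok, ])
    sm <- summary(fit)$coefficients
    r <- stats::cor(m$w_pred_normal[ok], m$w_emp_normal[ok])
    res <- rbind(res,
      mk_result(paste0("reweighting:", cue_pair, ":regression"),
                sm["w_pred_normal", "Estimate"],
                sm["w_pred_normal", "Pr(>|t|)"], sum(ok),
                sprintf("r=%.3f", r), stat_name = "slope"))
  }
  res
}

#' Incongruence-sensitivity test
#'
#' Two-tailed Wilcoxon signed-rank of the incongruent condition's sensory
#' noise against the congruent condition's.
#'
#' @inheritParams test_combination
#' @export
test_incongruence <- function(metrics, cue_pair = c("DS", "DA")) {
  cue_pair <- match.arg(cue_pair)
  m <- metrics[metrics$cue_pair == cue_pair, , drop = FALSE]
  paired_wilcox(m$sigma_inc, m$sigma_bi,
                paste0("incongruence:", cue_pair),
                c("incongruent lower", "incongruent higher"))
}

#' Continuity-corrected McNemar statistic from discordant counts
#'
#' `chi^2 = max(|b - c| - 1, 0)^2 / (b + c)` for the two discordant cells of
#' a paired 2x2 classification; undefined (NA, with a flag) when
#' `b + c = 0`. The correction is clamped at zero so equal discordant counts
#' give chi-square 0 and p = 1, matching the exact binomial null (the
#' unclamped textbook form overcorrects past zero there).
#'
#' @param b,c Discordant cell counts.
#' @return A list with `chisq`, `p`, and `defined`.
#' @export
mcnemar_cc <- function(b, c) {
  if (b + c == 0) return(list(chisq = NA_real_, p = NA_real_, defined = FALSE))
  chisq <- max(abs(b - c) - 1, 0)^2 / (b + c)
  list(chisq = chisq, p = stats::pchisq(chisq, 1, lower.tail = FALSE),
       defined = TRUE)
}

#' Compare markers between cue pairs
#'
#' Paired Wilcoxon tests of each index (CI, RI, IS) between the familiar
#' (DS) and novel (DA) pairs; a both/only-DS/only-DA/neither classification
#' per marker (present = index > 0) with McNemar's continuity-corrected test
#' on the discordant cells; and the Pearson correlation of CI between pairs.
#'
#' @param metrics Metrics table (post-exclusion), containing both cue pairs.
#' @return A list: `tests` (Wilcoxon rows), `classification` (per-marker
#'   counts with McNemar results), `ci_correlation`.
#' @export
compare_pairs <- function(metrics) {
  ds <- metrics[metrics$cue_pair == "DS", , drop = FALSE]
  da <- metrics[metrics$cue_pair == "DA", , drop = FALSE]
  common <- intersect(ds$participant, da$participant)
  ds <- ds[match(common, ds$participant), , drop = FALSE]
  da <- da[match(common, da$participant), , drop = FALSE]
  tests <- list(); cls <- list()
  for (idx in c("CI", "RI", "IS")) {
    a <- ds[[idx]]; b <- da[[idx]]
    ok <- stats::complete.cases(a, b)
    if (sum(ok) >= 6L) {
      tests[[idx]] <- paired_wilcox(a[ok], b[ok],
                                    paste0("pair-difference:", idx),
                                    c("DA larger", "DS larger"))
    }
    pos_ds <- a[ok] > 0; pos_da <- b[ok] > 0
    counts <- c(both = sum(pos_ds & pos_da),
                only_DS = sum(pos_ds & !pos_da),
                only_DA = sum(!pos_ds & pos_da),
                neither = sum(!pos_ds & !pos_da))
    mn <- mcnemar_cc(counts[["only_DS"]], counts[["only_DA"]])
    cls[[idx]] <- data.frame(marker = idx, t(counts), n = sum(ok),
                             chisq = mn$chisq, p = mn$p,
                             mcnemar_defined = mn$defined)
  }
  okci <- stats::complete.cases(ds$CI, da$CI)
  r <- if (sum(okci) >= 3L) stats::cor.test(ds$CI[okci], da$CI[okci]) else NULL
  list(tests = do.call(rbind, tests),
       classification = do.call(rbind, cls),
       ci_correlation = if (is.null(r)) NULL else
         data.frame(r = unname(r$estimate), p = r$p.value, n = sum(okci)))
}

#' Nuisance-cue control comparison
#'
#' One-sided test of whether sensory noise in the standard condition (second
#' cue present but fixed) exceeds the control condition (second cue removed),
#' plus a default-prior (JZS) Bayes factor in favour of the null on the
#' paired differences. The study design is within-observer, so the default
#' test is a signed-rank test; a rank-sum option is provided.
#'
#' @param sigma_standard,sigma_control Per-observer sensory noise estimates.
#' @param test `"signed-rank"` (paired, default) or `"rank-sum"`.
#' @param bf_scale Cauchy prior scale for the JZS Bayes factor
#'   (default `sqrt(2)/2`).
#' @return A one-row data frame with the one-sided p and `BF01`.
#' @export
nuisance_control <- function(sigma_standard, sigma_control,
                             test = c("signed-rank", "rank-sum"),
                             bf_scale = sqrt(2) / 2) {
  test <- match.arg(test)
  ok <- stats::complete.cases(sigma_standard, sigma_control)
  a <- sigma_standard[ok]; b <- sigma_control[ok]
  if (length(a) < 5L) stop("nuisance control needs n >= 5", call. = FALSE)
  wt <- if (test == "signed-rank") {
    suppressWarnings(stats::wilcox.test(a, b, paired = TRUE,
                                        alternative = "greater"))
  } else {
    suppressWarnings(stats::wilcox.test(a, b, alternative = "greater"))
  }
  bf01 <- 1 / jzs_bf10_ttest(a - b, scale = bf_scale)
  data.frame(test = test, stat = unname(wt$statistic), p = wt$p.value,
             n = length(a), BF01 = bf01, stringsAsFactors = FALSE)
}
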
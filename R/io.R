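# Interchange formats (CSV), YAML configuration, the end-to-end pipeline,
# and named regression fixtures.

trial_cols <- c("participant", "session", "condition", "mapping_direction",
                "side", "comparison_level", "conflict_sign", "order", "easy",
                "response")

#' Write / read a trial table
#'
#' One header row, UTF-8, `response` coded 0/1 with 1 = "second interval
#' further"; `order` = 1 means the reference came first.
#' @param trials A trial table.
#' @param path CSV path.
#' @export
write_trials <- function(trials, path) {
  missing <- setdiff(trial_cols, names(trials))
  if (length(missing)) {
    stop("trial table lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  utils::write.csv(trials[trial_cols], path, row.names = FALSE,
                   fileEncoding = "UTF-8")
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  tr <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  missing <- setdiff(trial_cols, names(tr))
  if (length(missing)) {
    stop("trial CSV lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  tr$participant <- as.character(tr$participant)
  tr$easy <- as.logical(tr$easy)
  tr
}

#' Write / read a fits table
#' @param fits A fits table from [fit_study()].
#' @param path CSV path.
#' @export
write_fits <- function(fits, path) {
  utils::write.csv(fits, path, row.names = FALSE, fileEncoding = "UTF-8")
}

#' @rdname write_fits
#' @export
read_fits <- function(path) {
  f <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  f$participant <- as.character(f$participant)
  f$flag[is.na(f$flag)] <- ""
  f
}

#' Write / read a metrics table
#' @param metrics A metrics table from [compute_metrics()].
#' @param path CSV path.
#' @export
write_metrics <- function(metrics, path) {
  utils::write.csv(metrics, path, row.names = FALSE, fileEncoding = "UTF-8")
}

#' @rdname write_metrics
#' @export
read_metrics <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  m$participant <- as.character(m$participant)
  m
}

#' Default pipeline configuration
#'
#' All design constants default to the study values: 14 comparison levels at
#' +/-0.10..1.00, 12 repetitions, 4% easy trials, conflicts of 1.5 JND,
#' lapse prior range [0, 0.2], PSE range [-1, 1].
#' @param n Participants in the simulated cohort.
#' @param seed Master seed.
#' @export
default_config <- function(n = 12L, seed = 1L) {
  list(
    seed = seed,
    design = list(levels = c(0.10, 0.25, 0.40, 0.55, 0.70, 0.85, 1.00),
                  n_reps = 12L, easy_rate = 0.04, conflict_mult = 1.5),
    population = list(n = n, sigma_D = 0.25, sigma_S = 0.30, sigma_A = 0.30,
                      du_factor = 2, sd_between = 0.05, sd_within = 0.015,
                      lapse_range = c(0, 0.06),
                      strategy_probs = c(`optimal-averaging` = 1)),
    schedule = default_schedule(),
    fit = list(lapse = "shared", lapse_convention = "further"),
    analysis = list(fence_mult = 2.5, lapse_cut = 0.10),
    repeatability = list(measure = "sigma_bi", n_boot = 500L, n_perm = 200L),
    power = NULL
  )
}

#' Read / write a pipeline configuration (YAML)
#' @param path YAML file path.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- default_config()
  for (nm in names(base)) if (is.null(cfg[[nm]])) cfg[[nm]] <- base[[nm]]
  sp <- cfg$population$strategy_probs
  if (!is.null(sp) && is.list(sp)) {
    cfg$population$strategy_probs <- unlist(sp)
  }
  cfg
}

#' @rdname read_config
#' @param config A configuration list.
#' @export
write_config <- function(config, path) {
  sp <- config$population$strategy_probs
  if (!is.null(sp) && !is.list(sp)) {
    config$population$strategy_probs <- as.list(sp)   # keep names in YAML
  }
  yaml::write_yaml(config, path)
}

config_to_objects <- function(config) {
  d <- config$design
  design <- depth_design(levels = d$levels, n_reps = d$n_reps,
                         easy_rate = d$easy_rate,
                         conflict_mult = d$conflict_mult)
  pop <- do.call(population_spec, config$population)
  list(design = design, pop = pop, schedule = config$schedule)
}

#' Run the full pipeline: simulate, fit, metrics, group analysis, repeatability
#'
#' Deterministic given the config's seed. Writes `trials.csv`, `fits.csv`,
#' `metrics.csv`, `exclusions.csv`, `analysis.md`, `repeatability.csv`
#' (plus `power.csv` when the config requests it) and a `manifest.yaml`
#' recording the seed and configuration.
#'
#' @param config A configuration list (see [default_config()]).
#' @param out_dir Output directory (created if needed).
#' @param quiet Suppress stage messages.
#' @return Invisibly, a list with the in-memory tables.
#' @export
run_pipeline <- function(config = default_config(), out_dir, quiet = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    r <- tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
    say("[%s] done in %.1fs", name, proc.time()[["elapsed"]] - t0)
    r
  }
  obj <- config_to_objects(config)
  trials <- stage("simulate", simulate_study(
    obj$pop, obj$schedule, obj$design, seed = config$seed,
    lapse_convention = config$fit$lapse_convention))
  write_trials(trials, file.path(out_dir, "trials.csv"))
  fits <- stage("fit", fit_study(
    trials, lapse = config$fit$lapse,
    lapse_convention = config$fit$lapse_convention))
  write_fits(fits, file.path(out_dir, "fits.csv"))
  metrics <- stage("markers", compute_metrics(
    fits, conflict_mult = obj$design$conflict_mult))
  write_metrics(metrics, file.path(out_dir, "metrics.csv"))
  excl <- stage("exclusions", apply_exclusions(
    metrics, fits, fence_mult = config$analysis$fence_mult,
    lapse_cut = config$analysis$lapse_cut,
    inverse_participants = detect_inverse_mapping(trials)))
  utils::write.csv(excl$report, file.path(out_dir, "exclusions.csv"),
                   row.names = FALSE)
  analysis <- stage("analyze", analysis_report(excl$metrics))
  writeLines(analysis$text, file.path(out_dir, "analysis.md"))

  rep_res <- NULL
  rp <- config$repeatability
  if (!is.null(rp)) {
    measure <- rp$measure
    rows <- stats::complete.cases(fits$sigma) & fits$condition == "DS"
    long <- data.frame(participant = fits$participant[rows],
                       session = fits$session[rows],
                       value = fits$sigma[rows])
    if (length(unique(long$participant)) >= 10L &&
        length(unique(long$session)) >= 2L) {
      rep_res <- stage("repeatability", fit_repeatability(
        long, n_boot = rp$n_boot, n_perm = rp$n_perm,
        seed = substream_seed(config$seed, 999L)))
      utils::write.csv(
        data.frame(measure = "sigma_DS", R = rep_res$R,
                   ci_lo = rep_res$ci[1], ci_hi = rep_res$ci[2],
                   d_LRR = rep_res$d_LRR, p_lrt = rep_res$p_lrt,
                   p_perm = rep_res$p_perm, converged = rep_res$converged),
        file.path(out_dir, "repeatability.csv"), row.names = FALSE)
    } else {
      say("[repeatability] skipped: needs >= 10 participants, >= 2 sessions")
    }
  }
  pw <- NULL
  if (!is.null(config$power)) {
    pw <- stage("power", do.call(power_grid, c(
      config$power, list(seed = substream_seed(config$seed, 998L)))))
    utils::write.csv(pw, file.path(out_dir, "power.csv"), row.names = FALSE)
  }
  write_config(list(seed = config$seed, config = config,
                    package_version = as.character(utils::packageVersion("cuecomb"))),
               file.path(out_dir, "manifest.yaml"))
  invisible(list(trials = trials, fits = fits, metrics = metrics,
                 exclusions = excl, analysis = analysis,
                 repeatability = rep_res, power = pw))
}

#' Human-readable group-analysis report
#'
#' Runs every applicable group test on a (post-exclusion) metrics table and
#' formats the results as markdown.
#' @param metrics Metrics table.
#' @return A list with `tables` (data frames of results) and `text`.
#' @export
analysis_report <- function(metrics) {
  tables <- list()
  lines <- c("# Group analysis", "")
  for (pr in intersect(c("DS", "DA"), unique(metrics$cue_pair))) {
    m <- metrics[metrics$cue_pair == pr, ]
    add <- function(tag, f) {
      r <- tryCatch(f, error = function(e) NULL)
      if (!is.null(r)) tables[[paste(pr, tag)]] <<- r
      r
    }
    comb <- add("combination", test_combination(metrics, pr))
    rew <- add("reweighting", test_reweighting(metrics, pr))
    inc <- add("incongruence", test_incongruence(metrics, pr))
    lines <- c(lines, sprintf("## Cue pair %s (n = %d)", pr, nrow(m)))
    for (tb in list(comb, rew, inc)) {
      if (is.null(tb)) next
      for (i in seq_len(nrow(tb))) {
        lines <- c(lines, sprintf("- %s: %s = %.3g, p = %.4g, n = %d (%s)",
                                  tb$hypothesis[i], tb$stat_name[i],
                                  tb$stat[i], tb$p[i], tb$n[i],
                                  tb$direction[i]))
      }
    }
    lines <- c(lines, "")
  }
  if (all(c("DS", "DA") %in% metrics$cue_pair)) {
    cp <- tryCatch(compare_pairs(metrics), error = function(e) NULL)
    if (!is.null(cp)) {
      tables[["pair comparison"]] <- cp
      lines <- c(lines, "## Cue-pair comparison")
      if (!is.null(cp$tests)) {
        for (i in seq_len(nrow(cp$tests))) {
          lines <- c(lines, sprintf("- %s: V = %.3g, p = %.4g (%s)",
                                    cp$tests$hypothesis[i], cp$tests$stat[i],
                                    cp$tests$p[i], cp$tests$direction[i]))
        }
      }
      for (i in seq_len(nrow(cp$classification))) {
        cl <- cp$classification[i, ]
        lines <- c(lines, sprintf(
          "- %s classification both/only-DS/only-DA/neither = %d/%d/%d/%d; McNemar chi2 = %s, p = %s",
          cl$marker, cl$both, cl$only_DS, cl$only_DA, cl$neither,
          if (cl$mcnemar_defined) sprintf("%.3g", cl$chisq) else "undefined",
          if (cl$mcnemar_defined) sprintf("%.4g", cl$p) else "-"))
      }
    }
  }
  list(tables = tables, text = lines)
}

#' Named simulation fixtures for regression testing
#'
#' Three deterministic cohorts (generated in code, fixed internal seeds):
#' `"optimal_cohort"` (everyone fuses optimally), `"switcher_cohort"`
#' (everyone switches cues trial-by-trial), and `"messy_cohort"` (a mixed
#' cohort containing a high-lapse participant and a very-high-noise
#' participant that exercise the exclusion rules).
#'
#' @param name Fixture name.
#' @return A list with `trials`, `pop`, and `description`.
#' @export
make_fixture <- function(name = c("optimal_cohort", "switcher_cohort",
                                  "messy_cohort")) {
  name <- match.arg(name)
  schedule <- list(`2` = c("D", "S", "DS", "DS+", "DS-"),
                   `3` = c("Du", "S", "DuS", "DuS+", "DuS-"))
  if (name == "optimal_cohort") {
    pop <- population_spec(n = 8L, sd_between = 0.03, sd_within = 0)
    trials <- simulate_study(pop, schedule, seed = 20001L)
    desc <- "8 optimal-averaging observers; CI > 0 expected throughout"
  } else if (name == "switcher_cohort") {
    pop <- population_spec(n = 8L, sd_between = 0.03, sd_within = 0,
                           strategy_probs = c(switching = 1))
    trials <- simulate_study(pop, schedule, seed = 20002L)
    desc <- "8 cue-switching observers; CI ~ 0, RI > 0 expected"
  } else {
    pop <- population_spec(n = 6L, sd_between = 0.02, sd_within = 0)
    trials <- simulate_study(pop, schedule, seed = 20003L)
    # graft in one high-lapse and one high-disparity-noise participant
    bad1 <- simulate_study(population_spec(n = 1L, lapse_range = c(0.15, 0.15),
                                           sd_between = 0, sd_within = 0),
                           schedule, seed = 20004L)
    bad2 <- simulate_study(population_spec(n = 1L, sigma_D = 1.6,
                                           sd_between = 0, sd_within = 0),
                           schedule, seed = 20005L)
    rename <- function(st, id) {
      tt <- attr(st, "truth")
      st$participant <- id
      tt$participant <- id
      attr(st, "truth") <- tt
      st
    }
    bad1 <- rename(bad1, "P900")
    bad2 <- rename(bad2, "P901")
    truth <- rbind(attr(trials, "truth"), attr(bad1, "truth"),
                   attr(bad2, "truth"))
    trials <- rbind(trials, bad1, bad2)
    attr(trials, "truth") <- truth
    desc <- "6 clean observers plus a high-lapse and a high-noise participant"
  }
  list(trials = trials, pop = pop, description = desc)
}
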
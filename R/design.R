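# Experimental design objects: comparison-level grid and condition labels.

#' Depth-discrimination design
#'
#' The 2IFC method-of-constants design: a reference at normalized depth 0 and
#' comparison stimuli at `+/- levels`, each repeated `n_reps` times, plus a
#' small fraction of "easy" catch trials in which the two intervals hold the
#' two most extreme depths.
#'
#' @param levels Positive comparison magnitudes (normalized units). The
#'   default is the 7-step grid 0.10 to 1.00, mirrored to 14 signed levels.
#' @param n_reps Repetitions per signed level (default 12, i.e. 168 main
#'   trials).
#' @param easy_rate Fraction of all trials that are easy catch trials
#'   (default 0.04).
#' @param physical_step_cm Physical depth per normalized unit (10 cm: the
#'   normalized range +/-1 spans 1 to 21 cm from the observer-specific
#'   reference at 11 cm).
#' @param side Whether stimuli appear in front of or behind the screen plane.
#' @param conflict_mult Cue-conflict magnitude in units of the conflicted
#'   cue's JND (default 1.5).
#' @return A `depth_design` list with the signed level grid in `$x`.
#' @export
depth_design <- function(levels = c(0.10, 0.25, 0.40, 0.55, 0.70, 0.85, 1.00),
                         n_reps = 12L,
                         easy_rate = 0.04,
                         physical_step_cm = 10,
                         side = c("front", "behind"),
                         conflict_mult = 1.5) {
  side <- match.arg(side)
  if (any(levels <= 0)) stop("`levels` must be positive magnitudes", call. = FALSE)
  if (n_reps < 1L) stop("`n_reps` must be >= 1", call. = FALSE)
  if (easy_rate < 0 || easy_rate >= 1) stop("`easy_rate` must be in [0, 1)", call. = FALSE)
  x <- c(-rev(sort(levels)), sort(levels))
  n_main <- length(x) * as.integer(n_reps)
  n_easy <- as.integer(round(easy_rate * n_main / (1 - easy_rate)))
  structure(list(levels = sort(levels), x = x, n_reps = as.integer(n_reps),
                 easy_rate = easy_rate, n_main = n_main, n_easy = n_easy,
                 physical_step_cm = physical_step_cm, side = side,
                 conflict_mult = conflict_mult, reference = 0),
            class = "depth_design")
}

#' Sensory-condition specification
#'
#' Conditions are named by their cues -- `D` (binocular disparity), `Du`
#' (disparity with added uncertainty), `S` (relative size), `A` (audio pitch)
#' -- with a trailing `+`/`-` for a cue-conflict condition (the conflict is
#' applied to the non-disparity cue of the reference stimulus) and a trailing
#' `i` for an incongruent condition (the comparison's second cue moves
#' opposite to the learned mapping).
#'
#' @param label One of `D`, `Du`, `S`, `A`, `DS`, `DA`, `DuS`, `DuA`,
#'   `DS+`, `DS-`, `DA+`, `DA-`, `DuS+`, `DuS-`, `DuA+`, `DuA-`, `DSi`, `DAi`.
#' @return A `condition_spec` with fields `cues`, `disparity_noisy`,
#'   `conflict_sign`, `incongruent`, and `alpha_free` (conflict conditions are
#'   the ones whose PSE is allowed to shift).
#' @export
condition_spec <- function(label) {
  stopifnot(is.character(label), length(label) == 1L)
  lab <- label
  conflict_sign <- 0L
  incongruent <- FALSE
  if (grepl("\\+$", lab)) { conflict_sign <- 1L;  lab <- sub("\\+$", "", lab) }
  else if (grepl("-$", lab)) { conflict_sign <- -1L; lab <- sub("-$", "", lab) }
  else if (grepl("i$", lab) && nchar(lab) > 1L) { incongruent <- TRUE; lab <- sub("i$", "", lab) }
  noisy <- grepl("^Du", lab)
  core <- sub("^Du", "D", lab)
  cues <- switch(core,
    "D" = "D", "S" = "S", "A" = "A",
    "DS" = c("D", "S"), "DA" = c("D", "A"),
    stop(sprintf("unknown condition label '%s'", label), call. = FALSE))
  if ((conflict_sign != 0L || incongruent) && length(cues) != 2L) {
    stop("conflict/incongruent conditions must be bimodal", call. = FALSE)
  }
  structure(list(label = label, cues = cues, disparity_noisy = noisy,
                 conflict_sign = conflict_sign, incongruent = incongruent,
                 alpha_free = conflict_sign != 0L),
            class = "condition_spec")
}

#' Default session schedule
#'
#' Sessions 2 and 4 test the standard single cues and congruent pairs;
#' session 2 adds the cue-conflict blocks, session 3 the noisy-disparity
#' variants (with their conflicts), and session 4 the incongruent blocks.
#' @export
default_schedule <- function() {
  list(
    `2` = c("D", "S", "A", "DS", "DA", "DS+", "DS-", "DA+", "DA-"),
    `3` = c("Du", "S", "A", "DuS", "DuA", "DuS+", "DuS-", "DuA+", "DuA-"),
    `4` = c("D", "S", "A", "DS", "DA", "DSi", "DAi")
  )
}
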
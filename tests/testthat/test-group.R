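# Group-level inference: exclusions, Wilcoxon/McNemar machinery,
# classification, and the nuisance control with its Bayes factor.

test_that("the IQR fence flags the documented toy case and nothing degenerate", {
  x <- c(0.2, 0.21, 0.22, 0.23, 5.0)
  # median 0.22, quartiles 0.21/0.23 -> fence half-width 2.5 * 0.02 = 0.05
  expect_equal(cuecomb:::iqr_fence(x), c(FALSE, FALSE, FALSE, FALSE, TRUE))
  expect_false(any(cuecomb:::iqr_fence(rep(0.3, 6))))
})

make_metrics <- function(n = 8, pair = "DS", sigma_D = NULL) {
  if (is.null(sigma_D)) sigma_D <- rep(0.25, n) + seq(0, 0.02, length.out = n)
  data.frame(participant = sprintf("P%02d", seq_len(n)), cue_pair = pair,
             sigma_D = sigma_D,
             sigma_2 = 0.3 + seq(0, 0.01, length.out = n),
             sigma_bi = 0.2, sigma_Du = 0.5, sigma_bi_noisy = 0.28,
             sigma_inc = 0.26, sigma_opt = 0.19,
             w_emp_normal = 0.6, w_emp_noisy = 0.4,
             w_pred_normal = 0.6, w_pred_noisy = 0.4,
             CI = 0.05, RI = 0.2, IS = 0.06, stringsAsFactors = FALSE)
}

test_that("exclusion rules act at the stated scopes", {
  m <- rbind(make_metrics(8, "DS"), make_metrics(8, "DA"))
  # one disparity-noise outlier (global), one size outlier (DS only)
  m$sigma_D[m$participant == "P01"] <- 3
  m$sigma_2[m$participant == "P02" & m$cue_pair == "DS"] <- 4
  fits <- data.frame(participant = rep(sprintf("P%02d", 1:8), each = 2),
                     session = rep(c(2L, 3L), 8), condition = "D",
                     lambda = 0.03, stringsAsFactors = FALSE)
  fits$lambda[fits$participant == "P03"] <- 0.12   # lapse rule, everywhere
  ex <- apply_exclusions(m, fits, inverse_participants = "P04")
  kept <- ex$metrics
  expect_false("P01" %in% kept$participant)
  expect_false("P03" %in% kept$participant)
  expect_false("P02" %in% kept$participant[kept$cue_pair == "DS"])
  expect_true("P02" %in% kept$participant[kept$cue_pair == "DA"])
  expect_false("P04" %in% kept$participant[kept$cue_pair == "DA"])
  expect_true("P04" %in% kept$participant[kept$cue_pair == "DS"])
  expect_setequal(unique(ex$report$rule),
                  c("disparity noise outlier", "paired-cue noise outlier",
                    "lapse>=0.10 across sessions", "inverse mapping"))
  expect_error(apply_exclusions(make_metrics(3)), ">= 4")
})

test_that("identical groups trigger no exclusions", {
  m <- make_metrics(6)
  ex <- apply_exclusions(m)
  expect_equal(nrow(ex$metrics), 6L)
  expect_equal(nrow(ex$report), 0L)
})

test_that("wilcox.test's exact signed-rank p matches exhaustive enumeration", {
  set.seed(501)
  for (n in c(6, 8, 10)) {
    for (rep in 1:4) {
      a <- round(rnorm(n, 0.2), 3)
      b <- round(rnorm(n), 3)
      d <- a - b
      if (any(d == 0) || any(duplicated(abs(d)))) next
      p_pkg <- suppressWarnings(wilcox.test(a, b, paired = TRUE)$p.value)
      expect_equal(p_pkg, enum_signed_rank_p(d), tolerance = 1e-12)
    }
  }
})

test_that("identical paired samples give the zero-difference convention", {
  m <- make_metrics(8)
  m$sigma_bi <- pmin(m$sigma_D, m$sigma_2)   # no benefit at all
  r <- test_combination(m, "DS")
  expect_equal(r$p[r$hypothesis == "combination:DS:vs-best"], 1)
  expect_equal(r$stat[r$hypothesis == "combination:DS:vs-best"], 0)
})

test_that("combination tests detect a genuine bimodal benefit", {
  set.seed(502)
  n <- 20
  m <- make_metrics(n)
  m$sigma_D <- 0.25 + rnorm(n, 0, 0.02)
  m$sigma_2 <- 0.30 + rnorm(n, 0, 0.02)
  m$sigma_opt <- optimal_sigma(m$sigma_D, m$sigma_2)$sigma_opt
  m$sigma_bi <- m$sigma_opt + rnorm(n, 0, 0.01)
  r <- test_combination(m, "DS")
  expect_lt(r$p[grepl("vs-best", r$hypothesis)], 0.01)
  expect_equal(r$direction[grepl("vs-best", r$hypothesis)], "bimodal lower")
  expect_gt(r$p[grepl("vs-optimal", r$hypothesis)], 0.05)
})

test_that("re-weighting tests see the weight drop and the exact regression", {
  set.seed(503)
  n <- 16
  m <- make_metrics(n)
  m$w_pred_normal <- runif(n, 0.4, 0.8)
  m$w_emp_normal <- m$w_pred_normal          # identity regression
  m$w_emp_noisy <- m$w_emp_normal - 0.2 + rnorm(n, 0, 0.02)
  m$w_pred_noisy <- m$w_pred_normal - 0.2
  r <- test_reweighting(m, "DS")
  expect_lt(r$p[grepl("weight-drop", r$hypothesis)], 0.01)
  reg <- r[grepl("regression", r$hypothesis), ]
  expect_equal(reg$stat, 1, tolerance = 1e-9)
  expect_match(reg$direction, "r=1.000")
  # equal drops: the vs-optimal comparison must not reject
  m$w_emp_noisy <- m$w_emp_normal - 0.2
  r2 <- test_reweighting(m, "DS")
  expect_equal(r2$p[grepl("vs-optimal-drop", r2$hypothesis)], 1)
})

test_that("incongruence test flags raised incongruent noise only", {
  set.seed(504)
  m <- make_metrics(15)
  m$sigma_bi <- 0.2 + rnorm(15, 0, 0.01)
  m$sigma_inc <- m$sigma_bi + 0.05 + rnorm(15, 0, 0.01)
  r <- test_incongruence(m, "DS")
  expect_lt(r$p, 0.01)
  expect_equal(r$direction, "incongruent higher")
  m1 <- make_metrics(1)
  expect_error(test_incongruence(m1, "DS"), ">= 6")
})

test_that("McNemar reproduces the printed worked example", {
  r <- mcnemar_cc(22, 6)
  expect_equal(r$chisq, 8.04, tolerance = 0.001)
  expect_equal(r$chisq, 8.03571428571, tolerance = 1e-9)
  expect_equal(r$p, 0.00458639208, tolerance = 1e-6)
  # agrees with the standard continuity-corrected implementation
  tab <- matrix(c(23, 6, 22, 9), 2)
  expect_equal(r$chisq,
               unname(stats::mcnemar.test(tab, correct = TRUE)$statistic))
  expect_false(mcnemar_cc(0, 0)$defined)
})

test_that("pair comparison classifies, partitions and correlates", {
  set.seed(505)
  n <- 20
  ds <- make_metrics(n, "DS"); da <- make_metrics(n, "DA")
  ds$CI <- rnorm(n, 0.05, 0.03); da$CI <- rnorm(n, 0.0, 0.03)
  ds$RI <- rnorm(n, 0.2, 0.05); da$RI <- rnorm(n, 0.2, 0.05)
  ds$IS <- rnorm(n, 0.05, 0.03); da$IS <- rnorm(n, 0.05, 0.03)
  cp <- compare_pairs(rbind(ds, da))
  cl <- cp$classification
  expect_equal(cl$both + cl$only_DS + cl$only_DA + cl$neither, cl$n)
  expect_equal(cl$n, rep(n, 3))
  expect_s3_class(cp$tests, "data.frame")
  expect_true(is.finite(cp$ci_correlation$r))
  # all-concordant classification: McNemar undefined, reported as such
  ds2 <- ds; da2 <- da
  ds2$CI <- abs(ds2$CI) + 0.01; da2$CI <- abs(da2$CI) + 0.01
  ds2$RI <- abs(ds2$RI) + 0.01; da2$RI <- abs(da2$RI) + 0.01
  ds2$IS <- abs(ds2$IS) + 0.01; da2$IS <- abs(da2$IS) + 0.01
  cp2 <- compare_pairs(rbind(ds2, da2))
  expect_false(any(cp2$classification$mcnemar_defined))
})

test_that("nuisance control reports a one-sided p and a JZS Bayes factor", {
  set.seed(506)
  s <- runif(12, 0.2, 0.4)
  r0 <- nuisance_control(s, s + rnorm(12, 0, 1e-4))
  expect_gt(r0$p, 0.2)
  expect_gt(r0$BF01, 1)      # no effect favours the null
  r1 <- nuisance_control(s * 1.8, s)
  expect_lt(r1$p, 0.01)
  expect_lt(r1$BF01, 1)
  expect_error(nuisance_control(s[1:3], s[1:3]), "n >= 5")
})

test_that("the nuisance Bayes factor favours the null when there is none", {
  set.seed(507)
  bf01 <- replicate(300, {
    1 / jzs_bf10_ttest(rnorm(12, 0, 0.03))
  })
  expect_gt(mean(bf01 > 1), 0.5)       # null-consistent data support the null
  expect_gt(median(bf01), 2)
})

test_that("a true nuisance inflation is detected in most small cohorts", {
  set.seed(508)
  pow <- mean(replicate(200, {
    s <- runif(12, 0.2, 0.4)
    nuisance_control(s * 1.5 + rnorm(12, 0, 0.05),
                     s + rnorm(12, 0, 0.05))$p < 0.05
  }))
  expect_gt(pow, 0.6)
})

test_that("the JZS Bayes factor matches the published reference value", {
  # one-sample design, N = 80, t = 2.03, unit-information scale:
  # JZS BF01 = 1.56 (Rouder et al.'s worked example)
  n <- 80; t_target <- 2.03
  z <- scale(rnorm(n, 10, 3))[, 1]
  d <- z + t_target / sqrt(n)        # mean/sd give exactly t = 2.03
  bf01 <- 1 / jzs_bf10_ttest(d, scale = 1)
  expect_equal(bf01, 1.56, tolerance = 0.01)
})

test_that("inverse-mapping learners are detected from raw audio trials", {
  obs_ok <- observer_profile(sigma_A = 0.25, lapse = 0.02)
  tr_ok <- simulate_trials(obs_ok, "A", seed = 61, participant = "GOOD")
  tr_bad <- simulate_trials(obs_ok, "A", seed = 62, participant = "BAD")
  r <- ifelse(tr_bad$order == 1L, tr_bad$response, 1L - tr_bad$response)
  tr_bad$response <- ifelse(tr_bad$order == 1L, 1L - r, r)  # reversed slope
  inv <- detect_inverse_mapping(rbind(tr_ok, tr_bad))
  expect_equal(inv, "BAD")
})
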
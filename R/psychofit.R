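# Bayesian psychometric-function fitting on dense parameter grids.
#
# Model: psi(x) = lambda + (1 - lambda) * Phi(beta * (x - alpha))
# ("further" lapse convention: asymptotes lambda and 1), or the symmetric
# guessing convention lambda/2 + (1 - lambda) * Phi (asymptotes lambda/2 and
# 1 - lambda/2). Likelihood is Bernoulli per trial; priors are uniform over
# the stated parameter ranges; the posterior summary is the (marginal)
# posterior mean over a dense grid, with the mode available as an option.
#
# The expensive part -- log psi over (level, alpha, beta, lambda) -- depends
# only on the design and the grids, never on the data, so it is precomputed
# once and reused; a fit is then a matrix product of the per-level response
# counts with the log tables. This is what makes whole-study and
# power-simulation fitting fast.

#' Psychometric function for a 2IFC discrimination task
#'
#' `psi(x) = lambda + (1 - lambda) * F(x; alpha, beta)` with `F` the
#' cumulative normal `Phi(beta * (x - alpha))`. `alpha` is the point of
#' subjective equality (PSE) and `1/beta` the normal's standard deviation;
#' the lapse rate `lambda` sets the asymptotes (`lambda` and 1 under the
#' default convention; `lambda/2` and `1 - lambda/2` under `"guess"`).
#'
#' @param x Comparison level(s), normalized depth units.
#' @param alpha PSE.
#' @param beta Slope (positive).
#' @param lambda Lapse rate.
#' @param lapse_convention `"further"` (default) or `"guess"`.
#' @return Probability of a "further" response.
#' @export
psi <- function(x, alpha = 0, beta = 1, lambda = 0,
                lapse_convention = c("further", "guess")) {
  lapse_convention <- match.arg(lapse_convention)
  F <- stats::pnorm(beta * (x - alpha))
  if (lapse_convention == "further") lambda + (1 - lambda) * F
  else lambda / 2 + (1 - lambda) * F
}

#' Parameter grids for the Bayesian psychometric fit
#'
#' Uniform priors over: `alpha` in `alpha_range` (linear grid), `beta` in
#' `beta_range` (log-spaced grid with cell-width prior weights, i.e. a
#' uniform prior on the continuous interval), `lambda` in `lambda_range`
#' (linear grid).
#'
#' @param n_beta,beta_range Slope grid size and range (positive; default
#'   (0.05, 200], a sensory-noise floor of about 0.0035 normalized units).
#' @param n_alpha,alpha_range PSE grid (default 81 points on `[-1, 1]`).
#' @param n_lambda,lambda_range Lapse grid (default 41 points on `[0, 0.2]`).
#' @export
pf_grid <- function(n_beta = 161, beta_range = c(0.05, 200),
                    n_alpha = 81, alpha_range = c(-1, 1),
                    n_lambda = 41, lambda_range = c(0, 0.2)) {
  beta <- exp(seq(log(beta_range[1]), log(beta_range[2]), length.out = n_beta))
  mid <- (beta[-1] + beta[-n_beta]) / 2
  beta_w <- diff(c(beta[1] - (mid[1] - beta[1]), mid,
                   beta[n_beta] + (beta[n_beta] - mid[n_beta - 1])))
  lambda <- seq(lambda_range[1], lambda_range[2], length.out = n_lambda)
  lambda_w <- rep(1, n_lambda)            # trapezoid weights for the
  lambda_w[c(1, n_lambda)] <- 0.5         # uniform-prior integral
  structure(list(
    beta = beta, beta_w = beta_w,
    alpha = seq(alpha_range[1], alpha_range[2], length.out = n_alpha),
    lambda = lambda, lambda_w = lambda_w
  ), class = "pf_grid")
}

# Log-likelihood tables for a fixed design (levels x) and grid.
# A1/A0 are (n_levels x n_cells x n_lambda) arrays of log psi / log(1 - psi);
# cells run over beta (alpha fixed at 0) or over (alpha, beta) pairs.
pf_tables <- function(x, grid, alpha_free = FALSE,
                      lapse_convention = c("further", "guess")) {
  lapse_convention <- match.arg(lapse_convention)
  key <- paste(format(c(x, grid$beta[1], grid$beta[length(grid$beta)]),
                      digits = 12), collapse = ",")
  key <- paste(key, length(grid$beta), length(grid$alpha), length(grid$lambda),
               alpha_free, lapse_convention, sep = "|")
  hit <- .pf_cache[[key]]
  if (!is.null(hit)) return(hit)
  nb <- length(grid$beta); na <- length(grid$alpha); nl <- length(grid$lambda)
  nx <- length(x)
  if (alpha_free) {
    Fm <- matrix(0, nx, na * nb)
    for (a in seq_len(na)) {
      Fm[, (seq_len(nb) - 1L) * na + a] <-
        stats::pnorm(outer(x - grid$alpha[a], grid$beta))
    }
    cell_alpha <- rep(grid$alpha, nb)
    cell_beta <- rep(grid$beta, each = na)
    cell_w <- rep(grid$beta_w, each = na)
  } else {
    Fm <- stats::pnorm(outer(x, grid$beta))
    cell_alpha <- rep(0, nb)
    cell_beta <- grid$beta
    cell_w <- grid$beta_w
  }
  nc <- ncol(Fm)
  A1 <- array(0, c(nx, nc, nl)); A0 <- A1
  for (k in seq_len(nl)) {
    lam <- grid$lambda[k]
    ps <- if (lapse_convention == "further") lam + (1 - lam) * Fm
          else lam / 2 + (1 - lam) * Fm
    ps <- pmin(pmax(ps, 1e-12), 1 - 1e-12)
    A1[, , k] <- log(ps)
    A0[, , k] <- log1p(-ps)
  }
  out <- list(x = x, A1 = A1, A0 = A0, cell_alpha = cell_alpha,
              cell_beta = cell_beta, cell_w = cell_w, alpha_free = alpha_free,
              grid = grid)
  .pf_cache[[key]] <- out
  out
}

.pf_cache <- new.env(parent = emptyenv())

# Fast row max for a matrix (max.col is C-level).
row_max <- function(M) M[cbind(seq_len(nrow(M)), max.col(M, ties.method = "first"))]

# Posterior summaries for many fits that share a design, with lambda fixed
# per row (index into grid$lambda). K1/K0: (n_fits x n_levels) counts of
# "further" / "closer" responses. Returns point estimates, optional credible
# intervals, and a boundary flag for slopes piling up at the top of the
# prior range (separable data).
pf_fit_rows <- function(K1, K0, tables, lambda_idx,
                        point = c("mean", "mode"), ci = FALSE) {
  point <- match.arg(point)
  n <- nrow(K1)
  out <- data.frame(alpha = numeric(n), beta = numeric(n),
                    alpha_lo = NA_real_, alpha_hi = NA_real_,
                    beta_lo = NA_real_, beta_hi = NA_real_,
                    flag = character(n), stringsAsFactors = FALSE)
  hi_beta <- tables$cell_beta >= 0.5 * max(tables$cell_beta)  # upper-half slope mass: separable data
  for (k in unique(lambda_idx)) {
    rows <- which(lambda_idx == k)
    LL <- K1[rows, , drop = FALSE] %*% tables$A1[, , k] +
          K0[rows, , drop = FALSE] %*% tables$A0[, , k]
    E <- exp(LL - row_max(LL)) * rep(tables$cell_w, each = length(rows))
    tot <- as.vector(E %*% rep(1, ncol(E)))
    if (point == "mean") {
      out$beta[rows] <- as.vector(E %*% tables$cell_beta) / tot
      out$alpha[rows] <- as.vector(E %*% tables$cell_alpha) / tot
    } else {
      mx <- max.col(E)
      out$beta[rows] <- tables$cell_beta[mx]
      out$alpha[rows] <- tables$cell_alpha[mx]
    }
    bmass <- as.vector(E[, hi_beta, drop = FALSE] %*%
                         rep(1, sum(hi_beta))) / tot
    out$flag[rows] <- ifelse(bmass > 0.5, "beta_boundary", "")
    if (ci) {
      for (i in seq_along(rows)) {
        w <- E[i, ]
        bq <- wquantile(tables$cell_beta, w, c(0.025, 0.975))
        out$beta_lo[rows[i]] <- bq[1]; out$beta_hi[rows[i]] <- bq[2]
        if (tables$alpha_free) {
          aq <- wquantile(tables$cell_alpha, w, c(0.025, 0.975))
          out$alpha_lo[rows[i]] <- aq[1]; out$alpha_hi[rows[i]] <- aq[2]
        }
      }
    }
  }
  out
}

# As pf_fit_rows but with lambda free (integrated over its uniform prior by
# trapezoid quadrature on the lambda grid): the single-stage three-parameter
# fit. A single pass over the lambda grid with running renormalisation keeps
# memory at one (rows x cells) slice; when every row has the same per-level
# trial totals the log-likelihood factorises as K1 (A1 - A0) + n A0, halving
# the matrix-product cost. Returns marginal posterior means of alpha, beta
# and lambda.
pf_fit_rows_free_lambda <- function(K1, K0, tables) {
  n <- nrow(K1); nl <- dim(tables$A1)[3]
  hi_beta <- as.numeric(tables$cell_beta >= 0.5 * max(tables$cell_beta))
  Ntot <- K1 + K0
  same_n <- n == 1L || all(Ntot == rep(Ntot[1L, ], each = n))
  if (same_n) {
    res <- pf_free_lambda_kernel(
      K1, Ntot[1L, , drop = TRUE], tables$A1, tables$A0,
      tables$cell_w, tables$cell_beta, tables$cell_alpha, hi_beta,
      tables$grid$lambda, tables$grid$lambda_w)
    return(data.frame(alpha = res[, 1L], beta = res[, 2L],
                      lambda = res[, 3L],
                      flag = ifelse(res[, 4L] > 0.5, "beta_boundary", ""),
                      stringsAsFactors = FALSE))
  }
  W <- cbind(w = tables$cell_w,
             wb = tables$cell_w * tables$cell_beta,
             wa = tables$cell_w * tables$cell_alpha,
             whi = tables$cell_w * hi_beta)
  acc <- matrix(0, n, ncol(W))
  num_l <- rep(0, n)
  mx <- rep(-Inf, n)
  lam <- tables$grid$lambda
  lam_w <- tables$grid$lambda_w
  for (k in seq_len(nl)) {
    L <- K1 %*% tables$A1[, , k] + K0 %*% tables$A0[, , k]
    m_new <- pmax(mx, row_max(L))
    resc <- exp(mx - m_new)
    acc <- acc * resc
    num_l <- num_l * resc
    E <- exp(L - m_new)
    S <- (E %*% W) * lam_w[k]
    acc <- acc + S
    num_l <- num_l + lam[k] * S[, 1L]
    mx <- m_new
  }
  data.frame(alpha = acc[, 3L] / acc[, 1L],
             beta = acc[, 2L] / acc[, 1L],
             lambda = num_l / acc[, 1L],
             flag = ifelse(acc[, 4L] / acc[, 1L] > 0.5, "beta_boundary", ""),
             stringsAsFactors = FALSE)
}

# Log marginal likelihood of lambda per fit: slopes (and PSEs, where free)
# integrated out against their uniform priors. Returns an (n_fits x
# n_lambda) matrix; one matrix product per lambda grid point serves all rows.
pf_lambda_marginal <- function(K1, K0, tables) {
  nl <- dim(tables$A1)[3]
  n <- nrow(K1)
  LLs <- vector("list", nl)
  mx <- rep(-Inf, n)
  for (k in seq_len(nl)) {
    L <- K1 %*% tables$A1[, , k] + K0 %*% tables$A0[, , k]
    mx <- pmax(mx, row_max(L))
    LLs[[k]] <- L
  }
  M <- matrix(0, n, nl)
  for (k in seq_len(nl)) {
    M[, k] <- log(as.vector(exp(LLs[[k]] - mx) %*% tables$cell_w)) + mx
  }
  M
}

# Stage-1 shared lapse: the lambda posterior of one unit (participant x
# session) is the product of its conditions' lambda marginals under a
# uniform prior. `blocks` is a list of lists with elements K1, K0, tables,
# unit (conditions grouped by which table applies, so each block is one
# batched matrix product). Returns the posterior-mean lambda per unit.
pf_shared_lambda <- function(blocks) {
  lambda <- blocks[[1]]$tables$grid$lambda
  M <- do.call(rbind, lapply(blocks, function(b) {
    pf_lambda_marginal(b$K1, b$K0, b$tables)
  }))
  lambda_w <- blocks[[1]]$tables$grid$lambda_w
  unit <- unlist(lapply(blocks, `[[`, "unit"))
  Msum <- rowsum(M, unit)
  W <- exp(Msum - row_max(Msum))
  lam <- as.vector((W %*% (lambda * lambda_w)) / (W %*% lambda_w))
  names(lam) <- rownames(Msum)
  lam
}

snap_lambda <- function(lambda, grid) {
  step <- grid$lambda[2] - grid$lambda[1]
  pmin(pmax(as.integer(round(lambda / step)) + 1L, 1L), length(grid$lambda))
}
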
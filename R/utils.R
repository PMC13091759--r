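# Internal helpers: seed management, weighted summaries, validation.

#' Evaluate an expression with a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards so that seeded helpers do not
#' disturb an enclosing simulation stream. With `seed = NULL` the expression
#' runs on the current stream.
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

# Deterministic per-unit substream seeds below 2^31.
substream_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 48271 + 7919 * as.numeric(i)) %% 2147483629)
}

# Weighted mean over grid cells (weights need not be normalised).
wmean <- function(x, w) sum(x * w) / sum(w)

# Weighted quantile over a discrete grid (cells sorted by x).
wquantile <- function(x, w, probs) {
  o <- order(x)
  x <- x[o]
  w <- w[o] / sum(w)
  cw <- cumsum(w)
  vapply(probs, function(p) x[which(cw >= p)[1]], numeric(1))
}

stopifnot_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop(sprintf("`%s` must be a single positive finite number", name),
         call. = FALSE)
  }
  invisible(x)
}
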
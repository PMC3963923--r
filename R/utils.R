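# Internal helpers shared across modules.

# round half away from zero at `digits` decimals (base round() is banker's)
roundHalfUp <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

chisq1P <- function(stat) stats::pchisq(stat, df = 1, lower.tail = FALSE)

# Safeguarded 1-D maximization: coarse bracketing grid, then Brent on the
# bracketing subinterval. Returns list(maximum, objective).
maximize1d <- function(f, lower, upper, nGrid = 41L, tol = 1e-9) {
  xs <- seq(lower, upper, length.out = nGrid)
  vals <- vapply(xs, f, numeric(1))
  vals[!is.finite(vals)] <- -Inf
  i <- which.max(vals)
  lo <- xs[max(1L, i - 1L)]
  hi <- xs[min(nGrid, i + 1L)]
  opt <- stats::optimize(f, lower = lo, upper = hi, maximum = TRUE, tol = tol)
  if (opt$objective < vals[i]) {
    opt <- list(maximum = xs[i], objective = vals[i])
  }
  opt
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopIf <- function(cond, msg, ...) {
  if (cond) stop(sprintf(msg, ...), call. = FALSE)
}
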
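# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

.stopf <- function(...) stop(sprintf(...), call. = FALSE)

.check_number <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    .stopf("'%s' must be a single finite number", name)
  if (positive && x <= 0) .stopf("'%s' must be > 0", name)
  if (nonneg && x < 0) .stopf("'%s' must be >= 0", name)
  invisible(x)
}

# Evaluate expr with a temporarily seeded RNG, restoring the caller's
# RNG state afterwards so library code never disturbs user simulations.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    set.seed(seed)
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
  }
  expr
}

# Derive a stream of child seeds (< 2^31) from one parent seed.
child_seeds <- function(seed, k) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, k))
}

# log(exp(z) - 1), stable for large and small z > 0
.log_expm1 <- function(z) ifelse(z > 33, z, log(expm1(z)))

# Composite Gauss-Legendre rule on (0, 1] with dyadic panels refined
# toward 0 (the substitution that resolves the x ~ 0 boundary layer of
# the sojourn-time integrand).
.xquad <- function(x_min = 1e-8, per_panel = 16L) {
  brk <- unique(c(0, pmin(x_min * 2^(0:ceiling(log2(1 / x_min))), 1)))
  xs <- NULL; ws <- NULL
  for (j in seq_len(length(brk) - 1L)) {
    g <- pracma::gaussLegendre(per_panel, brk[j], brk[j + 1L])
    xs <- c(xs, g$x); ws <- c(ws, g$w)
  }
  list(x = xs, w = ws)
}
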
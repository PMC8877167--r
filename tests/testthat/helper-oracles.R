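# Independent oracles used across the suite. These deliberately avoid
# the package's own integration and enumeration code paths.

# Brute-force enumeration of all unordered nonsynonymous single-step
# codon changes (stop codons excluded), from first principles.
brute_force_nonsyn_steps <- function() {
  gc <- Biostrings::GENETIC_CODE
  bases <- c("A", "C", "G", "T")
  rows <- list()
  for (c1 in names(gc)) for (pos in 1:3) for (b in bases) {
    c2 <- c1
    substr(c2, pos, pos) <- b
    if (c2 <= c1) next
    a1 <- gc[[c1]]; a2 <- gc[[c2]]
    if (a1 == "*" || a2 == "*" || a1 == a2) next
    rows[[length(rows) + 1L]] <- data.frame(
      codon_1 = c1, codon_2 = c2, aa_1 = a1, aa_2 = a2,
      base_1 = substr(c1, pos, pos), base_2 = substr(c2, pos, pos),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

# Fine-quadrature oracle for the DFE-averaged expected SFS: the same
# double integral evaluated independently at ten times the resolution
# in both dimensions (10x points per log-decade of |S|, 10x points per
# dyadic frequency panel, wider panel ranges).
oracle_expected_sfs <- function(theta, n, beta, s_mean,
                                n_s = 160L, n_x = 160L,
                                x_min = 1e-9, s_min = 1e-10) {
  gl <- function(m, a, b) pracma::gaussLegendre(m, a, b)
  # frequency quadrature
  brk <- unique(c(0, pmin(x_min * 2^(0:ceiling(log2(1 / x_min))), 1)))
  xs <- NULL; xw <- NULL
  for (j in seq_len(length(brk) - 1L)) {
    g <- gl(n_x, brk[j], brk[j + 1L]); xs <- c(xs, g$x); xw <- c(xw, g$w)
  }
  # |S| quadrature on the log scale with gamma-density weight
  rate <- beta / s_mean
  S1 <- max(stats::qgamma(1 - 1e-15, beta, rate), s_min * 10)
  yb <- seq(log(s_min), log(S1),
            length.out = max(5L, ceiling((log(S1) - log(s_min)) / log(10))) + 1L)
  ys <- NULL; yw <- NULL
  for (j in seq_len(length(yb) - 1L)) {
    g <- gl(n_s, yb[j], yb[j + 1L]); ys <- c(ys, g$x); yw <- c(yw, g$w)
  }
  S <- exp(ys)
  dens_w <- yw * exp(beta * log(rate) - lgamma(beta) + beta * ys - rate * S)
  p0 <- stats::pgamma(s_min, beta, rate)
  # sojourn ratio (1 - e^{-S(1-x)})/(1 - e^{-S}) at S = -|S|, stably
  le <- function(z) ifelse(z > 33, z, log(expm1(z)))
  out <- numeric(n - 1L)
  for (i in seq_len(n - 1L)) {
    gx <- choose(n, i) * xs^(i - 1) * (1 - xs)^(n - i - 1) * xw
    f_of_S <- vapply(seq_along(S), function(k) {
      R <- exp(le(S[k] * (1 - xs)) - le(S[k]))
      sum(R * gx)
    }, numeric(1))
    out[i] <- theta * (sum(dens_w * f_of_S) + p0 / i)
  }
  out
}

# Closed-form weighted least squares via the normal equations.
oracle_wls <- function(x, y, w) {
  X <- cbind(1, x)
  A <- t(X) %*% (w * X)
  b <- solve(A, t(X) %*% (w * y))
  resid <- y - X %*% b
  df <- length(y) - 2L
  s2 <- sum(w * resid^2) / df
  se <- sqrt(diag(solve(A)) * s2)
  list(intercept = unname(b[1]), slope = unname(b[2]),
       slope_se = unname(se[2]))
}

# Small deterministic site table with known tallies: 7 Ala-Gly
# polymorphisms (C:G step), 3 Ala-Gly substitutions, plus C:G and A:T
# four-fold synonymous rows.
fixture_site_table <- function(n = 8L) {
  row <- function(gene, idx, cat, from, to, count = NA, nn = NA)
    data.frame(gene = gene, codon_idx = idx, category = cat,
               codon_from = from, codon_to = to, count = count, n = nn,
               stringsAsFactors = FALSE)
  counts <- c(1, 1, 2, 3, 1, 5, 7)
  rows <- list()
  for (j in seq_along(counts))
    rows[[length(rows) + 1L]] <- row(paste0("g", 1 + j %% 3), j,
                                     "polymorphism", "GCA", "GGA",
                                     counts[j], n)
  rows[[length(rows) + 1L]] <- row("g1", 101, "divergence", "GCC", "GGC")
  rows[[length(rows) + 1L]] <- row("g2", 102, "divergence", "GCA", "GGA")
  rows[[length(rows) + 1L]] <- row("g3", 103, "divergence", "GCT", "GGT")
  # four-fold C:G comparator: GCC<->GCG (Ala family), 5 rows
  for (j in 1:5)
    rows[[length(rows) + 1L]] <- row(paste0("g", 1 + j %% 3), 200 + j,
                                     "polymorphism", "GCC", "GCG", j, n)
  rows[[length(rows) + 1L]] <- row("g1", 301, "divergence", "GCC", "GCG")
  rows[[length(rows) + 1L]] <- row("g2", 302, "divergence", "CTC", "CTG")
  # four-fold A:T rows (GGA<->GGT, Gly family), should not enter a C:G
  # comparator
  rows[[length(rows) + 1L]] <- row("g1", 401, "polymorphism", "GGA",
                                   "GGT", 2, n)
  rows[[length(rows) + 1L]] <- row("g2", 402, "divergence", "GGA", "GGT")
  do.call(rbind, rows)
}
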
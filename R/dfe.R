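# GammaZero MK estimator: fits a gamma distribution of deleterious
# fitness effects to paired selected/neutral site frequency spectra by
# Poisson maximum likelihood, then contrasts observed with expected
# divergence to obtain omega, omega_na, omega_a and alpha.
#
# Scaled-selection convention, used consistently throughout the
# package: S = 4 * N_e * s. The DFE places all its mass on deleterious
# effects (S <= 0); `s_mean` is the mean of |S|.

#' Relative fixation rate of a semidominant mutation
#'
#' `Q(S) = S / (1 - exp(-S))`, the fixation probability of a mutation
#' with scaled selection coefficient `S = 4 Ne s` relative to a neutral
#' one, with `Q(0) = 1` by continuity. Deleterious mutations (`S < 0`)
#' fix at a reduced but nonzero rate - the leak that lets population
#' size change bias MK estimates.
#'
#' @param S numeric vector of scaled selection coefficients.
#' @return Numeric vector of relative fixation rates.
#' @examples
#' fixation_factor(c(0, -2, -10))
#' @export
fixation_factor <- function(S) {
  if (any(!is.finite(S))) .stopf("S must be finite")
  out <- numeric(length(S))
  small <- abs(S) < 1e-8
  out[small] <- 1 + S[small] / 2
  neg <- !small & S < 0
  # S<0: Q = -|S| / (1 - e^{|S|}) = |S| / (e^{|S|} - 1) = |S| e^{-log(expm1(|S|))}
  out[neg] <- exp(log(-S[neg]) - .log_expm1(-S[neg]))
  pos <- !small & S > 0
  out[pos] <- S[pos] / (1 - exp(-S[pos]))
  out
}

#' Gamma distribution of deleterious fitness effects
#'
#' @param beta gamma shape parameter.
#' @param s_mean mean of |S| (S = 4 Ne s) of deleterious mutations.
#' @return Object of class `gamma_dfe`.
#' @export
gamma_dfe <- function(beta, s_mean) {
  .check_number(beta, "beta", positive = TRUE)
  .check_number(s_mean, "s_mean", positive = TRUE)
  structure(list(beta = beta, s_mean = s_mean), class = "gamma_dfe")
}

#' @export
print.gamma_dfe <- function(x, ...) {
  cat(sprintf("<gamma DFE: shape beta = %.4g, mean |S| = %.4g>\n",
              x$beta, x$s_mean))
  invisible(x)
}

#' Numerical and optimization controls for the GammaZero fit
#'
#' @param epsilon ancestral misorientation rate in `[0, 1)`: a fraction
#'   `epsilon` of derived-allele classes is flipped (`i` with `n - i`)
#'   in the expected spectrum. Off (0) by default.
#' @param ri if `TRUE`, per-frequency-class nuisance factors shared
#'   between neutral and selected spectra are profiled out (normalized
#'   so the singleton class factor is 1). Off by default.
#' @param n_s Gauss-Legendre points per decade of the log-|S| grid used
#'   to integrate over the gamma DFE.
#' @param n_x Gauss-Legendre points per dyadic panel of the allele
#'   frequency integral.
#' @param x_min smallest dyadic breakpoint of the frequency integral.
#' @param s_min below this |S| the DFE mass is treated as exactly
#'   neutral (analytic term).
#' @param restarts number of dispersed optimizer starts (at least 3).
#' @param reltol relative convergence tolerance of the optimizer.
#' @param maxit maximum optimizer iterations per start.
#' @return Object of class `fit_options`.
#' @export
fit_options <- function(epsilon = 0, ri = FALSE, n_s = 16L, n_x = 16L,
                        x_min = 1e-8, s_min = 1e-9, restarts = 3L,
                        reltol = 1e-8, maxit = 400L) {
  if (epsilon < 0 || epsilon >= 1) .stopf("epsilon must be in [0, 1)")
  if (n_s < 8L || n_x < 8L)
    .stopf("quadrature orders n_s and n_x must be at least 8")
  if (restarts < 3L) .stopf("at least 3 optimizer restarts are required")
  structure(list(epsilon = epsilon, ri = isTRUE(ri),
                 n_s = as.integer(n_s), n_x = as.integer(n_x),
                 x_min = x_min, s_min = s_min,
                 restarts = as.integer(restarts),
                 reltol = reltol, maxit = as.integer(maxit)),
            class = "fit_options")
}

# ---- quadrature machinery -------------------------------------------

# cache of x-quadratures and class matrices, keyed by (n, n_x, x_min)
.quad_cache <- new.env(parent = emptyenv())

# M[x_node, i] = w_x * choose(n, i) * x^(i-1) * (1-x)^(n-i-1),
# so that class shapes are R(S, x) %*% M for sojourn ratio R.
.class_matrix <- function(n, opts) {
  key <- paste(n, opts$n_x, opts$x_min, sep = "|")
  got <- .quad_cache[[key]]
  if (!is.null(got)) return(got)
  q <- .xquad(opts$x_min, opts$n_x)
  i <- seq_len(n - 1L)
  M <- outer(q$x, i, function(x, i)
    exp(lchoose(n, i) + (i - 1) * log(x) + (n - i - 1) * log1p(-x)))
  M <- M * q$w
  out <- list(x = q$x, M = M)
  .quad_cache[[key]] <- out
  out
}

# Sojourn-density ratio relative to neutrality for deleterious S:
# R(|S|, x) = (1 - exp(S(1-x))) / (1 - exp(S)) at S = -|S|,
# computed stably; R -> (1 - x) as |S| -> 0.
.sojourn_ratio <- function(Sabs, x) {
  Z <- outer(Sabs, 1 - x)
  R <- exp(ifelse(Z > 33, Z, log(expm1(Z))) -
             ifelse(Sabs > 33, Sabs, .log_expm1(Sabs)))
  zero <- Sabs < 1e-12
  if (any(zero)) R[zero, ] <- rep(1 - x, each = sum(zero))
  R
}

# Quadrature over the gamma DFE on a log-|S| grid: per-decade
# Gauss-Legendre panels between s_min and the far upper quantile, plus
# the analytic probability mass below s_min (treated as neutral).
.dfe_quad <- function(beta, s_mean, opts) {
  rate <- beta / s_mean
  S1 <- max(stats::qgamma(1 - 1e-14, beta, rate), opts$s_min * 10)
  ylo <- log(opts$s_min); yhi <- log(S1)
  # one panel per decade of |S|; large shapes concentrate the gamma in
  # a log-width ~ 1/sqrt(beta) spike, so densify panels accordingly
  nk <- max(4L, ceiling((yhi - ylo) / log(10) * max(1, sqrt(beta / 2))))
  brk <- seq(ylo, yhi, length.out = nk + 1L)
  ys <- NULL; ws <- NULL
  for (j in seq_len(nk)) {
    g <- pracma::gaussLegendre(opts$n_s, brk[j], brk[j + 1L])
    ys <- c(ys, g$x); ws <- c(ws, g$w)
  }
  S <- exp(ys)
  lw <- beta * log(rate) - lgamma(beta) + beta * ys - rate * S
  list(S = S, w = ws * exp(lw),
       p_neutral = stats::pgamma(opts$s_min, beta, rate))
}

# DFE-averaged class shapes (theta = 1), unfolded classes 1..n-1
.sel_shape <- function(beta, s_mean, n, opts) {
  cm <- .class_matrix(n, opts)
  dq <- .dfe_quad(beta, s_mean, opts)
  R <- .sojourn_ratio(dq$S, cm$x)
  as.numeric(dq$w %*% (R %*% cm$M)) + dq$p_neutral / seq_len(n - 1L)
}

.apply_epsilon <- function(e, eps) {
  if (eps <= 0) return(e)
  (1 - eps) * e + eps * rev(e)
}

.fold_expect <- function(e, n) {
  half <- n %/% 2L
  vapply(seq_len(half), function(i) {
    j <- n - i
    if (j == i) e[i] else e[i] + e[j]
  }, numeric(1))
}

#' Expected site frequency spectrum under the Poisson random field
#'
#' Class-`i` expectation (unfolded, `i = 1..n-1`) is
#' `theta * Int_0^1 H(S, x) C(n,i) x^i (1-x)^(n-i) dx`
#' averaged over the DFE, where `H(S, x)` is the standard sojourn
#' density of a semidominant mutation and constant conventions are
#' absorbed into `theta`. The neutral limit gives the familiar
#' `theta / i` shape. Integration uses composite Gauss-Legendre rules:
#' dyadic panels in `x` (refined toward 0, where strongly deleterious
#' alleles concentrate) and per-decade panels on log |S| with the
#' near-zero gamma mass handled analytically.
#'
#' @param theta mutation-rate scaler of the site category (absorbs site
#'   count and per-site mutation rate).
#' @param n haploid sample size (at least 4).
#' @param dfe a [gamma_dfe()] for selected sites, or `NULL` for the
#'   neutral (S = 0) expectation.
#' @param opts a [fit_options()] object (quadrature orders, epsilon).
#' @param folded if `TRUE`, return the folded expectation.
#' @return Numeric vector of expected counts per frequency class.
#' @export
expected_sfs <- function(theta, n, dfe = NULL, opts = fit_options(),
                         folded = FALSE) {
  .check_number(theta, "theta", nonneg = TRUE)
  .check_number(n, "n", positive = TRUE)
  n <- as.integer(n)
  if (n < 4L) .stopf("n must be at least 4")
  shape <- if (is.null(dfe)) 1 / seq_len(n - 1L) else {
    stopifnot(inherits(dfe, "gamma_dfe"))
    .sel_shape(dfe$beta, dfe$s_mean, n, opts)
  }
  e <- .apply_epsilon(theta * shape, opts$epsilon)
  if (folded) .fold_expect(e, n) else e
}

#' Expected nonadaptive substitution rate under a gamma DFE
#'
#' Integrates the relative fixation rate [fixation_factor()] over the
#' gamma distribution of deleterious effects: the fraction of
#' nonsynonymous substitutions expected from fixation of neutral and
#' slightly deleterious mutations alone.
#'
#' @param dfe a [gamma_dfe()].
#' @param opts a [fit_options()] (quadrature controls).
#' @export
omega_na_from_dfe <- function(dfe, opts = fit_options()) {
  stopifnot(inherits(dfe, "gamma_dfe"))
  dq <- .dfe_quad(dfe$beta, dfe$s_mean, opts)
  sum(dq$w * fixation_factor(-dq$S)) + dq$p_neutral
}

# ---- likelihood and fitting -----------------------------------------

# Profile log-likelihood for one spectrum: Poisson counts with
# expectation theta * shape (theta profiled in closed form).
.profile_piece <- function(obs, shape) {
  tot <- sum(obs)
  denom <- sum(shape)
  theta <- if (denom > 0) tot / denom else 0
  mu <- theta * shape
  ll <- sum(ifelse(obs > 0, obs * log(pmax(mu, 1e-300)), 0) - mu -
              lgamma(obs + 1))
  list(theta = theta, loglik = ll, mu = mu)
}

# Joint likelihood of selected + neutral spectra at (beta, s_mean).
# The two categories share one per-site mutation rate theta, scaled by
# their site counts L_sel and L_neu: it is the level of the selected
# spectrum relative to the neutral one (the pN/pS signal) that makes
# the mean selection strength identifiable, so theta must not float
# independently per category. theta (and optional r_i class factors)
# are profiled out in closed form.
.gamma_zero_loglik <- function(beta, s_mean, sel_obs, neu_obs, n, folded,
                               L_sel, L_neu, opts) {
  shape_neu <- .apply_epsilon(1 / seq_len(n - 1L), opts$epsilon) * L_neu
  shape_sel <- .apply_epsilon(.sel_shape(beta, s_mean, n, opts),
                              opts$epsilon) * L_sel
  if (folded) {
    shape_neu <- .fold_expect(shape_neu, n)
    shape_sel <- .fold_expect(shape_sel, n)
  }
  obs <- c(neu_obs, sel_obs)
  r <- rep(1, length(shape_neu))
  for (it in seq_len(if (opts$ri) 4L else 1L)) {
    pr <- .profile_piece(obs, c(r * shape_neu, r * shape_sel))
    if (!opts$ri) break
    denom <- pr$theta * (shape_neu + shape_sel)
    r_new <- ifelse(denom > 0, (neu_obs + sel_obs) / denom, 1)
    r <- r_new / r_new[1L]
  }
  list(loglik = pr$loglik, theta = pr$theta,
       theta_neu = pr$theta * L_neu, theta_sel = pr$theta * L_sel,
       r = if (opts$ri) r else NULL)
}

.FIT_BOX <- list(log_beta = log(c(1e-2, 50)), log_s = log(c(1e-6, 1e8)))

.fit_objective <- function(par, sel_obs, neu_obs, n, folded, L_sel,
                           L_neu, opts) {
  lb <- par[1]; ls <- par[2]
  pen <- 0
  if (lb < .FIT_BOX$log_beta[1] || lb > .FIT_BOX$log_beta[2] ||
      ls < .FIT_BOX$log_s[1] || ls > .FIT_BOX$log_s[2]) {
    d <- max(0, .FIT_BOX$log_beta[1] - lb, lb - .FIT_BOX$log_beta[2]) +
      max(0, .FIT_BOX$log_s[1] - ls, ls - .FIT_BOX$log_s[2])
    return(1e10 * (1 + d))
  }
  -(.gamma_zero_loglik(exp(lb), exp(ls), sel_obs, neu_obs, n, folded,
                       L_sel, L_neu, opts)$loglik) + pen
}

.optimize_from <- function(start, sel_obs, neu_obs, n, folded, L_sel,
                           L_neu, opts) {
  stats::optim(log(start), .fit_objective, sel_obs = sel_obs,
               neu_obs = neu_obs, n = n, folded = folded,
               L_sel = L_sel, L_neu = L_neu, opts = opts,
               method = "Nelder-Mead",
               control = list(reltol = opts$reltol, maxit = opts$maxit))
}

#' Fit the GammaZero model to paired spectra
#'
#' Maximizes the product of independent Poisson likelihoods over all
#' frequency classes of the neutral and selected spectra in
#' `(beta, s_mean, theta_sel, theta_neu)`, the two theta scalers being
#' profiled out in closed form. The optimizer runs from at least three
#' dispersed starts (weak / intermediate / strong selection); ties are
#' broken by highest log-likelihood, then smallest `beta`.
#'
#' @param sel,neu selected and neutral [sfs_spectrum()]s with matching
#'   sample size and folded status, positive totals.
#' @param opts a [fit_options()].
#' @param seed optional seed controlling the jitter of extra starts
#'   beyond the three canonical ones.
#' @return Object of class `dfe_fit` holding the fitted [gamma_dfe()],
#'   thetas, log-likelihood and convergence flag; divergence-based
#'   rates are filled in by [adaptive_rates()].
#' @export
fit_gamma_zero <- function(sel, neu, opts = fit_options(), seed = NULL) {
  stopifnot(inherits(sel, "sfs_spectrum"), inherits(neu, "sfs_spectrum"))
  if (sel$n != neu$n) .stopf("selected and neutral spectra must share n")
  if (sel$folded != neu$folded)
    .stopf("selected and neutral spectra must share folded status")
  if (sel$folded && opts$epsilon > 0)
    .stopf("misorientation epsilon is meaningless for folded spectra")
  if (sum(sel$counts) <= 0 || sum(neu$counts) <= 0)
    .stopf("both spectra need positive totals")
  n <- sel$n
  starts <- list(c(0.2, 10), c(0.5, 1e3), c(1.0, 1e5))
  if (opts$restarts > 3L) {
    extra <- with_seed(seed, replicate(opts$restarts - 3L, c(
      exp(stats::runif(1, log(0.05), log(5))),
      exp(stats::runif(1, log(0.1), log(1e6)))), simplify = FALSE))
    starts <- c(starts, extra)
  }
  best <- NULL
  for (s0 in starts) {
    o <- .optimize_from(s0, sel$counts, neu$counts, n, sel$folded,
                        sel$L, neu$L, opts)
    if (is.null(best) || o$value < best$value - 1e-9 ||
        (abs(o$value - best$value) <= 1e-9 && o$par[1] < best$par[1]))
      best <- o
  }
  beta <- exp(best$par[1]); s_mean <- exp(best$par[2])
  prof <- .gamma_zero_loglik(beta, s_mean, sel$counts, neu$counts, n,
                             sel$folded, sel$L, neu$L, opts)
  structure(list(
    dfe = gamma_dfe(beta, s_mean),
    theta_sel = prof$theta_sel, theta_neu = prof$theta_neu,
    r = prof$r, loglik = prof$loglik,
    converged = best$convergence == 0L,
    n_starts_used = length(starts),
    n = n, folded = sel$folded, opts = opts,
    omega = NA_real_, omega_na = NA_real_, omega_a = NA_real_,
    alpha = NA_real_),
    class = "dfe_fit")
}

# single warm-started refit (used by bootstrap replicates)
.fit_warm <- function(sel_counts, neu_counts, n, folded, L_sel, L_neu,
                      start_par, opts) {
  o <- stats::optim(start_par, .fit_objective, sel_obs = sel_counts,
                    neu_obs = neu_counts, n = n, folded = folded,
                    L_sel = L_sel, L_neu = L_neu,
                    opts = opts, method = "Nelder-Mead",
                    control = list(reltol = 1e-8, maxit = 300L))
  c(beta = exp(o$par[1]), s_mean = exp(o$par[2]))
}

#' @export
print.dfe_fit <- function(x, ...) {
  cat(sprintf(paste0(
    "<GammaZero fit: beta = %.4g, mean |S| = %.4g, logLik = %.2f%s>\n"),
    x$dfe$beta, x$dfe$s_mean, x$loglik,
    if (!x$converged) ", NOT converged" else ""))
  if (is.finite(x$omega))
    cat(sprintf("  omega = %.4g  omega_na = %.4g  omega_a = %.4g  alpha = %.4g\n",
                x$omega, x$omega_na, x$omega_a, x$alpha))
  invisible(x)
}

#' Complete a fit with divergence-based adaptive rates
#'
#' `omega` is the per-site selected/neutral divergence ratio;
#' `omega_na` follows from the fitted DFE via [omega_na_from_dfe()];
#' the adaptive rate is the excess `omega_a = omega - omega_na` and
#' `alpha = omega_a / omega`. If more divergence is observed than the
#' fitted DFE predicts, adaptive evolution is inferred.
#'
#' @param fit a `dfe_fit` from [fit_gamma_zero()].
#' @param div a [div_counts()] with positive neutral counts.
#' @return The completed `dfe_fit` (identically satisfying
#'   `omega = omega_a + omega_na`).
#' @export
adaptive_rates <- function(fit, div) {
  stopifnot(inherits(fit, "dfe_fit"), inherits(div, "div_counts"))
  if (div$d_neu <= 0) .stopf("omega undefined: no neutral substitutions")
  if (div$l_sel <= 0 || div$l_neu <= 0)
    .stopf("omega requires positive site counts")
  fit$omega <- (div$d_sel / div$l_sel) / (div$d_neu / div$l_neu)
  fit$omega_na <- omega_na_from_dfe(fit$dfe, fit$opts)
  fit$omega_a <- fit$omega - fit$omega_na
  fit$alpha <- if (fit$omega > 0) fit$omega_a / fit$omega else NA_real_
  fit
}

# ---- gene-resolved units and bootstrap ------------------------------

#' Gene-resolved analysis unit
#'
#' Holds per-gene selected/neutral SFS contributions and divergence
#' counts for one analysis unit (an amino-acid pair or an RSA bin).
#' Sites are the unit of SFS aggregation; genes are the resampling unit
#' of the bootstrap.
#'
#' @param sel_counts,neu_counts numeric matrices (genes x frequency
#'   classes) of SFS contributions.
#' @param d_sel,d_neu per-gene substitution counts.
#' @param l_sel,l_neu per-gene divergence site counts.
#' @param n haploid sample size of the spectra.
#' @param genes gene identifiers (rownames used when absent).
#' @param L_sel,L_neu per-gene polymorphism site counts (default: the
#'   per-gene segregating totals).
#' @param folded folded status of the spectra.
#' @return Object of class `gene_unit`.
#' @export
gene_unit <- function(sel_counts, neu_counts, d_sel, d_neu, l_sel, l_neu,
                      n, genes = NULL, L_sel = NULL, L_neu = NULL,
                      folded = FALSE) {
  sel_counts <- as.matrix(sel_counts); neu_counts <- as.matrix(neu_counts)
  G <- nrow(sel_counts)
  if (nrow(neu_counts) != G || length(d_sel) != G || length(d_neu) != G ||
      length(l_sel) != G || length(l_neu) != G)
    .stopf("all per-gene components must cover the same genes")
  genes <- genes %||% rownames(sel_counts) %||% paste0("g", seq_len(G))
  structure(list(sel_counts = sel_counts, neu_counts = neu_counts,
                 d_sel = as.numeric(d_sel), d_neu = as.numeric(d_neu),
                 l_sel = as.numeric(l_sel), l_neu = as.numeric(l_neu),
                 L_sel = L_sel %||% rowSums(sel_counts),
                 L_neu = L_neu %||% rowSums(neu_counts),
                 n = as.integer(n), genes = as.character(genes),
                 folded = isTRUE(folded)),
            class = "gene_unit")
}

#' Aggregate a gene unit into spectra and divergence counts
#'
#' @param unit a [gene_unit()].
#' @param idx gene indices (with repetition allowed, as in a bootstrap
#'   resample); default all genes once.
#' @return List with `sel`, `neu` ([sfs_spectrum()]s) and `div`
#'   ([div_counts()]).
#' @export
aggregate_genes <- function(unit, idx = NULL) {
  stopifnot(inherits(unit, "gene_unit"))
  idx <- idx %||% seq_along(unit$genes)
  list(
    sel = sfs_spectrum(colSums(unit$sel_counts[idx, , drop = FALSE]),
                       n = unit$n, L = sum(unit$L_sel[idx]),
                       folded = unit$folded),
    neu = sfs_spectrum(colSums(unit$neu_counts[idx, , drop = FALSE]),
                       n = unit$n, L = sum(unit$L_neu[idx]),
                       folded = unit$folded),
    div = div_counts(d_sel = sum(unit$d_sel[idx]),
                     d_neu = sum(unit$d_neu[idx]),
                     l_sel = sum(unit$l_sel[idx]),
                     l_neu = sum(unit$l_neu[idx])))
}

#' Bootstrap a gene unit to obtain rate variances
#'
#' Resamples genes with replacement, rebuilds the aggregate spectra and
#' divergence counts, refits the GammaZero model and recomputes the
#' rates. Replicate refits warm-start from the full-data maximum and
#' use a coarser quadrature (`refit_opts`), which keeps B = 100
#' replicates at desk scale; the full-data fit uses `opts` unchanged.
#' The resulting variances are the reciprocal-variance weights of the
#' downstream regressions.
#'
#' @param unit a [gene_unit()] with at least two genes.
#' @param B number of bootstrap replicates (at least 2; 100 by
#'   default).
#' @param seed integer seed; replicates are deterministic given it.
#' @param opts [fit_options()] for the full-data fit.
#' @param refit_opts [fit_options()] for replicate refits; defaults to
#'   a coarser quadrature adequate for variance estimation.
#' @return Object of class `mk_bootstrap`: the full-data `fit`,
#'   variances and percentile CIs of `omega_a` and `omega_na`, and the
#'   replicate table.
#' @export
bootstrap_by_gene <- function(unit, B = 100L, seed = NULL,
                              opts = fit_options(), refit_opts = NULL) {
  stopifnot(inherits(unit, "gene_unit"))
  G <- length(unit$genes)
  if (G < 2L) .stopf("bootstrap requires at least 2 genes")
  if (B < 2L) .stopf("B must be at least 2")
  refit_opts <- refit_opts %||% fit_options(
    epsilon = opts$epsilon, ri = opts$ri, n_s = 8L, n_x = 8L,
    x_min = 1e-6, s_min = opts$s_min)
  agg <- aggregate_genes(unit)
  fit <- adaptive_rates(fit_gamma_zero(agg$sel, agg$neu, opts, seed),
                        agg$div)
  start_par <- log(c(fit$dfe$beta, fit$dfe$s_mean))
  seeds <- child_seeds(seed, B)
  reps <- vector("list", B)
  for (b in seq_len(B)) {
    idx <- with_seed(seeds[b], sample.int(G, G, replace = TRUE))
    a <- aggregate_genes(unit, idx)
    if (sum(a$sel$counts) <= 0 || sum(a$neu$counts) <= 0 ||
        a$div$d_neu <= 0) {
      reps[[b]] <- data.frame(beta = NA_real_, s_mean = NA_real_,
                              omega = NA_real_, omega_na = NA_real_,
                              omega_a = NA_real_, alpha = NA_real_)
      next
    }
    par <- .fit_warm(a$sel$counts, a$neu$counts, unit$n, unit$folded,
                     a$sel$L, a$neu$L, start_par, refit_opts)
    dfe <- gamma_dfe(par[["beta"]], par[["s_mean"]])
    omega <- (a$div$d_sel / a$div$l_sel) / (a$div$d_neu / a$div$l_neu)
    omega_na <- omega_na_from_dfe(dfe, refit_opts)
    reps[[b]] <- data.frame(beta = dfe$beta, s_mean = dfe$s_mean,
                            omega = omega, omega_na = omega_na,
                            omega_a = omega - omega_na,
                            alpha = if (omega > 0) (omega - omega_na) / omega
                                    else NA_real_)
  }
  reps <- do.call(rbind, reps)
  ci <- function(v) stats::quantile(v, c(0.025, 0.975), na.rm = TRUE,
                                    names = FALSE)
  structure(list(
    fit = fit, B = B, n_failed = sum(is.na(reps$omega_a)),
    var_omega_a = stats::var(reps$omega_a, na.rm = TRUE),
    var_omega_na = stats::var(reps$omega_na, na.rm = TRUE),
    ci_omega_a = ci(reps$omega_a), ci_omega_na = ci(reps$omega_na),
    ci_beta = ci(reps$beta), ci_s_mean = ci(reps$s_mean),
    replicates = reps),
    class = "mk_bootstrap")
}

#' @export
print.mk_bootstrap <- function(x, ...) {
  cat(sprintf(
    "<gene bootstrap, B = %d%s: var(omega_a) = %.3g, var(omega_na) = %.3g>\n",
    x$B, if (x$n_failed) sprintf(" (%d failed)", x$n_failed) else "",
    x$var_omega_a, x$var_omega_na))
  invisible(x)
}
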
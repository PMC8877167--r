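test_that("fixation factor matches closed forms and limits", {
  expect_equal(fixation_factor(0), 1)
  expect_equal(fixation_factor(-2), 2 / (exp(2) - 1), tolerance = 1e-12)
  expect_equal(fixation_factor(2), 2 / (1 - exp(-2)), tolerance = 1e-12)
  # monotone decay to zero under increasingly strong purifying selection
  q <- fixation_factor(-c(1, 5, 20, 100, 500, 1e4))
  expect_true(all(diff(q) < 0))
  expect_lt(q[6], 1e-12)
  # continuity through zero
  expect_equal(fixation_factor(1e-10), 1, tolerance = 1e-9)
  expect_equal(fixation_factor(-745), 0, tolerance = 1e-300)
})

test_that("neutral expected SFS is theta / i", {
  expect_equal(expected_sfs(1, 4), c(1, 1 / 2, 1 / 3))
  n <- 20
  expect_equal(expected_sfs(100, n), 100 / seq_len(n - 1))
  expect_error(expected_sfs(1, 3), "at least 4")
})

test_that("selected expectation is continuous at the neutral limit and
           skews toward rare alleles under strong selection", {
  n <- 12
  weak <- expected_sfs(1, n, gamma_dfe(0.5, 1e-7))
  expect_equal(weak, 1 / seq_len(n - 1), tolerance = 1e-6)
  strong <- expected_sfs(1, n, gamma_dfe(0.5, 1000))
  expect_gt(strong[1] / strong[2], 2)  # neutral ratio is 2:1
  expect_true(all(strong < 1 / seq_len(n - 1) + 1e-12))
})

test_that("expected SFS matches the fine-resolution quadrature oracle", {
  n <- 20
  panel <- list(c(0.4, 2000), c(0.5, 50), c(1.2, 10), c(0.3, 0.5))
  for (p in panel) {
    mine <- expected_sfs(3, n, gamma_dfe(p[1], p[2]))
    orac <- oracle_expected_sfs(3, n, p[1], p[2])
    expect_lt(max(abs(mine / orac - 1)), 1e-6)
  }
})

test_that("folding and misorientation act on expectations as specified", {
  n <- 10
  e <- expected_sfs(2, n, gamma_dfe(0.4, 100))
  ef <- expected_sfs(2, n, gamma_dfe(0.4, 100), folded = TRUE)
  expect_equal(ef, c(e[1:4] + e[9:6], e[5]), ignore_attr = TRUE)
  opts_e <- fit_options(epsilon = 0.1)
  ee <- expected_sfs(2, n, gamma_dfe(0.4, 100), opts = opts_e)
  expect_equal(ee, 0.9 * e + 0.1 * rev(e))
})

test_that("omega_na integrates the fixation factor over the DFE", {
  # a large shape concentrates the gamma at its mean: point-mass check
  expect_equal(omega_na_from_dfe(gamma_dfe(2000, 2)), fixation_factor(-2),
               tolerance = 1e-3)
  # independent adaptive-quadrature oracle at a generic shape
  orac <- stats::integrate(function(s)
    stats::dgamma(s, 0.8, 0.8 / 30) * fixation_factor(-s), 0, Inf,
    rel.tol = 1e-10)$value
  expect_equal(omega_na_from_dfe(gamma_dfe(0.8, 30)), orac,
               tolerance = 1e-7)
  expect_equal(omega_na_from_dfe(gamma_dfe(0.5, 1e-8)), 1,
               tolerance = 1e-7)
  # asymptotic power law: d log(omega_na) / d log(s_mean) ~ -beta
  for (beta in c(0.3, 0.6)) {
    lo <- omega_na_from_dfe(gamma_dfe(beta, 1e4))
    hi <- omega_na_from_dfe(gamma_dfe(beta, 1e6))
    slope <- (log(hi) - log(lo)) / (log(1e6) - log(1e4))
    expect_equal(slope, -beta, tolerance = 0.05 * beta)
  }
})

test_that("zero-noise fit recovers the generating parameters", {
  sc <- sim_scenario(L = 1e6, contraction = 1, zero_noise = TRUE)
  sim <- simulate_unit(sc, s_mean = 2000, a = 0, seed = 1)
  agg <- aggregate_genes(sim$unit)
  fit <- adaptive_rates(fit_gamma_zero(agg$sel, agg$neu, seed = 1),
                        agg$div)
  expect_true(fit$converged)
  expect_equal(fit$dfe$beta, 0.4, tolerance = 0.01)
  expect_equal(fit$dfe$s_mean, 2000, tolerance = 0.05)
  expect_equal(fit$omega_a, 0, tolerance = 2e-3)
  expect_equal(fit$omega, fit$omega_a + fit$omega_na)
})

test_that("a neutral selected spectrum yields omega_na near one", {
  n <- 20
  theta <- 500
  sel <- sfs_spectrum(expected_sfs(theta, n), n = n, L = 1e5)
  neu <- sfs_spectrum(expected_sfs(theta, n), n = n, L = 1e5)
  fit <- fit_gamma_zero(sel, neu, seed = 2)
  expect_equal(omega_na_from_dfe(fit$dfe, fit$opts), 1, tolerance = 0.05)
})

test_that("likelihood at the truth dominates perturbed parameters", {
  n <- 20
  theta <- 2000
  dfe <- gamma_dfe(0.4, 500)
  sel_mu <- expected_sfs(theta, n, dfe)
  neu_mu <- expected_sfs(theta, n)
  ll <- function(beta, s_mean) {
    mu_s <- expected_sfs(theta, n, gamma_dfe(beta, s_mean))
    sum(sel_mu * log(mu_s) - mu_s) + sum(neu_mu * log(neu_mu) - neu_mu)
  }
  expect_gt(ll(0.4, 500), ll(0.8, 500))
  expect_gt(ll(0.4, 500), ll(0.4, 5000))
})

test_that("adaptive rates complete the fit and guard degenerate input", {
  fit <- fit_gamma_zero(
    sfs_spectrum(expected_sfs(100, 10, gamma_dfe(0.4, 200)), 10, L = 1e4),
    sfs_spectrum(expected_sfs(100, 10), 10, L = 1e4), seed = 3)
  omega_na <- omega_na_from_dfe(fit$dfe, fit$opts)
  # choose divergence so omega equals omega_na: omega_a must vanish
  d <- div_counts(d_sel = omega_na * 1000, d_neu = 1000,
                  l_sel = 1e5, l_neu = 1e5)
  done <- adaptive_rates(fit, d)
  expect_equal(done$omega_a, 0, tolerance = 1e-12)
  expect_equal(done$alpha, 0, tolerance = 1e-12)
  expect_error(adaptive_rates(fit, div_counts(5, 0, 10, 10)), "undefined")
})

test_that("gene bootstrap is deterministic and its variance shrinks with
           more data", {
  sc_small <- sim_scenario(L = 2e4, L_div = 1e5, genes_per_unit = 5)
  sc_big <- sim_scenario(L = 2e5, L_div = 1e6, genes_per_unit = 50)
  u_small <- simulate_unit(sc_small, s_mean = 300, a = 0, seed = 4)$unit
  u_big <- simulate_unit(sc_big, s_mean = 300, a = 0, seed = 5)$unit
  b1 <- bootstrap_by_gene(u_small, B = 8, seed = 9)
  b2 <- bootstrap_by_gene(u_small, B = 8, seed = 9)
  expect_identical(b1$var_omega_a, b2$var_omega_a)
  expect_identical(b1$replicates, b2$replicates)
  expect_gte(b1$var_omega_a, 0)
  b3 <- bootstrap_by_gene(u_big, B = 8, seed = 9)
  expect_lt(b3$var_omega_a, b1$var_omega_a)
  expect_error(bootstrap_by_gene(u_small, B = 1, seed = 1), "at least 2")
})

test_that("fit options are validated", {
  expect_error(fit_options(epsilon = 1), "epsilon")
  expect_error(fit_options(restarts = 2), "restarts")
  expect_error(fit_options(n_s = 4), "at least 8")
  expect_error(fit_gamma_zero(
    sfs_spectrum(c(0, 0, 0), 4), sfs_spectrum(c(1, 1, 1), 4)),
    "positive totals")
})
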
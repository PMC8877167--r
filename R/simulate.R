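# Synthetic-data generator: complete studies with known truth under a
# two-epoch population history. Polymorphism is generated at size N_p
# (Poisson noise around the Poisson-random-field expectation under the
# gamma DFE) and divergence at size N_d, optionally with an added
# adaptive component, so the artifactual-correlation prediction of the
# two-epoch theory can be exercised end to end.
#
# Scaling convention: per-unit `s_mean` values are stated at N_p;
# divergence-phase mean effects are s_mean * (N_d / N_p) =
# s_mean / contraction, making the two-epoch link explicit.

#' Define a simulation scenario
#'
#' Defaults describe the desk-scale study: 30 units, sample size
#' n = 20, a 5-fold population contraction (N_p/N_d = 0.2) mirroring
#' hominid history, no adaptive evolution, a gamma DFE with shape 0.4,
#' and a log-spaced gradient of mean selection strengths across units
#' that stands in for a covariate such as amino-acid dissimilarity.
#'
#' @param n_units number of analysis units.
#' @param beta gamma DFE shape, shared across units.
#' @param s_mean_range range of per-unit mean |S| (at N_p); units take
#'   log-spaced values across it.
#' @param contraction ratio N_p / N_d (< 1 means contraction).
#' @param adaptive adaptive substitution rate relative to the mutation
#'   rate: a single nonnegative number, or a function of `s_mean`.
#' @param L polymorphism sites per unit.
#' @param L_div divergence sites per unit.
#' @param n haploid sample size.
#' @param genes_per_unit genes per unit (the bootstrap resampling
#'   unit).
#' @param theta_site per-site scaled mutation rate (4 Ne u); 0.001 is a
#'   typical human value.
#' @param d_neu neutral per-site divergence; 0.01 is the approximate
#'   human-chimp synonymous divergence.
#' @param B default bootstrap replicates for downstream fitting.
#' @param rsa_link `"none"` for an RSA covariate independent of the
#'   truth, `"adaptive"` to tie RSA monotonically to the unit's
#'   adaptive rate.
#' @param zero_noise if `TRUE`, counts equal their expectations exactly
#'   (for oracle tests).
#' @param seed integer seed.
#' @return Object of class `sim_scenario`.
#' @export
sim_scenario <- function(n_units = 30L, beta = 0.4,
                         s_mean_range = c(50, 5000), contraction = 0.2,
                         adaptive = 0, L = 3e5, L_div = 1e6, n = 20L,
                         genes_per_unit = 20L, theta_site = 1e-3,
                         d_neu = 0.01, B = 50L,
                         rsa_link = c("none", "adaptive"),
                         zero_noise = FALSE, seed = 1L) {
  .check_number(n_units, "n_units", positive = TRUE)
  .check_number(beta, "beta", positive = TRUE)
  .check_number(contraction, "contraction", positive = TRUE)
  .check_number(L, "L", positive = TRUE)
  .check_number(L_div, "L_div", positive = TRUE)
  .check_number(n, "n", positive = TRUE)
  .check_number(genes_per_unit, "genes_per_unit", positive = TRUE)
  if (length(s_mean_range) != 2L || any(s_mean_range <= 0))
    .stopf("s_mean_range must be two positive numbers")
  if (!is.function(adaptive)) .check_number(adaptive, "adaptive",
                                            nonneg = TRUE)
  structure(list(
    n_units = as.integer(n_units), beta = beta,
    s_mean_range = sort(as.numeric(s_mean_range)),
    contraction = contraction, adaptive = adaptive,
    L = L, L_div = L_div, n = as.integer(n),
    genes_per_unit = as.integer(genes_per_unit),
    theta_site = theta_site, d_neu = d_neu, B = as.integer(B),
    rsa_link = match.arg(rsa_link), zero_noise = isTRUE(zero_noise),
    seed = as.integer(seed)),
    class = "sim_scenario")
}

.adaptive_rate <- function(scenario, s_mean) {
  if (is.function(scenario$adaptive)) scenario$adaptive(s_mean)
  else rep_len(scenario$adaptive, length(s_mean))
}

#' Simulate one analysis unit
#'
#' Selected SFS counts are Poisson draws around the
#' [expected_sfs()] expectation at population size N_p; neutral counts
#' around the neutral expectation with the same theta; substitution
#' counts are Poisson with neutral rate `d_neu` and selected rate
#' `d_neu * (omega_na(N_d) + a)`, where omega_na at the divergence
#' phase uses mean effect `s_mean / contraction`. Sites are spread
#' uniformly over genes to give the bootstrap its resampling structure.
#'
#' @param scenario a [sim_scenario()].
#' @param s_mean mean |S| of this unit at N_p.
#' @param a adaptive rate of this unit.
#' @param seed integer seed.
#' @param opts [fit_options()] controlling the expectation quadrature.
#' @return List with `unit` (a [gene_unit()]) and `truth` (one-row data
#'   frame with the exact expected rates, including the apparent
#'   omega_a the two-epoch model predicts).
#' @export
simulate_unit <- function(scenario, s_mean, a = NULL, seed = NULL,
                          opts = fit_options()) {
  stopifnot(inherits(scenario, "sim_scenario"))
  a <- a %||% .adaptive_rate(scenario, s_mean)
  n <- scenario$n; G <- scenario$genes_per_unit
  dfe_p <- gamma_dfe(scenario$beta, s_mean)
  dfe_d <- gamma_dfe(scenario$beta, s_mean / scenario$contraction)
  theta <- scenario$L * scenario$theta_site
  e_sel <- expected_sfs(theta, n, dfe_p, opts) / G
  e_neu <- expected_sfs(theta, n, NULL, opts) / G
  omega_na_Nd <- omega_na_from_dfe(dfe_d, opts)
  omega_na_Np <- omega_na_from_dfe(dfe_p, opts)
  lam_neu <- scenario$L_div * scenario$d_neu / G
  lam_sel <- lam_neu * (omega_na_Nd + a)
  draw <- function(mu, k) {
    if (scenario$zero_noise) matrix(rep(mu, k), nrow = k, byrow = TRUE)
    else matrix(stats::rpois(k * length(mu), rep(mu, each = k)), nrow = k)
  }
  unit <- with_seed(seed, {
    sel <- draw(e_sel, G); neu <- draw(e_neu, G)
    d_sel <- if (scenario$zero_noise) rep(lam_sel, G)
             else stats::rpois(G, lam_sel)
    d_neu <- if (scenario$zero_noise) rep(lam_neu, G)
             else stats::rpois(G, lam_neu)
    gene_unit(sel, neu, d_sel = d_sel, d_neu = d_neu,
              l_sel = rep(scenario$L_div / G, G),
              l_neu = rep(scenario$L_div / G, G),
              n = n, L_sel = rep(scenario$L / G, G),
              L_neu = rep(scenario$L / G, G))
  })
  truth <- data.frame(
    s_mean = s_mean, beta = scenario$beta, a = a,
    omega_na_Nd = omega_na_Nd, omega_na_Np = omega_na_Np,
    omega_expected = omega_na_Nd + a,
    omega_a_expected = omega_na_Nd + a - omega_na_Np)
  list(unit = unit, truth = truth)
}

#' Simulate a complete study
#'
#' Generates `n_units` units whose mean selection strengths follow a
#' log-spaced gradient linked to a synthetic covariate (linear in
#' log s_mean, standing in for delta-volume or delta-polarity), plus an
#' RSA covariate, and attaches the exact theory truth per unit.
#'
#' @param scenario a [sim_scenario()].
#' @param opts [fit_options()] for the expectation quadrature.
#' @return List with `units` (list of [gene_unit()]s), `covariates`
#'   (data frame: unit, covariate, rsa), `truth` (data frame) and the
#'   scenario.
#' @export
simulate_study <- function(scenario, opts = fit_options()) {
  stopifnot(inherits(scenario, "sim_scenario"))
  U <- scenario$n_units
  s_means <- exp(seq(log(scenario$s_mean_range[1]),
                     log(scenario$s_mean_range[2]), length.out = U))
  a_vals <- .adaptive_rate(scenario, s_means)
  seeds <- child_seeds(scenario$seed, U + 1L)
  units <- vector("list", U)
  truth <- vector("list", U)
  for (u in seq_len(U)) {
    sim <- simulate_unit(scenario, s_means[u], a_vals[u], seeds[u], opts)
    units[[u]] <- sim$unit
    truth[[u]] <- cbind(unit = u, sim$truth)
  }
  rsa <- with_seed(seeds[U + 1L], {
    base <- (seq_len(U) - 0.5) / U
    if (scenario$rsa_link == "adaptive")
      base[order(order(a_vals + stats::runif(U) * 1e-9))]
    else sample(base)
  })
  covariates <- data.frame(unit = seq_len(U),
                           covariate = log(s_means), rsa = rsa)
  list(units = units, covariates = covariates,
       truth = do.call(rbind, truth), scenario = scenario)
}

#' Generate a codon-resolved site table
#'
#' Emits polymorphism and divergence rows realizing requested
#' amino-acid-pair changes and four-fold synonymous changes, plus an
#' RSA table, for exercising the site-level pipeline; counts round-trip
#' exactly through [build_pair_unit()].
#'
#' @param pair_requests data frame with columns `aa1`, `aa2`, `n_poly`,
#'   `n_div`: how many polymorphism and divergence rows to emit per
#'   amino-acid pair.
#' @param fourfold_requests data frame with columns `type` (mutational
#'   type label, e.g. `"C:G"`), `n_poly`, `n_div` for the synonymous
#'   comparator rows.
#' @param n haploid sample size recorded on polymorphism rows.
#' @param n_genes genes to spread sites over.
#' @param seed integer seed.
#' @return List with `sites` (the site table), `rsa` (per-site RSA
#'   values) and `codon_freqs` (uniform genomic codon frequencies).
#' @export
make_site_table <- function(pair_requests, fourfold_requests, n = 20L,
                            n_genes = 5L, seed = 1L) {
  pairs <- single_step_pairs()
  ff <- fourfold_steps_by_type()
  rows <- list()
  idx <- 0L
  with_seed(seed, {
    emit <- function(steps, count, category) {
      for (j in seq_len(count)) {
        k <- sample.int(nrow(steps), 1L)
        idx <<- idx + 1L
        rows[[length(rows) + 1L]] <<- data.frame(
          gene = paste0("g", sample.int(n_genes, 1L)),
          codon_idx = idx, category = category,
          codon_from = steps$codon_a[k], codon_to = steps$codon_b[k],
          count = if (category == "polymorphism")
            sample.int(n - 1L, 1L, prob = 1 / seq_len(n - 1L))
            else NA_integer_,
          n = if (category == "polymorphism") as.integer(n) else
            NA_integer_,
          stringsAsFactors = FALSE)
      }
    }
    if (!is.null(pair_requests)) for (i in seq_len(nrow(pair_requests))) {
      key <- paste(sort(c(pair_requests$aa1[i], pair_requests$aa2[i])),
                   collapse = ":")
      pr <- pairs[[key]]
      if (is.null(pr)) .stopf("amino acids %s are not a single-step pair",
                              key)
      emit(pr$steps, pair_requests$n_poly[i], "polymorphism")
      emit(pr$steps, pair_requests$n_div[i], "divergence")
    }
    if (!is.null(fourfold_requests))
      for (i in seq_len(nrow(fourfold_requests))) {
        steps <- ff[[fourfold_requests$type[i]]]
        if (is.null(steps) || !nrow(steps))
          .stopf("unknown mutational type '%s'", fourfold_requests$type[i])
        emit(steps, fourfold_requests$n_poly[i], "polymorphism")
        emit(steps, fourfold_requests$n_div[i], "divergence")
      }
    sites <- do.call(rbind, rows)
    rsa <- data.frame(gene = sites$gene, codon_idx = sites$codon_idx,
                      rsa = stats::runif(nrow(sites)))
    freqs <- rep(1 / 64, 64)
    names(freqs) <- names(Biostrings::GENETIC_CODE)
    list(sites = sites, rsa = rsa, codon_freqs = freqs)
  })
}
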
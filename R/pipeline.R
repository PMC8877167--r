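# Assembles analysis units - amino-acid pairs with matched four-fold
# synonymous comparators, RSA bins, BGC-restricted variants - and
# drives the full fit-and-regress analysis.

.pair_key <- function(a, b) ifelse(a < b, paste(a, b, sep = "|"),
                                   paste(b, a, sep = "|"))

.check_site_table <- function(sites) {
  need <- c("gene", "codon_idx", "category", "codon_from", "codon_to",
            "count", "n")
  if (!all(need %in% names(sites)))
    .stopf("site table must have columns %s", paste(need, collapse = ", "))
  if (!all(sites$category %in% c("polymorphism", "divergence")))
    .stopf("category must be 'polymorphism' or 'divergence'")
  poly <- sites$category == "polymorphism"
  if (any(poly & (is.na(sites$count) | is.na(sites$n) |
                  sites$count <= 0 | sites$count >= sites$n)))
    .stopf("polymorphism rows need 0 < derived count < n")
  invisible(sites)
}

# per-gene class tallies of matching polymorphism rows -> matrix G x (n-1)
.tally_by_gene <- function(rows, genes, n) {
  m <- matrix(0, nrow = length(genes), ncol = n - 1L,
              dimnames = list(genes, NULL))
  if (nrow(rows)) {
    t <- tapply(rep(1, nrow(rows)), list(rows$gene, rows$count), sum)
    for (g in rownames(t)) for (cl in colnames(t))
      if (!is.na(t[g, cl])) m[g, as.integer(cl)] <- t[g, cl]
  }
  m
}

.div_by_gene <- function(rows, genes) {
  v <- stats::setNames(rep(0, length(genes)), genes)
  if (nrow(rows)) {
    t <- table(rows$gene)
    v[names(t)] <- as.numeric(t)
  }
  v
}

#' Build an amino-acid-pair analysis unit from a site table
#'
#' Selected polymorphism and divergence come from the codon changes
#' realizing the pair's single-nucleotide steps. The neutral comparator
#' is built from third-position changes within four-fold degenerate
#' families that share the pair's mutational types; when several types
#' connect the pair, the per-type comparator spectra are averaged with
#' weights given by the genomic frequencies of the pair's codons
#' participating in each type (uniform frequencies by default), and
#' comparator divergence is averaged with the same weights. Site tables
#' list variant rows only, so unit-level omega is a count ratio;
#' synthetic [gene_unit()]s carry true site totals.
#'
#' @param pair an `aa_pair` from [single_step_pairs()].
#' @param sites a site table (see [make_site_table()]).
#' @param codon_freqs named numeric vector of genomic codon
#'   frequencies; `NULL` for uniform.
#' @param bgc_only restrict to BGC-neutral (`A:T`, `C:G`) steps; rows
#'   of other types are dropped from both the selected and comparator
#'   side.
#' @param property_table physico-chemical table for the covariates, per
#'   [aa_properties()].
#' @return Object of class `unit_record`: aggregated spectra, counts, a
#'   [gene_unit()] for bootstrapping, and covariates. Units with no
#'   qualifying selected sites are returned with `empty = TRUE` rather
#'   than raising an error.
#' @export
build_pair_unit <- function(pair, sites, codon_freqs = NULL,
                            bgc_only = FALSE,
                            property_table = aa_properties()) {
  stopifnot(inherits(pair, "aa_pair"))
  .check_site_table(sites)
  steps <- pair$steps
  if (bgc_only) steps <- steps[steps$bgc_neutral, ]
  id <- paste(pair$aa, collapse = ":")
  diss <- pair_dissimilarity(pair, property_table)
  empty_unit <- function() structure(
    list(id = id, pair = pair, empty = TRUE, sel = NULL, neu = NULL,
         div = NULL, unit = NULL,
         covariates = list(dvolume = diss[["dvolume"]],
                           dpolarity = diss[["dpolarity"]],
                           pnps = NA_real_, pnps2 = NA_real_)),
    class = "unit_record")
  if (!nrow(steps)) return(empty_unit())

  sel_keys <- .pair_key(steps$codon_a, steps$codon_b)
  key <- .pair_key(sites$codon_from, sites$codon_to)
  sel_poly <- sites[sites$category == "polymorphism" & key %in% sel_keys, ]
  sel_div <- sites[sites$category == "divergence" & key %in% sel_keys, ]
  if (!nrow(sel_poly)) return(empty_unit())
  n <- unique(sel_poly$n)
  if (length(n) != 1L) .stopf("mixed sample sizes among matching rows")

  types <- unique(steps$type)
  ff <- fourfold_steps_by_type()[types]
  # type weights: genomic frequency of the pair's codons participating
  # in each type's steps
  freq_of <- function(codons) {
    if (is.null(codon_freqs)) length(codons)
    else sum(codon_freqs[codons], na.rm = TRUE)
  }
  w_type <- vapply(types, function(t) {
    st <- steps[steps$type == t, ]
    freq_of(unique(c(st$codon_a, st$codon_b)))
  }, numeric(1))
  if (!any(w_type > 0)) w_type[] <- 1
  w_type <- w_type / sum(w_type)

  genes <- sort(unique(sites$gene))
  sel_m <- .tally_by_gene(sel_poly, genes, n)
  d_sel_g <- .div_by_gene(sel_div, genes)
  neu_m <- matrix(0, nrow = length(genes), ncol = n - 1L,
                  dimnames = list(genes, NULL))
  d_neu_g <- stats::setNames(rep(0, length(genes)), genes)
  for (ti in seq_along(types)) {
    fkeys <- .pair_key(ff[[ti]]$codon_a, ff[[ti]]$codon_b)
    np <- sites[sites$category == "polymorphism" & key %in% fkeys, ]
    nd <- sites[sites$category == "divergence" & key %in% fkeys, ]
    if (nrow(np) && !all(np$n == n))
      .stopf("mixed sample sizes between selected and comparator rows")
    neu_m <- neu_m + w_type[ti] * .tally_by_gene(np, genes, n)
    d_neu_g <- d_neu_g + w_type[ti] * .div_by_gene(nd, genes)
  }

  G <- length(genes)
  unit <- gene_unit(sel_m, neu_m,
                    d_sel = d_sel_g, d_neu = d_neu_g,
                    l_sel = rep(1 / G, G), l_neu = rep(1 / G, G),
                    n = n, genes = genes)
  agg <- aggregate_genes(unit)
  p_n <- sum(agg$sel$counts); p_s <- sum(agg$neu$counts)
  structure(list(
    id = id, pair = pair, empty = FALSE,
    sel = agg$sel, neu = agg$neu, div = agg$div, unit = unit,
    covariates = list(dvolume = diss[["dvolume"]],
                      dpolarity = diss[["dpolarity"]],
                      pnps = if (p_s > 0) p_n / p_s else NA_real_,
                      pnps2 = NA_real_)),
    class = "unit_record")
}

#' @export
print.unit_record <- function(x, ...) {
  if (x$empty) {
    cat(sprintf("<unit %s: empty (no qualifying selected sites)>\n", x$id))
  } else {
    cat(sprintf("<unit %s: p_N = %g, p_S = %g, D_sel = %g, D_neu = %g>\n",
                x$id, sum(x$sel$counts), sum(x$neu$counts),
                x$div$d_sel, x$div$d_neu))
  }
  invisible(x)
}

#' Split a unit's spectra for independent pN/pS estimation
#'
#' Each gene's selected and neutral class counts are partitioned
#' fairly (binomial with probability 1/2, the hypergeometric split
#' conditional on totals) into two halves: the first half replaces the
#' unit's fitting spectra, the second yields the `pnps2` covariate, so
#' the polymorphism statistic and the fitted rates use disjoint data.
#'
#' @param unit a non-empty `unit_record`, or a [gene_unit()].
#' @param seed integer seed (deterministic split).
#' @return The unit with halved fitting data and `covariates$pnps2`
#'   set. For a bare `gene_unit`, a list with `unit` and `pnps2`.
#' @export
split_for_pnps <- function(unit, seed) {
  gu <- if (inherits(unit, "unit_record")) {
    if (unit$empty) .stopf("cannot split an empty unit")
    unit$unit
  } else unit
  stopifnot(inherits(gu, "gene_unit"))
  halves <- with_seed(seed, {
    sel1 <- matrix(stats::rbinom(length(gu$sel_counts),
                                 as.integer(gu$sel_counts), 0.5),
                   nrow = nrow(gu$sel_counts),
                   dimnames = dimnames(gu$sel_counts))
    neu1 <- matrix(stats::rbinom(length(gu$neu_counts),
                                 as.integer(gu$neu_counts), 0.5),
                   nrow = nrow(gu$neu_counts),
                   dimnames = dimnames(gu$neu_counts))
    list(sel1 = sel1, neu1 = neu1)
  })
  sel2 <- gu$sel_counts - halves$sel1
  neu2 <- gu$neu_counts - halves$neu1
  pnps2 <- if (sum(neu2) > 0) sum(sel2) / sum(neu2) else NA_real_
  gu1 <- gene_unit(halves$sel1, halves$neu1, d_sel = gu$d_sel,
                   d_neu = gu$d_neu, l_sel = gu$l_sel, l_neu = gu$l_neu,
                   n = gu$n, genes = gu$genes,
                   L_sel = gu$L_sel / 2, L_neu = gu$L_neu / 2,
                   folded = gu$folded)
  if (inherits(unit, "unit_record")) {
    agg <- aggregate_genes(gu1)
    unit$unit <- gu1
    unit$sel <- agg$sel; unit$neu <- agg$neu
    unit$covariates$pnps2 <- pnps2
    unit
  } else list(unit = gu1, pnps2 = pnps2)
}

#' Assign sites to RSA bins of near-equal size
#'
#' Quantile binning: sites are ordered by RSA (stable order for ties)
#' and cut into `k` contiguous groups whose sizes differ by at most
#' one. With heavily tied RSA values the realized quantile boundaries
#' can repeat; a warning is emitted since such bins are then not
#' strictly separated in RSA.
#'
#' @param rsa data frame with columns `gene`, `codon_idx`, `rsa`
#'   (values in `[0, 1]`).
#' @param k number of bins (default 20).
#' @return The input with a `bin` column (1-based, nondecreasing in
#'   RSA); per-bin mean RSA is attached as attribute `bin_means`.
#' @export
bin_sites_by_rsa <- function(rsa, k = 20L) {
  if (!all(c("gene", "codon_idx", "rsa") %in% names(rsa)))
    .stopf("rsa table must have columns gene, codon_idx, rsa")
  if (any(rsa$rsa < 0 | rsa$rsa > 1)) .stopf("RSA values must lie in [0, 1]")
  k <- as.integer(k)
  if (k < 2L) .stopf("k must be at least 2")
  if (nrow(rsa) < k) .stopf("fewer sites (%d) than bins (%d)", nrow(rsa), k)
  ord <- order(rsa$rsa)  # stable for ties
  sizes <- rep(nrow(rsa) %/% k, k)
  extra <- nrow(rsa) %% k
  if (extra) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  bin <- integer(nrow(rsa))
  bin[ord] <- rep(seq_len(k), times = sizes)
  out <- rsa
  out$bin <- bin
  if (length(unique(rsa$rsa)) < k)
    warning("heavily tied RSA values: bins are not strictly separated")
  attr(out, "bin_means") <- tapply(out$rsa, out$bin, mean)
  out
}

#' Randomly reallocate genes to RSA bins
#'
#' Permutes bins at the gene level: each gene's modal bin label is
#' reassigned by a random permutation of the genes' modal bins, and all
#' of the gene's sites follow it. The multiset of gene-level bin
#' assignments is preserved exactly; site-level bin sizes vary with
#' gene sizes. Used for the randomization test of the RSA-rate
#' correlation.
#'
#' @param assignment output of [bin_sites_by_rsa()].
#' @param seed integer seed.
#' @return The assignment with permuted `bin` values.
#' @export
randomize_bins <- function(assignment, seed) {
  if (!all(c("gene", "bin") %in% names(assignment)))
    .stopf("assignment must have gene and bin columns")
  modal <- vapply(split(assignment$bin, assignment$gene), function(b)
    as.integer(names(sort(table(b), decreasing = TRUE))[1]), integer(1))
  perm <- with_seed(seed, sample(modal))
  names(perm) <- names(modal)
  out <- assignment
  out$bin <- unname(perm[as.character(out$gene)])
  attr(out, "bin_means") <- tapply(out$rsa, out$bin, mean)
  out
}

# ---- full pipeline ---------------------------------------------------

.fit_unit_row <- function(gu, B, seed, opts, boot = TRUE) {
  if (boot) {
    bt <- bootstrap_by_gene(gu, B = B, seed = seed, opts = opts)
    fit <- bt$fit
    c(beta_hat = fit$dfe$beta, s_mean_hat = fit$dfe$s_mean,
      omega = fit$omega, omega_na = fit$omega_na, omega_a = fit$omega_a,
      alpha = fit$alpha, var_omega_a = bt$var_omega_a,
      var_omega_na = bt$var_omega_na)
  } else {
    agg <- aggregate_genes(gu)
    fit <- adaptive_rates(fit_gamma_zero(agg$sel, agg$neu, opts, seed),
                          agg$div)
    c(beta_hat = fit$dfe$beta, s_mean_hat = fit$dfe$s_mean,
      omega = fit$omega, omega_na = fit$omega_na, omega_a = fit$omega_a,
      alpha = fit$alpha, var_omega_a = NA_real_, var_omega_na = NA_real_)
  }
}

.regress_block <- function(units_df, xvars, weighted = TRUE) {
  rows <- list()
  for (stat in c("omega_a", "omega_na")) {
    vcol <- paste0("var_", stat)
    for (xv in xvars) {
      ok <- is.finite(units_df[[xv]]) & is.finite(units_df[[stat]])
      if (weighted) ok <- ok & is.finite(units_df[[vcol]]) &
          units_df[[vcol]] > 0
      if (sum(ok) < 3L) next
      fit <- if (weighted)
        weighted_linear_fit(units_df[[xv]][ok], units_df[[stat]][ok],
                            units_df[[vcol]][ok])
      else unweighted_fit(units_df[[xv]][ok], units_df[[stat]][ok])
      rows[[length(rows) + 1L]] <- data.frame(
        statistic = stat, factor = xv, slope = fit$slope,
        se = fit$slope_se, r = fit$r, p_value = fit$p_value, n = fit$n,
        sig = significance_code(fit$p_value))
    }
  }
  do.call(rbind, rows)
}

# log mean |S| diagnostics (unweighted, as in the artifact check)
.log_s_block <- function(units_df, xvars) {
  rows <- list()
  for (xv in xvars) {
    ok <- is.finite(units_df[[xv]]) & is.finite(units_df$s_mean_hat) &
      units_df$s_mean_hat > 0
    if (sum(ok) < 3L) next
    fit <- unweighted_fit(units_df[[xv]][ok],
                          log(units_df$s_mean_hat[ok]))
    rows[[length(rows) + 1L]] <- data.frame(
      statistic = "log_mean_S", factor = xv, slope = fit$slope,
      se = fit$slope_se, r = fit$r, p_value = fit$p_value, n = fit$n,
      sig = significance_code(fit$p_value))
  }
  do.call(rbind, rows)
}

#' Run the full analysis pipeline
#'
#' Two modes share the same fit-and-regress engine. In synthetic mode
#' (`config$scenario` set) a study is simulated, each unit is
#' optionally split for independent pN/pS, fitted with the GammaZero
#' estimator, bootstrapped by gene for variances, and the rates are
#' regressed on the covariates (the s_mean-linked covariate, RSA, and
#' pN2/pS2) by reciprocal-variance weighting, with log mean |S|
#' diagnostics alongside. In site-table mode (`config$sites` set) the
#' units are amino-acid pairs built against their four-fold
#' comparators, optionally BGC-restricted, with data-poor units (below
#' `min_p_s` synonymous polymorphisms or `min_d_neu` neutral
#' substitutions) flagged and excluded from regressions.
#'
#' Outputs are a deterministic function of (inputs, config, seed).
#'
#' @param config a list. Common keys: `seed`, `B` (bootstrap
#'   replicates), `bootstrap` (logical), `split_pnps` (logical),
#'   `opts` (a [fit_options()]), `folded`, `epsilon`. Synthetic mode:
#'   `scenario` (a [sim_scenario()]). Site-table mode: `sites`, and
#'   optionally `codon_freqs`, `bgc_only`, `min_p_s`, `min_d_neu`,
#'   `property_table`.
#' @return List with `units` (per-unit table), `regressions`,
#'   `log_s_table`, and mode-specific extras (`truth` for synthetic
#'   runs; `excluded` unit ids for site-table runs).
#' @export
run_pipeline <- function(config) {
  if (!is.list(config)) .stopf("config must be a list")
  epsilon <- config$epsilon %||% 0
  folded <- isTRUE(config$folded)
  if (folded && epsilon > 0)
    .stopf("config error: 'folded' and 'epsilon' contradict (misorientation is meaningless for folded spectra)")
  opts <- config$opts %||% fit_options(epsilon = epsilon)
  seed <- config$seed %||% 1L
  boot <- config$bootstrap %||% TRUE
  split_pnps <- config$split_pnps %||% TRUE
  if (!is.null(config$scenario)) {
    .pipeline_synthetic(config, opts, seed, boot, split_pnps)
  } else if (!is.null(config$sites)) {
    .pipeline_sites(config, opts, seed, boot, split_pnps)
  } else .stopf("config error: supply either 'scenario' or 'sites'")
}

.pipeline_synthetic <- function(config, opts, seed, boot, split_pnps) {
  scenario <- config$scenario
  stopifnot(inherits(scenario, "sim_scenario"))
  B <- config$B %||% scenario$B
  study <- simulate_study(scenario, opts)
  U <- length(study$units)
  seeds <- child_seeds(seed, 2L * U)
  rows <- vector("list", U)
  for (u in seq_len(U)) {
    gu <- study$units[[u]]
    pnps_full <- sum(gu$sel_counts) / max(1, sum(gu$neu_counts))
    pnps2 <- NA_real_
    if (split_pnps) {
      sp <- split_for_pnps(gu, seeds[u])
      gu <- sp$unit
      pnps2 <- sp$pnps2
    }
    est <- .fit_unit_row(gu, B, seeds[U + u], opts, boot)
    rows[[u]] <- data.frame(unit = u,
                            covariate = study$covariates$covariate[u],
                            rsa = study$covariates$rsa[u],
                            pnps = pnps_full, pnps2 = pnps2,
                            t(est))
  }
  units_df <- do.call(rbind, rows)
  xvars <- c("covariate", "rsa", if (split_pnps) "pnps2" else "pnps")
  list(units = units_df,
       regressions = .regress_block(units_df, xvars, weighted = boot),
       log_s_table = .log_s_block(units_df, xvars),
       truth = study$truth, scenario = scenario, seed = seed)
}

.pipeline_sites <- function(config, opts, seed, boot, split_pnps) {
  sites <- .check_site_table(config$sites)
  bgc_only <- isTRUE(config$bgc_only)
  min_p_s <- config$min_p_s %||% 1
  min_d_neu <- config$min_d_neu %||% 1
  B <- config$B %||% 50L
  prop <- config$property_table %||% aa_properties()
  pairs <- single_step_pairs(bgc_neutral_only = bgc_only)
  seeds <- child_seeds(seed, 2L * length(pairs))
  rows <- list(); excluded <- character()
  for (i in seq_along(pairs)) {
    ur <- build_pair_unit(pairs[[i]], sites,
                          codon_freqs = config$codon_freqs,
                          bgc_only = bgc_only, property_table = prop)
    if (ur$empty) { excluded <- c(excluded, ur$id); next }
    if (sum(ur$neu$counts) < min_p_s || ur$div$d_neu < min_d_neu) {
      excluded <- c(excluded, ur$id); next
    }
    if (split_pnps) ur <- split_for_pnps(ur, seeds[i])
    can_boot <- boot && length(ur$unit$genes) >= 2L
    est <- .fit_unit_row(ur$unit, B, seeds[length(pairs) + i], opts,
                         can_boot)
    rows[[length(rows) + 1L]] <- data.frame(
      unit = ur$id, dvolume = ur$covariates$dvolume,
      dpolarity = ur$covariates$dpolarity, pnps = ur$covariates$pnps,
      pnps2 = ur$covariates$pnps2 %||% NA_real_, t(est))
  }
  units_df <- if (length(rows)) do.call(rbind, rows) else NULL
  xvars <- c("dvolume", "dpolarity", if (split_pnps) "pnps2" else "pnps")
  list(units = units_df,
       regressions = if (!is.null(units_df))
         .regress_block(units_df, xvars, weighted = boot) else NULL,
       log_s_table = if (!is.null(units_df))
         .log_s_block(units_df, xvars) else NULL,
       excluded = excluded, bgc_only = bgc_only, seed = seed)
}
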
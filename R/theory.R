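# Closed-form model of the bias in MK-style estimates of the adaptive
# substitution rate when the effective population size differs between
# the divergence and polymorphism phases.
#
# Under a gamma distribution (shape beta) of deleterious effects with
# mean scaled strength s_bar, the nonsynonymous/synonymous substitution
# rate behaves asymptotically as omega ~ k (N s_bar)^(-beta). Because
# omega reflects the divergence-phase size N_d while omega_na is
# inferred from polymorphism sampled at N_p, the MK difference
# omega_a' = omega - omega_na picks up a bias term whenever N_p != N_d,
# and that bias depends on s_bar - hence the artifactual correlation
# with any covariate of the mean selection strength.

#' Parameters of the two-epoch bias model
#'
#' @param beta gamma shape of the distribution of deleterious effects.
#' @param s_bar mean absolute scaled selection strength against
#'   deleterious mutations (enters only through products `N * s_bar`).
#' @param N_d effective population size during the divergence phase.
#' @param N_p effective population size pertaining to the polymorphism
#'   data.
#' @param k,m free positive constants of the omega and pN/pS power laws;
#'   only ratios and signs matter for the qualitative predictions, so
#'   both default to 1.
#' @param adaptive_fn optional adaptive rate as a function of `s_bar`
#'   (the A(s_bar) term); `NULL` means no adaptive evolution. See
#'   [adaptive_constant()] and [adaptive_power()].
#' @return An object of class `theory_params`.
#' @export
theory_params <- function(beta, s_bar, N_d, N_p, k = 1, m = 1,
                          adaptive_fn = NULL) {
  .check_number(beta, "beta", positive = TRUE)
  .check_number(s_bar, "s_bar", positive = TRUE)
  .check_number(N_d, "N_d", positive = TRUE)
  .check_number(N_p, "N_p", positive = TRUE)
  .check_number(k, "k", positive = TRUE)
  .check_number(m, "m", positive = TRUE)
  if (!is.null(adaptive_fn) && !is.function(adaptive_fn))
    .stopf("adaptive_fn must be NULL or a function of s_bar")
  structure(list(beta = beta, s_bar = s_bar, N_d = N_d, N_p = N_p,
                 k = k, m = m, adaptive_fn = adaptive_fn),
            class = "theory_params")
}

#' Constant adaptive rate
#' @param a nonnegative adaptive substitution rate relative to the
#'   mutation rate.
#' @return Function of `s_bar` returning `a`.
#' @export
adaptive_constant <- function(a) {
  .check_number(a, "a", nonneg = TRUE)
  function(s_bar) rep_len(a, length(s_bar))
}

#' Power-law adaptive rate
#' @param coef,exponent coefficient and exponent of
#'   `coef * s_bar^exponent`.
#' @return Function of `s_bar`.
#' @export
adaptive_power <- function(coef, exponent) {
  .check_number(coef, "coef", nonneg = TRUE)
  .check_number(exponent, "exponent")
  function(s_bar) coef * s_bar^exponent
}

.adaptive_value <- function(params) {
  if (is.null(params$adaptive_fn)) 0 else {
    a <- params$adaptive_fn(params$s_bar)
    if (any(a < 0)) .stopf("adaptive_fn must be nonnegative")
    a
  }
}

#' Expected nonadaptive substitution rate at population size N
#'
#' The asymptotic power law `k * (N * s_bar)^(-beta)`: evaluated at
#' `N_d` it is the divergence-phase omega (absent adaptation); at `N_p`
#' it is the omega_na that polymorphism-based inference recovers.
#'
#' @param N effective population size.
#' @param params a [theory_params()] object.
#' @export
omega_nonadaptive_expected <- function(N, params) {
  .check_number(N, "N", positive = TRUE)
  stopifnot(inherits(params, "theory_params"))
  params$k * (N * params$s_bar)^(-params$beta)
}

#' Apparent adaptive rate under population-size change
#'
#' `omega_a' = k ((N_p/N_d)^beta - 1) (N_p s_bar)^(-beta) + A(s_bar)`.
#' With no adaptation this is pure bias: positive under expansion
#' (`N_p > N_d`), negative under contraction, and shrinking in
#' magnitude as `s_bar` grows.
#'
#' @inheritParams omega_nonadaptive_expected
#' @export
omega_a_apparent <- function(params) {
  stopifnot(inherits(params, "theory_params"))
  with(params, k * ((N_p / N_d)^beta - 1) * (N_p * s_bar)^(-beta)) +
    .adaptive_value(params)
}

#' Expected pN/pS under the gamma DFE
#'
#' `pN/pS = m * (N_p * s_bar)^(-beta)`.
#' @inheritParams omega_nonadaptive_expected
#' @export
pnps_expected <- function(params) {
  stopifnot(inherits(params, "theory_params"))
  with(params, m * (N_p * s_bar)^(-beta))
}

#' Apparent adaptive rate expressed through pN/pS
#'
#' `omega_a' = (k/m) ((N_p/N_d)^beta - 1) * pN/pS + A(s_bar)`: linear in
#' pN/pS with zero intercept absent adaptation, with slope sign set by
#' the direction of the size change (negative under contraction).
#'
#' @param pnps observed or predicted pN/pS ratio (nonnegative).
#' @inheritParams omega_nonadaptive_expected
#' @export
omega_a_from_pnps <- function(pnps, params) {
  stopifnot(inherits(params, "theory_params"))
  if (any(pnps < 0)) .stopf("pnps must be nonnegative")
  with(params, (k / m) * ((N_p / N_d)^beta - 1) * pnps) +
    .adaptive_value(params)
}

#' Apparent proportion of adaptive substitutions
#'
#' `alpha' = 1 - (N_d/N_p)^beta`; unlike the omega_a bias, this is
#' independent of the strength of selection.
#' @inheritParams omega_nonadaptive_expected
#' @export
alpha_apparent <- function(params) {
  stopifnot(inherits(params, "theory_params"))
  with(params, 1 - (N_d / N_p)^beta)
}

#' Full theory prediction
#'
#' Evaluates every quantity of the bias model and decomposes the
#' apparent adaptive rate into its true component `A(s_bar)` and the
#' bias induced by the size change, so
#' `omega_a_apparent = omega_a_true + omega_a_predicted_bias`.
#'
#' @inheritParams omega_nonadaptive_expected
#' @return Object of class `theory_prediction` (a list of named
#'   numeric components).
#' @export
theory_predict <- function(params) {
  stopifnot(inherits(params, "theory_params"))
  a_true <- .adaptive_value(params)
  apparent <- omega_a_apparent(params)
  structure(list(
    omega = omega_nonadaptive_expected(params$N_d, params) + a_true,
    omega_na = omega_nonadaptive_expected(params$N_p, params),
    omega_a_apparent = apparent,
    alpha_apparent = alpha_apparent(params),
    pnps = pnps_expected(params),
    omega_a_true = a_true,
    omega_a_predicted_bias = apparent - a_true),
    class = "theory_prediction")
}

#' @export
print.theory_prediction <- function(x, ...) {
  cat("<two-epoch MK bias prediction>\n")
  for (f in names(x)) cat(sprintf("  %-22s %.6g\n", f, x[[f]]))
  invisible(x)
}

#' Sweep the bias model over mean selection strengths
#'
#' Convenience table for diagnostics: evaluates pN/pS, the apparent
#' omega_a and alpha over a grid of `s_bar` values with all other
#' parameters fixed.
#'
#' @param params a [theory_params()] object (its `s_bar` is ignored).
#' @param s_bar_values numeric vector of mean selection strengths.
#' @return Data frame with columns `s_bar`, `pnps`, `omega_a_apparent`,
#'   `alpha_apparent`.
#' @export
theory_sweep <- function(params, s_bar_values) {
  stopifnot(inherits(params, "theory_params"))
  rows <- lapply(s_bar_values, function(s) {
    p <- params; p$s_bar <- s
    data.frame(s_bar = s, pnps = pnps_expected(p),
               omega_a_apparent = omega_a_apparent(p),
               alpha_apparent = alpha_apparent(p))
  })
  do.call(rbind, rows)
}
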
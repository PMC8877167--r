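---
title: "Population-size change, MK estimators, and artifactual correlations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population-size change, MK estimators, and artifactual correlations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mkshift)
```

## The problem

McDonald–Kreitman (MK) style estimators of the adaptive substitution
rate contrast divergence with polymorphism: the site frequency spectrum
(SFS) at selected and neutral sites is used to fit a distribution of
fitness effects (DFE), the DFE predicts how much nonadaptive divergence
to expect, and any excess is attributed to positive selection. The
catch is that divergence accumulated at the historical effective
population size $N_d$, while polymorphism reflects the current size
$N_p$. `mkshift` implements (i) a closed-form model of the resulting
bias, (ii) the GammaZero maximum-likelihood estimator that the analyses
rely on, (iii) the site-level pipelines (amino-acid pairs, RSA bins,
BGC filtering) in which the bias matters, and (iv) a synthetic-data
generator with known truth, so the whole chain is testable without any
external data.

## The two-epoch bias model

Assume nonsynonymous mutations are neutral or deleterious with effects
drawn from a gamma distribution with shape $\beta$ and mean scaled
strength $\bar{s}$. Asymptotically the nonsynonymous/synonymous rate
ratio behaves as a power law, $\omega \approx k\,(N\bar{s})^{-\beta}$,
and likewise $p_N/p_S = m\,(N_p\bar{s})^{-\beta}$. Because $\omega$ is
set by $N_d$ while the inferred nonadaptive rate $\omega_{na}$ is set
by $N_p$, the MK difference picks up a bias:

$$\omega_a' \;=\; k\left[(N_p/N_d)^{\beta} - 1\right](N_p\bar{s})^{-\beta} + A(\bar{s}),$$

where $A(\bar{s})$ is any true adaptive component. Three consequences,
all implemented in `theory_predict()` and verified by the test suite:

* the bias is positive under expansion ($N_p > N_d$) and negative
  under contraction;
* its magnitude decreases as $\bar{s}$ grows, so *any* covariate of
  the mean selection strength acquires an artifactual correlation with
  $\omega_a'$ — positive under contraction, negative under expansion —
  and, equivalently, $\omega_a'$ becomes linear in $p_N/p_S$ with a
  slope whose sign is set by the direction of the size change;
* the apparent proportion of adaptive substitutions
  $\alpha' = 1 - (N_d/N_p)^{\beta}$ does not depend on $\bar{s}$ at
  all.

The constants $k$ and $m$ are left symbolic in the source equations;
we default both to 1 since only ratios and signs enter the qualitative
predictions, and both are settable in `theory_params()`. $A(\bar{s})$
is an arbitrary callable (`adaptive_constant()`, `adaptive_power()`).
Everything is expressed through products $N\bar{s}$, so no $2N$ versus
$4N$ convention can leak in; the estimator below states its convention
explicitly.

## The GammaZero estimator

`fit_gamma_zero()` fits a gamma DFE of deleterious effects (convention:
$S = 4N_e s \le 0$, `s_mean` is the mean of $|S|$) to paired
selected/neutral spectra by maximizing independent Poisson likelihoods
over all frequency classes. The expected class-$i$ count is

$$E_i = \theta L \int_0^1 \mathbb{E}_S\!\left[H(S, x)\right]
\binom{n}{i} x^i (1-x)^{n-i}\,dx, \qquad
H(S,x) = \frac{1 - e^{-S(1-x)}}{x(1-x)(1 - e^{-S})},$$

the standard sojourn density of a semidominant mutation under the
Poisson random field, with constants absorbed into $\theta$. The
neutral limit is $\theta L / i$. Crucially, the two site categories
share a single per-site $\theta$ scaled by their site counts $L$: it
is the *level* of the selected spectrum relative to the neutral one
(the $p_N/p_S$ signal) that identifies $\bar{s}$; letting each
category carry a free scaler leaves the mean strength on a likelihood
ridge. $\theta$ (and optional per-class nuisance factors `ri`) are
profiled out in closed form, so the optimizer works in just
$(\log\beta, \log \bar{s})$, Nelder–Mead from three dispersed starts
(weak / intermediate / strong selection), ties broken by likelihood
then smaller $\beta$. Ancestral misorientation (`epsilon`) and folded
spectra are supported but off by default; combining `folded` with
`epsilon` is rejected as contradictory.

Divergence enters only afterwards (`adaptive_rates()`):
$\omega$ is the per-site divergence ratio, $\omega_{na}$ the
expectation of the fixation factor $Q(S) = S/(1-e^{-S})$ under the
fitted DFE, and $\omega_a = \omega - \omega_{na}$,
$\alpha = \omega_a/\omega$. This mirrors the GammaZero workflow of
fitting the DFE to polymorphism only. No byte-level match to any
particular external implementation is attempted; correctness is
established against this package's own simulation oracle and a
fine-resolution quadrature oracle instead.

### Numerical choices

Both integrals are evaluated by composite Gauss–Legendre rules chosen
for uniform relative accuracy:

* **frequency integral**: dyadic panels refined geometrically toward
  $x = 0$ (default 16 points per panel from $10^{-8}$), because under
  strong selection all mass sits in a boundary layer of width
  $\sim 1/|S|$;
* **DFE average**: per-decade panels on $\log|S|$ between $10^{-9}$
  and the far upper gamma quantile, with the probability mass below
  $10^{-9}$ added analytically as exactly neutral. The log scale is
  essential: for small shapes the gamma spreads mass over dozens of
  decades, and for large shapes the SFS is dominated by the extreme
  lower tail.

With the defaults the test suite asserts agreement of the expected SFS
with an independently coded oracle at ten times the resolution to
better than $10^{-6}$ relative error across shapes $0.15{-}1.2$ and
mean strengths $0.5{-}10^5$. Quantile-transform quadratures, tried
first, failed to reach that accuracy uniformly, which is why the
log-grid scheme is the one shipped; very large shapes (point-mass-like
DFEs) additionally densify the $|S|$ panels as $\sqrt{\beta}$, since
the gamma then concentrates in a log-width $\sim 1/\sqrt{\beta}$
spike.

Bootstrap-by-gene (`bootstrap_by_gene()`, default $B = 100$) resamples
genes with replacement and refits. Replicates warm-start from the
full-data maximum with a single optimizer run and a coarser quadrature
— variance estimation does not need $10^{-6}$ integrals — while the
full-data fit keeps the defaults. Replicates that lose all neutral
data are recorded as failed rather than silently dropped.

## Site-level pipelines

`single_step_pairs()` enumerates the 75 amino-acid pairs connected by
one nucleotide change under the standard genetic code (a brute-force
enumeration is the test oracle). For each pair,
`build_pair_unit()` takes selected polymorphism/divergence from the
codon changes realizing the pair's steps and builds the neutral
comparator from third-position changes in four-fold degenerate
families *of the same mutational type*; multi-type pairs get a
weighted average comparator, weighted by the genomic frequencies of
the pair's codons per type. BGC filtering (`bgc_only`) keeps only
A&lt;&gt;T and C&lt;&gt;G changes — it filters *changes*, not pairs,
so a pair survives if at least one of its steps is BGC-neutral and the
number of analyzable pairs is an emergent property of the data, never
hard-coded. On the selected side the restriction is exactly a row
filter; the comparator additionally renormalizes its type weights over
the retained steps, so for a multi-type pair the comparator of a
restricted run equals that of a pre-filtered run up to scale (the
shapes, and hence the fits, agree). Degenerate inputs (no qualifying sites, zero synonymous
polymorphism, zero neutral divergence) yield flagged empty units that
the pipeline excludes from regressions with a record of what was
dropped.

`split_for_pnps()` partitions every frequency class fairly between two
half-spectra (binomial with probability one half, which conditional on
the class total is the hypergeometric split): one half is fitted, the
other supplies the $p_{N2}/p_{S2}$ covariate, removing the sampling
non-independence between the polymorphism statistic and the fitted
rates. `bin_sites_by_rsa()` builds the 20 near-equal occupancy RSA
bins by a stable quantile cut (ties keep input order; heavy ties
trigger a warning), and `randomize_bins()` permutes bins at the gene
level for the randomization control, preserving the multiset of
gene-level assignments exactly — site-level bin sizes then vary with
gene sizes, which is the price of permuting whole genes.

`run_pipeline()` drives either a synthetic study or a site table
through fit, bootstrap, and the regression battery, and is a
deterministic function of (inputs, config, seed).

## Regression machinery

`weighted_linear_fit()` is weighted least squares with
reciprocal-variance weights; the reported $r$ is the weighted Pearson
correlation with the same weights (the weighted model-$R$ is also
emitted as `r_model`, since published analyses do not always say which
convention they used), and the P value is the slope's two-sided
$t$ test — a documented choice, as correlation P values are rarely
specified precisely in the literature this serves.
`compare_slopes()` tests slope equality through the
analysis-of-variance P of a group-by-x interaction in a pooled
weighted model, optionally after dividing each group's response by its
weighted mean (plain-mean toggle available) so rates of different
magnitude can be compared on a common scale.
`randomization_pvalue()` uses add-one smoothing, $(1 + \#\{|t^*| \ge
|t|\})/(1 + R)$: with a finite permutation count an empirical P of
exactly zero would overstate the evidence.

## The synthetic generator

`sim_scenario()` fixes the study conditions; `simulate_study()` draws
them. Per unit, selected SFS counts are Poisson around the model
expectation at $N_p$, neutral counts around $\theta L / i$,
substitutions Poisson with neutral rate `d_neu` and selected rate
`d_neu * (omega_na(N_d) + a)`, with sites spread uniformly over genes.
Noise is Poisson throughout — exactly the assumption the estimator
makes — and a `zero_noise` mode returns the expectations themselves
for exact oracle tests. Defaults, chosen once as the desk-scale study:
30 units, $n = 20$, $\beta = 0.4$, mean strengths log-spaced over
$50{-}5000$, $L = 3\times10^5$ polymorphism sites and $10^6$
divergence sites per unit, 20 genes per unit, $B = 50$,
$\theta_{site} = 10^{-3}$ and neutral divergence $10^{-2}$ (typical
human diversity and human–chimp synonymous divergence), and a 5-fold
contraction ($N_p/N_d = 0.2$), matching the inference that current
hominid effective sizes are 5–10 times below the ancestral size. The
covariate is linear in $\log\bar{s}$ — the theory only requires a
monotone link — and an RSA covariate can be tied to the adaptive
component or left independent.

What the generator does *not* emulate: linkage (sweeps, background
selection), non-equilibrium allele-age effects that give neutral and
selected variation different effective sizes, mis-polarized ancestral
states, base-composition heterogeneity, or real codon usage. Passing
tests therefore demonstrate internal consistency of estimator and
theory under the model's own assumptions, not robustness on real
genomes.

Parameter-recovery and artifact-direction checks in the suite use
these conditions unchanged: shape recovery at $L = 10^6$, and the full
generate–split–fit–bootstrap–regress loop under contraction
(predominantly negative fitted $\omega_a$, negative weighted
correlation with $p_{N2}/p_{S2}$) and expansion (both signs flip).

## Known limitations

* The power-law theory is asymptotic in $N\bar{s}$; the package does
  not police its domain of validity, and end-to-end agreement is only
  asserted at moderately large mean strengths.
* Only the gamma-of-deleterious-effects (GammaZero) DFE family is
  implemented; no lognormal or discrete classes, and no
  demography-aware joint likelihood.
* No multiple-hit correction is applied to divergence (hominid-scale
  divergence is low); site tables with multi-difference codons exclude
  those codons since step attribution is ambiguous.
* Units built from site tables carry only variant rows, so their
  omega is a count ratio unless true site totals are supplied;
  synthetic units carry true totals.
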
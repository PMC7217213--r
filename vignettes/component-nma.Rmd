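---
title: "Component network meta-analysis: model, estimation, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Component network meta-analysis: model, estimation, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnma)
```

## The problem

Evidence networks often contain multicomponent interventions: a trial may
compare `CBT + SSRI` against `SSRI`, another `CBT` against placebo. Standard
network meta-analysis (NMA) treats every distinct combination as its own
node, which is assumption-free but wasteful — a combination assessed in one
small trial is estimated essentially from that trial alone. The component
NMA (CNMA) model assumes the effect of a combination is the **sum of its
component effects** on the analysis scale (log odds ratio, log risk ratio,
mean difference). Under that assumption, equal components cancel in
comparisons (`A+B` vs `A` estimates `B`), every study containing a component
informs it, and the assumption itself can be tested against the standard
model.

## Data model and multi-arm bookkeeping

The unit of analysis is the pairwise comparison: study label, `treat1`,
`treat2`, effect `d = treat1 − treat2`, and its standard error, assumed
known and fixed as usual in meta-analysis. A `p`-arm study must contribute
all `p(p−1)/2` pairwise rows; `nma_network()` enforces this, rejects
duplicated comparisons, and orders treatments, studies and rows
lexicographically (stable) unless the user supplies an explicit order, so
every matrix the package prints is reproducible. Arm-level binary data are
converted by `contrasts_from_arms()` to log odds ratios with the standard
`1/a + 1/(n1−a) + 1/b + 1/(n2−b)` variance; when a 2×2 table of a comparison
contains a zero cell, 0.5 is added to all four cells of *that comparison* (a
conventional continuity correction; the model itself is agnostic to it).

The `p(p−1)/2` contrasts of a multi-arm study are correlated. To use them in
a weighted least-squares model that treats rows as independent, their
standard errors are enlarged (`adjust_multiarm()`) so that the study's
contribution to the network information matrix equals the information matrix
of the joint arm-level generalised least-squares model. The construction
recovers arm variances `s_t` by least squares from `v_jk = s_j + s_k`,
reads the (reconciled) contrast variances as resistance distances, inverts
the double-centred matrix `−0.5 Jc V Jc` to get the study Laplacian, and
takes the adjusted weight of contrast `(j,k)` as minus the corresponding
off-diagonal entry. For a `p`-arm study with equal contrast variances `v`
this gives adjusted variance `v·p/2` (so `1.5 v` for three arms); two-arm
studies are untouched, and the operation is idempotent because adjusted
values are always recomputed from raw standard errors. If the observed
variances are not decomposable to relative accuracy `1e-8` the least-squares
reconciliation is used with a warning; a non-positive implied arm variance
is an error, since no arm-level model can generate it.

## Estimation

All models are weighted least squares with Moore–Penrose pseudoinverses.
With incidence matrix `B` and weights `W`:

* standard NMA: design `X = B`, `delta_nma = X (X'WX)^+ X'W d`, hat matrix
  `H = X (X'WX)^+ X'W`; treatment effects come from the Laplacian
  pseudoinverse `(B'WB)^+` with the reference pinned to zero.
* additive CNMA: design `Xa = B C`, component effects
  `beta = (Xa'WXa)^+ Xa'W d`, treatment effects `theta = C beta`, fitted
  contrasts `delta_a = Xa beta`, covariances `(Xa'WXa)^+`, `C(Xa'WXa)^+C'`
  and `Xa(Xa'WXa)^+Xa'`.
* interaction CNMA: identical machinery on a `C` extended by
  `add_interactions()` — one appended column per interaction, set to 1 for
  every treatment containing all of its components. An interaction that
  occurs in no treatment would yield an all-zero (inestimable) column and is
  rejected. Columns are labelled `A*B` with components sorted; the mechanism
  extends unchanged to three-way terms.

The combination matrix `C` is parsed from treatment labels
(`build_combination()`), splitting on a separator (default `+`, surrounding
whitespace stripped, case-sensitive, matching labels such as
`Face-to-face CBT + SSRI`). An *inactive* treatment (e.g. placebo) gets an
all-zero row and is not counted as a component — an additional modelling
assumption, distinct from merely choosing a reference for reporting. Dose
codings are supported by entering multiplicities greater than 1.

**Identification.** `fit_cnma()` requires `rank(Xa) = c` and otherwise fails
naming the non-identified components (those touched by the null space of
`Xa`). A silent pseudoinverse answer is easy to misread as full
identification; the opt-in `allow_deficient = TRUE` (and the disconnected
path) instead exposes the estimable subspace explicitly via `estimable()`
and `component_contrast()`.

## Heterogeneity, model fit, and the additivity test

Model fit is measured by Cochran's Q under common-effect weights:
`Q = (d − delta_nma)'W(d − delta_nma)` with `n_a − k − (n−1)` degrees of
freedom, and `Qa` with `n_a − k − r`, `r = rank(Xa)`. Because the CNMA
projection is nested inside the NMA projection and the two commute
(`Ha H = Ha = H Ha`), the Q difference is itself a quadratic form —
`Qa − Q = (delta_a − delta_nma)'W(delta_a − delta_nma)` — and is referred to
a chi-square distribution with `n − r − 1` degrees of freedom as a test of
the additivity assumption; nested component models are compared the same way
(`compare_nested()`, df = rank difference). The implementation verifies the
Pythagorean identity numerically on every call.

**Random effects.** The between-study variance is estimated by the
multivariate method of moments,
`tau2 = max((Q − df) / tr((I − H) U W), 0)`, where `U` is the per-study
block diagonal of `0.5 B B'` (for two-arm-only networks `U = I` and the
formula reduces to the generalised DerSimonian–Laird equation; the test
suite cross-checks this against an independent pairwise meta-analysis
implementation). `tau2` is added to every *raw* sampling variance, the
multi-arm adjustment is redone on the enlarged variances, and the model is
refitted. Each design (standard, additive, each interaction model) estimates
its own `tau2` with its own hat matrix and degrees of freedom — the designs
absorb different amounts of inconsistency, so sharing one value would
conflate lack of fit with heterogeneity.

**Which weights for the additivity test?** The Q statistics above use
common-effect weights, and `additivity_test(..., weights = "common")`
(default) reports that classical comparison — it is how the test is usually
quoted alongside random-effects estimates. But when true between-study
variance is present, the common-weight quadratic form is inflated by a
factor of roughly `1 + tau2·w` per comparison and the test over-rejects.
`weights = "random"` therefore re-projects *both* models under shared
weights that include the standard model's `tau2` estimate (a preset-tau2
comparison), which restores approximately nominal size; the package's
calibration study uses this variant. The two variants answer the same
question under different error models; we expose both rather than silently
choosing.

## Disconnected networks

If the comparison graph has several connected components
(`detect_subnets()`), no standard NMA exists — and consequently the
additivity assumption is **not testable**; `additivity_test()` refuses
disconnected fits rather than returning a p-value. The component design
`Xa = B C` may nonetheless have full column rank when the subnets share
components, in which case all component effects are uniquely estimated. With
lower rank, exactly the contrasts in the row space of `Xa` are estimable
(checked by projecting the contrast onto the row space, residual tolerance
`1e-10`). Specifying a reference component drops its column from `C` and
`Xa`, a normalisation that makes the reduced design invertible whenever its
rank equals its column count; reference-dropping and the minimum-norm
pseudoinverse answer agree for every contrast estimable under both
parameterisations. For partially identified fits the reported covariance is
the weighted least-squares covariance of the chosen (restricted)
parameterisation — there is no canonical alternative, and we document rather
than hide that choice.

## The synthetic-network generator

`sim_spec()` / `simulate_network()` generate networks with known truth for
calibration and power studies. Design choices:

* **Truth.** `theta* = C [beta; gamma]`: additive component effects plus
  optional interaction effects for named component pairs.
* **Heterogeneity at the arm level.** Each study draws independent arm
  effects `u_t ~ N(0, tau2/2)`; a contrast receives `u_t1 − u_t2`. This
  realises the contrast-level common-`tau2` random-effects model — variance
  `tau2` per contrast, within-study covariance `tau2 · 0.5 B B'` — while
  keeping within-study consistency exact, which a single per-study scalar
  added to all contrasts would violate.
* **Sampling error at the arm level too**, with arm standard deviations
  drawn as `runif(se_range)/sqrt(2)`, so two-arm contrast standard errors
  fall in `se_range` and multi-arm standard errors decompose exactly into
  arm variances — the precondition of the multi-arm adjustment holds by
  construction.
* **Defaults.** `se_range = c(0.2, 0.5)` on the log odds-ratio scale —
  typical of moderately sized binary-outcome trials in mental-health
  networks; one seeded generator per simulated network, so equal seeds give
  byte-identical data.

What the generator does *not* emulate: selective reporting, dose–response
within a component beyond user-supplied multiplicities, effect modification
by trial-level covariates, and non-normal sampling error in small trials.
Calibration results obtained from it therefore demonstrate correctness of
the estimators under the model's own assumptions, not robustness to their
violation.

## Numerical choices

* Pseudoinverse and rank: singular values below `1e-10` times the largest
  are treated as exact zeros. Connected-network Laplacians have exact rank
  `n − 1`; the tolerance only guards floating-point noise.
* Ordering: treatments, components, studies and contrast rows are sorted
  lexicographically (stable, radix) unless overridden, so all matrices and
  outputs are deterministic.
* `tau2` is truncated at zero; a random-effects fit with truncated `tau2`
  is bit-identical to the common-effect fit.
* Degenerate inputs are typed errors, not NA results: non-positive standard
  errors, incomplete multi-arm blocks, duplicated comparisons, all-zero
  design columns, negative degrees of freedom, rank-0 disconnected designs.
* Wald confidence intervals with normal quantiles on the additive scale,
  no multiplicity adjustment.

## Problem sizes used by the test and acceptance suites

The oracle battery compares the estimators against an independent dense
normal-equations solution on 100 random connected networks (up to 8
treatments, up to ~20 studies, mixed two- and three-arm). The calibration
study uses 500 replicates of a 90-study network on the five-treatment
hypothetical topology (components A, B, C; `beta* = (1, 0.5, −0.2)`;
`tau2 = 0.04`), chosen to match the scale of the published depression
network that motivates the package (93 studies); it checks component bias,
95% CI coverage, and the type-I error of the random-weights additivity test
at `alpha = 0.05`. These sizes keep a full run in the low minutes on one
core.

## Known limitations

* The additivity test has low power for components observed in few studies;
  a non-significant `Qa − Q` is compatibility, not proof, of additivity.
* Interaction selection is left to the user: the package exposes the
  primitives (`add_interactions()`, `compare_nested()`) but no automated
  forward/backward search.
* Within-design/between-design decompositions of Q, node-splitting
  inconsistency models, arm-based models and population-adjusted indirect
  comparisons are out of scope.
* Disconnected fits report restricted-parameterisation covariances;
  uncertainty statements for derived contrasts inherit that choice.
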
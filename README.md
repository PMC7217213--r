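# cnma — frequentist component network meta-analysis

Network meta-analysis (NMA) pools direct and indirect evidence over a graph
of randomised trials to compare many treatments at once. In many evidence
networks the treatments are *multicomponent interventions* — combinations of
drugs, psychotherapies or care components such as `Face-to-face CBT + SSRI`.
Standard NMA gives every distinct combination its own node, so a combination
tested in a single small trial is estimated from that trial alone. Component
NMA (CNMA) instead models each treatment's effect, on an additive scale such
as the log odds ratio, as the sum of the effects of its components, so
studies of the components inform the combination ("borrowing strength"), and
the additivity assumption becomes testable. `cnma` implements this model
family — additive and interaction CNMA, common and random effects, connected
and disconnected networks — for meta-analysts working with contrast- or
arm-level trial data.

## The model

With `m` pairwise comparisons `d` (effect of `treat1` minus `treat2`,
standard errors fixed and known), `n` treatments and diagonal weight matrix
`W` (inverse variances, multi-arm adjusted), the standard NMA estimate is
the weighted least-squares projection

    delta_nma = X (X' W X)^+ X' W d,      X = B,

where `B` is the m×n edge–vertex incidence matrix of the network
(`+1/−1` per compared pair), `(.)^+` the Moore–Penrose pseudoinverse, and
`H = X (X'WX)^+ X'W` the hat matrix. The additive CNMA model inserts the
n×c combination matrix `C` (which components make up each treatment; an
inactive treatment such as placebo has an all-zero row):

    delta_a = Xa beta,   Xa = B C,
    beta_hat = (Xa' W Xa)^+ Xa' W d,   theta_hat = C beta_hat.

Interaction models append columns to `C` (one per interaction, 1 for every
treatment containing all its components). Model fit is measured by Cochran's
Q: `Q = (d − delta_nma)' W (d − delta_nma)` on `n_a − k − (n−1)` degrees of
freedom (`n_a` arms, `k` studies), `Qa` likewise with `df_a = n_a − k − r`,
`r = rank(Xa)`. Because the two projections are nested and commute, the
additivity test is the Pythagorean difference

    Qa − Q = (delta_a − delta_nma)' W (delta_a − delta_nma),   df = n − r − 1.

Random-effects models estimate the between-study variance by the
multivariate method of moments, `tau2 = max((Q − df) / tr((I−H)UW), 0)`,
with `U` the per-study block diagonal of `0.5 B B'`, add it to every raw
sampling variance, redo the multi-arm adjustment, and refit.

In a *disconnected* network no standard NMA exists, but if the subnetworks
share components, `Xa` can still have full rank and the component effects —
or at least the contrasts in the row space of `Xa` — remain estimable.

## Worked example

Six trials of a psychotherapy (CBT), a drug class (SSRI), their combination
and placebo, as log odds ratios:

```r
library(cnma)

trials <- tibble::tibble(
  study  = c("s01", "s02", "s03", "s04", "s05", "s06"),
  treat1 = c("CBT", "SSRI", "CBT+SSRI", "CBT+SSRI", "CBT", "SSRI"),
  treat2 = c("placebo", "placebo", "placebo", "SSRI", "SSRI", "placebo"),
  effect = c(0.55, 0.48, 1.10, 0.62, 0.10, 0.60),
  se     = c(0.22, 0.15, 0.32, 0.28, 0.25, 0.18)
)
net <- nma_network(trials)
standard <- fit_nma(net, effects = "random", reference = "placebo")
additive <- fit_cnma(net, build_combination(net, inactive = "placebo"),
                     effects = "random")

tidy(additive, exponentiate = TRUE)
#> # A tibble: 2 × 5
#>   term  estimate std.error conf.low conf.high
#> 1 CBT       1.80    0.130      1.40      2.33
#> 2 SSRI      1.68    0.0998     1.38      2.05

forest_text(additive)
#> Treatment  OR (95% CI)
#> (compared to placebo)
#> CBT        1.80 [1.40-2.33]
#> CBT+SSRI   3.03 [2.17-4.24]
#> SSRI       1.68 [1.38-2.05]

additivity_test(standard, additive)
#> Model comparison (standard vs additive, common weights)
#>   Q difference = 0.0070, df = 1, p = 0.9334
```

The component rows are the net effects of CBT and SSRI versus placebo as
odds ratios. The combination row is their product on the OR scale
(`1.80 × 1.68 = 3.03`): additivity on the log scale is multiplicativity on
the ratio scale. The additivity test compares the additive model against the
standard model that gives `CBT+SSRI` its own node; here the data are
compatible with additivity (p = 0.93).

Other entry points: `contrasts_from_arms()`/`read_arms()` for arm-level
binary data, `add_interactions()` for interaction models,
`compare_nested()` for nested Q tests, `detect_subnets()` /
`fit_disconnected()` / `component_contrast()` for disconnected networks,
`sim_spec()` / `simulate_network()` for synthetic networks with known truth,
`league_table()`, `component_table()`, `autoplot()` for reporting, and a
command-line interface (`inst/cli/cnma.R`, see `?cli_main`).

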
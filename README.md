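# arcfa: autoregressive confirmatory factor analysis

Survey respondents answer multi-item scales one item at a time, and an
item can leave a trace on the next responses — a memory it activated, an
affective reaction it primed — that has nothing to do with the latent traits
the scale measures. The standard independent-clusters CFA (IC-CFA) assumes
these sequential "context effects" away and routinely pays for it with
measurement-model misfit. `arcfa` implements the autoregressive CFA
(AR-CFA): an ordinary independent-clusters loading structure whose item
*residuals* carry first-order autoregressive effects ordered by item
administration position,

```
y_i = ν + Λ η_i + ε_i,    ε_i = κ ε_i + u_i,    u_i ~ MVN(0, Θ),
Σ    = Λ Ψ Λ' + (I − κ)⁻¹ Θ (I − κ)⁻ᵀ,
```

with κ strictly lower triangular in administration order. Because context
effects travel multiplicatively along AR paths, they fade with distance —
the property that separates the AR-CFA from simply freeing residual
correlations.

The package is aimed at psychometricians and survey methodologists who want
to specify, estimate and compare these models, and at simulation work on
their behavior:

* **Model specification** — `build_ic_cfa()`, `build_ar_cfa()` (adjacent or
  adjacent-plus-construct AR topologies), `build_rc_cfa()` (the equal-df
  residual-correlation comparison model), `apply_equality_constraints()`
  (AR terms pooled by trait pair, optionally split by item-scoring
  pattern), `model_df()`.
* **Maximum-likelihood estimation** — `fit_cfa()` minimizes the normal-theory
  discrepancy with analytic gradients (quasi-Newton plus Newton polish),
  reports observed-information standard errors, a standardized solution,
  delta-method averages of AR effects (`derived_group_mean()`), and
  likelihood-ratio tests with a structural nesting check
  (`likelihood_ratio_test()`).
* **Fit indices** — `fit_indices()` and `comparison_table()`: CFI, TLI,
  RMSEA, SRMR, AIC/BIC (covariance likelihood; deltas and orderings are the
  contract).
* **Simulation** — `make_population()`, `simulate_dataset()`,
  `run_monte_carlo()` for bias/RMSE/convergence studies of IC-CFA vs AR-CFA.
* **Data in** — `read_moments()` (full or lower-triangular published
  correlation matrices with SDs), `read_raw()` (case-level CSV with optional
  group-mean centering), and `minipip_fixture()`: the published 20-item
  Big Five (mini-IPIP) correlation matrix, SDs and N = 8,569 that serve as
  the worked example.
* **Command line** — `inst/cli/arcfa` wraps `arcfa_cli()` with `fit`,
  `compare`, `simulate` and `fixture` subcommands.

## Worked example

The mini-IPIP administers four items per Big Five trait in a repeating
e, a, c, n, o cycle. Fit the IC-CFA and the AR-CFA (19 adjacent + 15
within-construct AR terms) to the bundled published moments:

```r
library(arcfa)
mom <- minipip_fixture()              # published moments, N = 8569
lay <- minipip_layout()               # 20 items, 5 traits, cycled order
ic  <- fit_cfa(build_ic_cfa(lay), mom)
ar  <- fit_cfa(build_ar_cfa(lay, "adjacent_plus_construct"), mom)
comparison_table(list(ic_cfa = ic, ar_cfa = ar), moments = mom)
```

```
              ic_cfa    ar_cfa
AIC        4.898e+05 4.864e+05
BIC        4.902e+05 4.870e+05
CFI        8.029e-01 9.016e-01
TLI        7.659e-01 8.516e-01
RMSEA      7.079e-02 5.636e-02
SRMR       5.562e-02 4.405e-02
Chi-square 7.030e+03 3.556e+03
df         1.600e+02 1.260e+02
```

Freeing the 34 AR coefficients costs 34 df (160 → 126) and improves every
index: CFI 0.80 → 0.90, RMSEA 0.07 → 0.06, and lower AIC/BIC. The nested
comparison is decisive:

```r
likelihood_ratio_test(ic, ar)
#   delta_chi2 delta_df p_value delta_aic delta_bic nested
#      3474.77       34       0   3406.77   3166.87   TRUE
```

(Chi-squares here are plain ML on the printed 2-decimal correlations;
robust-scaled published chi-squares differ, the derived indices agree at
printed precision.)

Individual context effects are small but systematic, and fade
multiplicatively along AR paths:

```r
ar$theta["ar.e2.a2"]                       # 0.097 (SE 0.011)
path_effect(ar, c("e2", "a2", "c2"))       # 0.0089: two-step indirect effect
derived_group_mean(ar, c("ar.e2.a2", "ar.e3.a3", "ar.e4.a4"), label = "e->a")
#   label estimate      se    t  p_value
#    e->a    0.124 0.00983 12.6 3.06e-36
```

The positive e→a average says that endorsing an extraversion item nudges the
*next* agreeableness item's residual upward — consistent responding that the
latent traits cannot explain. Modeling it also sharpens discriminant
validity: the mean absolute factor correlation drops from 0.18 (IC-CFA) to
0.15 (AR-CFA).

```r
mc <- run_monte_carlo(sample_sizes = c(250, 500, 1000),
                      ar_values = c(0, 0.1, 0.2, 0.3),
                      replications = 100, seed = 1)
```

summarizes bias, RMSE, convergence and mean fit per cell: the AR-CFA is
unbiased even when the truth has no AR effects, while the IC-CFA inflates
factor correlations and loses fit as true AR effects grow.

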
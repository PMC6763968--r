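---
title: "Autoregressive CFA: model, estimation, and simulation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Autoregressive CFA: model, estimation, and simulation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(arcfa)
```

## The measurement model

When survey items are administered in a fixed order, answering an item can
change how the next items are answered: retrieving a memory or generating an
affective reaction primes the response to what follows, in ways unrelated to
the latent traits the scale is meant to measure. The ordinary
independent-clusters CFA (IC-CFA),

$$ y_i = \nu + \Lambda \eta_i + \varepsilon_i, \qquad
   \eta_i \sim \mathrm{MVN}(0, \Psi), \quad
   \varepsilon_i \sim \mathrm{MVN}(0, \Theta_{\mathrm{diag}}), $$

treats every such sequential dependency as misfit. The AR-CFA keeps the
independent-clusters loading structure but lets each item's residual depend
on the residuals of earlier items through a strictly lower-triangular matrix
$\kappa$ of autoregressive coefficients:

$$ y_i = \nu + \Lambda \eta_i + \varepsilon_i, \qquad
   \varepsilon_i = \kappa\,\varepsilon_i + u_i, \qquad
   u_i \sim \mathrm{MVN}(0, \Theta), $$

with implied covariance

$$ \Sigma \;=\; \Lambda \Psi \Lambda^\top \;+\;
   (I - \kappa)^{-1}\,\Theta\,(I - \kappa)^{-\top}. $$

Because $\kappa$ is strictly lower triangular in administration order,
$(I-\kappa)^{-1}$ exists for any coefficient values, has unit diagonal, and
its $(r, c)$ entry sums the products of AR coefficients along every directed
path from item $c$ to item $r$. Context effects therefore *fade*: a two-step
indirect effect is the product of two small coefficients
(`path_effect()`), which is exactly what distinguishes the AR-CFA from the
comparison model in which each AR term is replaced by a free residual
covariance (`build_rc_cfa()`) — same degrees of freedom, no fading.

Two AR topologies are built in. With items blocked by construct,
`"adjacent"` (one term per consecutive pair, $p-1$ terms) already carries
both within- and between-construct dependence. With constructs cycled — as
in the bundled 20-item Big Five layout — `"adjacent_plus_construct"` adds a
term from each item to the previous item of the same trait, so both the
immediate and the construct-specific channels are modeled (34 terms for the
20-item layout: 19 adjacent plus 15 within-trait). When a within-trait pair
is also adjacent the term is emitted once.

## Identification and parameterization choices

* **Unit factor variances.** Factors are identified by fixing their
  variances at 1 with all loadings free, so the $\Psi$ off-diagonals are
  factor correlations and the standardized solution is direct. Marker-item
  identification would give identical fit and df; only unstandardized
  estimates differ, and we report standardized output for comparability.
* **Covariance-only fitting.** Item intercepts are saturated and carry no
  testable information at the covariance level, so no mean structure is
  estimated.
* **Equality constraints by parameter sharing.** Entries with a common
  equality label occupy one slot of the free-parameter vector, so
  constraints are exact by construction rather than enforced by penalty.
* **Exemption rule for constraint schemes.** An AR term whose target item
  has no within-trait predecessor (the first administration cycle) is hit by
  a between-construct effect only, making its coefficient incomparable with
  later terms that absorb both channels; such terms stay free under both
  `by_type` and `by_type_and_scoring`. On the bundled layout this exempts
  four terms and gives 14 (10 trait-pair groups + 4) and 17 (13
  scoring-by-type cells + 4) free AR parameters respectively.
* **Start values.** Loadings start at $0.7\,\mathrm{SD}(y_j)$, factor
  correlations at 0.2, AR terms at 0, residual variances at half the item
  variance — conventional values that keep the initial $\Sigma$ positive
  definite.

## Estimation

The normal-theory discrepancy
$F = \ln|\Sigma| + \mathrm{tr}(S\Sigma^{-1}) - \ln|S| - p$ is minimized by a
quasi-Newton (PORT) run with analytic gradients, followed by safeguarded
Newton steps that finish the last digits (quasi-Newton codes stop on
relative progress, a hair short of a gradient tolerance). $\chi^2 =
(N-1)F_{\min}$, the Wishart convention; at the bundled example's $N = 8{,}569$
the $N$ vs $N-1$ choice is immaterial at printed precision.

Numerical safeguards, chosen where the method itself is silent:

* Residual variances travel on the log scale inside the optimizer, so
  $\Theta$'s diagonal stays positive. Convergence is declared on the
  internal-scale gradient (tolerance $10^{-6}$, maximum absolute
  component), where a boundary solution with a variance pinned at zero — a
  Heywood case — is a genuine stationary point; such solutions are flagged
  with a warning naming the offending variance. The equality-constrained
  `by_type` model on the bundled moments is exactly this case
  (`theta.o1` $\to 0$).
* $\Psi$ is kept admissible by an eigenvalue floor of $10^{-8}$ with a
  large-but-finite penalty rather than a hard failure, and any non-PD
  $\Sigma$ is an inadmissible point the optimizer retreats from, never a
  crash.
* $(I-\kappa)^{-1}$ is computed by forward substitution on the triangular
  system, never dense inversion; AR coefficients are unconstrained in sign
  and magnitude (fitted within-construct terms are frequently negative for
  alternately reverse-scored items).
* On failure to meet the tolerance the fit restarts from up to two jittered
  start vectors and keeps the best admissible solution; a fit that still
  fails is returned with `converged = FALSE` and a loud warning — never a
  silent success. Small samples (around 250) genuinely produce such
  failures for the AR-CFA, which is part of the method's documented
  behavior.

Standard errors come from the observed information, $((N-1)/2)$ times the
Hessian of $F$ at the optimum (central differences of the analytic
gradient, on the natural scale so no delta-method step is needed for the
log-parameterized variances). Averages of AR effects (`derived_group_mean()`)
use the delta method on the parameter covariance: for a mean
$a^\top\hat\theta$ the variance is $a^\top V a$. Individual parameters and
derived means are tested against a normal reference.

Nested models are compared by the plain likelihood-ratio difference
$\Delta\chi^2 = \chi^2_r - \chi^2_f$ on $\Delta df$ degrees of freedom,
after a structural nesting check (same layout, restricted free set a subset
of the full one, equality partition at least as fine). Robust
(Satorra-Bentler) corrections require raw-data fourth moments and are
deliberately not implemented; fitted to printed, 2-decimal moments, plain ML
chi-squares are therefore expected to differ from robust-scaled published
values even when the derived indices agree at printed precision. Non-nested
pairs — notably AR-CFA vs its equal-df residual-correlation
reparameterization — are refused the chi-square test and reported through
AIC/BIC differences only.

## Fit indices

CFI, TLI, RMSEA and SRMR use their standard formulas (see `?fit_indices`);
CFI is clamped to $[0,1]$ and TLI capped at 1 unless `clamp_tli = FALSE`.
SRMR is the root mean square of residual correlations *including* the
diagonal by default; the off-diagonal-only dialect sits behind
`srmr_diagonal = FALSE`, and on the bundled moments both land on the same
two-decimal values. AIC and BIC use the multivariate-normal covariance
likelihood without a mean block, so absolute values differ from software
that includes a saturated mean structure; differences and orderings between
models fitted to the same moments are the supported contract.

## What the simulator emulates — and what it does not

`make_population()` builds the generating model the way simulation studies
in this literature conventionally do: all standardized loadings 0.8, all
factor correlations 0.2, every AR coefficient of the chosen topology set to
one common value (0 to 0.3), and innovation variances solved in
administration order so every item variance is exactly 1. The solve is
sequential because earlier items' innovations reach later items through
$(I-\kappa)^{-1}$; combinations that leave no room under unit variance (say
a loading of 1 with nonzero AR) error out rather than producing a
non-positive variance.

`simulate_dataset()` draws continuous multivariate-normal responses;
`likert = 5` optionally discretizes through equal-probability normal
thresholds. Continuous generation is the default because it is the cleanest
recovery surface for studying the estimator itself; real Likert items add
coarseness and threshold asymmetries the generator does not emulate, along
with every other feature of real respondents (person-specific AR strength,
fatigue trends, cluster structure). Passing recovery tests therefore shows
the estimator is correct under its own assumptions, not that real scales
satisfy them.

`run_monte_carlo()` crosses sample sizes (250/500/1000 are the conventional
grid) with true AR values (0 to 0.3), derives per-replication seeds
deterministically from one master seed, and summarizes bias, RMSE,
convergence rate, and mean CFI/RMSEA per cell and model. The default is 500
replications per cell; 100 is the documented reduced desk-scale mode used in
the package's own acceptance checks, where sampling error on the summaries
is still a few thousandths for bias at $N = 1000$. Non-converged
replications are excluded from bias/RMSE and counted against the convergence
rate. The acceptance suite checks the two qualitative findings this design
is built to expose: the AR-CFA is unbiased even when the truth has no AR
effects (no-harm), and the IC-CFA inflates factor correlations and degrades
CFI/RMSEA as true AR effects grow.

## Degenerate inputs and edge behavior

Moment matrices must be symmetric within $10^{-9}$ (lower-triangle input is
mirrored exactly) and positive definite — violations are hard errors that
report the offending eigenvalue, and the smallest eigenvalue of a loaded $S$
is kept on the object for diagnosis. Raw data get listwise deletion with a
logged count, a named error for zero-variance columns, and optional
group-mean centering that removes cluster fixed effects. A saturated spec
(df = 0) fits with $F_{\min} = 0$ and has RMSEA/TLI reported as
not-applicable; over-parameterized specs (negative df) error at
`model_df()`.

## Known limitations

* Only first-order AR structures among residuals: no higher-order AR,
  moving-average, or ARMA residual processes.
* No cross-loading specifications, ESEM rotation, or Bayesian estimation
  (shrinkage priors, PPP/DIC); no robust corrections or missing-data FIML;
  items are treated as continuous under ML.
* A single shared administration order: person-specific AR matrices for
  randomized item orders are out of scope.
* The bundled example stores published moments at 2-decimal precision, so
  refit statistics are expected to match published values at printed
  precision, not beyond.
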
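---
title: "Methods: constrained polynomial model comparison for trait-outcome surfaces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: constrained polynomial model comparison for trait-outcome surfaces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polycomp)
```

## The statistical model

All candidate models are restrictions of the full second-order polynomial
in two centered predictors,

$$L_i = b_0 + b_1 E_i + b_2 N_i + b_3 E_i^2 + b_4 E_i N_i + b_5 N_i^2 + \varepsilon_i,
\qquad \varepsilon_i \sim \mathcal N(0, \sigma^2),$$

where $E$ is extraversion, $N$ is neuroticism and $L$ a loneliness score.
In the longitudinal variant the follow-up outcome is regressed on the same
surface plus the baseline outcome with a freely estimated slope, so that
the surface describes *change* in loneliness conditional on its baseline
level.

Before fitting, all bounded instrument scores are linearly mapped to a
common 1–7 range by proportion-of-maximum scaling (POMS),
$x \mapsto 1 + 6\,(x - \min)/(\max - \min)$, using the instrument's
*theoretical* bounds — only those guarantee that a score that attains its
scale bounds maps exactly onto 1 and 7. The traits are then centered at
their sample means (the outcome is not centered). Both steps are affine,
so $R^2$, likelihood-ratio statistics, and all information-theoretic
quantities are unchanged by them; only the coefficient metric is fixed to
a common, interpretable scale.

## From hypotheses to constraint systems

Each substantive hypothesis is encoded as a set of *zero restrictions*,
*equality ties*, and *linear inequality constraints* on $b_1,\dots,b_5$.
Writing the trait slopes as
$s_E(e, n) = b_1 + 2 b_3 e + b_4 n$ and $s_N(e, n) = b_2 + b_4 e + 2 b_5 n$,
and $(e_{lo}, e_{hi}, n_{lo}, n_{hi})$ for the observed range box of the
centered traits, the main-effect shapes are (extraversion protective,
neuroticism a risk factor; all shape models fix $b_4 = 0$):

| shape | constraints | logic |
|---|---|---|
| linear E | $b_3 = 0$, $b_1 \le 0$ | constant negative slope |
| saturating E | $b_3 \ge 0$, $b_1 + 2 b_3 e_{hi} \le 0$ | decreasing, flattest at high E; the corner condition pins the *flattest* point of the slope, so monotonicity holds across the whole box |
| exponential E | $b_3 \le 0$, $b_1 + 2 b_3 e_{lo} \le 0$ | decreasing, steepest at high E |
| linear N | $b_5 = 0$, $b_2 \ge 0$ | constant positive slope |
| saturating N | $b_5 \le 0$, $b_2 + 2 b_5 n_{hi} \ge 0$ | increasing, flattest at high N |
| exponential N | $b_5 \ge 0$, $b_2 + 2 b_5 n_{lo} \ge 0$ | increasing, steepest at high N |

Anchoring the corner conditions to the *observed* range box — rather than
to, say, ±2 SD — makes "monotone over all realistic trait values" a
property of the data at hand; the box is recomputed for every dataset and
the catalogue is rebuilt from it.

The two interaction hypotheses are one-parameter surfaces:

* **Mutual compensation**: $L = b_0 + c\,(E - e_{hi})(N - n_{lo})$ with
  $c \le 0$. The outcome sits at baseline whenever $E$ is maximal *or*
  $N$ is minimal, and is elevated only when both protective levels are
  absent; expanding the product gives the equality ties
  $b_1 = -c\,n_{lo}$, $b_2 = -c\,e_{hi}$, $b_4 = c$, $b_3 = b_5 = 0$.
* **Optimal constellation**: $L = b_0 + c\,(E - e_{lo})(N - n_{hi})$ with
  $c \ge 0$; the outcome is lowered only in the high-E/low-N corner, and
  the implied interaction is positive.

The catalogue is completed by the Null and Full models, the three
single-trait shapes per trait, and the full $3 \times 3$ grid of two-trait
shape combinations — 19 models in all. The two grid cells that carry no
named substantive hypothesis (saturating–saturating and
exponential–exponential) are included because information-theoretic
comparison requires the candidate set to be *complete*: omitting a
plausible pattern silently redistributes its evidence over the remaining
models.

Two accounting conventions matter for reproducing published tables:

* $K$ counts the intercept, every free (or merely sign-constrained)
  coefficient, and the residual variance. A parameter restricted only by a
  direction inequality still counts as free, and $K$ is *not* reduced when
  an estimate lands on a constraint boundary.
* The nesting relation is decided structurally (zero-set containment plus
  shape implication: none ⊂ linear ⊂ {saturating, exponential} ⊂ free;
  the composite interaction surfaces nest only the Null model and are
  nested only in the Full model). This matches feasible-set containment
  for this fixed catalogue and is transitively closed by construction.

## Estimation

For fixed regression coefficients the Gaussian likelihood profiles to a
least-squares criterion, and each model's zero restrictions and equality
ties are absorbed into a linear map from its free parameters to
$(b_0,\dots,b_5)$. Estimation therefore reduces to least squares under at
most four linear inequality constraints — a tiny convex quadratic program.
It is solved *exactly* by enumerating active sets: for every subset of
constraints the KKT system is solved, and the feasible, dual-feasible
solution with the smallest residual sum of squares is the global optimum.
There is no iterative optimizer, no starting value and no convergence
tolerance to tune; fits are deterministic and reproducible to machine
precision. Active constraints are reported on the fit object.

**Missing follow-up outcomes.** Predictors and the baseline outcome are
treated as completely observed; a person missing only the follow-up
outcome contributes a marginal trait-likelihood term that is identical
across all candidate models and therefore cancels from every likelihood
difference, weight and ratio. The maximized log-likelihood is accordingly
computed over complete cases, while `n_obs` — the sample size used by the
AICc small-sample correction — counts *all* retained persons. With zero
missingness the longitudinal fit coincides exactly with complete-case
least squares.

Residual variance uses the maximum-likelihood divisor (complete-case $m$,
not $m - p$), which is what makes $\mathrm{LL}$ comparable across models
with different $K$. Adjusted $R^2$ uses
$1 - (1 - R^2)(m - 1)/(m - p - 1)$ with $p = K - 2$ free slopes (the
composite interaction surfaces count $p = 1$).

Robust (sandwich) standard errors are deliberately omitted: they alter no
likelihood, AICc or weight, and the package's inferential currency is the
model comparison, not per-coefficient Wald tests. Plain
observed-information standard errors are attached for convenience and
should be read with care when a constraint is active.

## Model comparison

* $\mathrm{AICc} = -2\mathrm{LL} + 2K + 2K(K+1)/(n - K - 1)$ with
  $n = $ `n_obs` (all retained persons, in both the cross-sectional and
  longitudinal analyses).
* **Redundancy pruning.** When a model's maximized log-likelihood exceeds
  that of a model nested within it by less than 1, its extra parameters
  buy essentially no fit and it is excluded before weights are computed.
  Models are processed by increasing $K$ (ties broken by catalogue
  order), each retained simpler model eliminating every more complex
  model nesting it that fails the threshold — this makes the rule
  deterministic and handles chains (a chain with gains of 0.2 at each
  step collapses to its simplest member). Exclusions are logged with the
  triggering pair, never silent.
* **Akaike weights** are normalized $\exp(-\Delta_i/2)$ over the retained
  set; the **95% confidence set** is the smallest AICc-ordered prefix
  whose cumulative weight exceeds 0.95. Weights are reported over the
  full retained set by default; `renormalize = TRUE` adds weights
  renormalized within the confidence set, the convention used when a
  published table lists only the set itself. Published tables exist in
  both conventions, which is why both are available but the full-set
  weights are the default.

## Response-surface interpretation

When the Full Model earns a place in the confidence set, its coefficients
are read through response-surface methodology: slope and curvature along
the congruence line $E = N$ ($a_1 = b_1 + b_2$, $a_2 = b_3 + b_4 + b_5$)
and along the incongruence line $E = -N$ ($a_3 = b_1 - b_2$,
$a_4 = b_3 - b_4 + b_5$). Predictions are evaluated exactly on a grid over
the range box, and every grid point is masked by whether it falls inside
the convex hull of the observed trait pairs: the hull is a reproducible,
assumption-free stand-in for the bag-and-fence constructions sometimes
drawn under such surfaces, and it serves the same purpose — a fitted
quadratic extrapolates wildly outside the data region, so no
interpretation is offered there. The stationary point is reported only
when the curvature determinant exceeds $10^{-8}$; otherwise it is flagged
undefined rather than divided out of a near-singular system.

Per-trait shape classification evaluates the trait's slope at both ends of
the range box (at the mean of the other trait). No curvature (below
$10^{-8}$) is *linear*; a monotone slope whose magnitude grows towards
higher trait levels is *exponential*, one that shrinks is *saturating*;
a slope reversal inside the box is *non-monotone*, in which case the
fraction of observed persons on each side of the vertex is reported. The
per-person convention (rather than grid area) is used for that split
because statements like "a positive effect for 89% of participants" are
claims about persons; it weights the reversal by where people actually
sit on the trait.

## Influence screening

Influence is screened on the full polynomial (the most flexible model, so
diagnostics are not confounded with lack of fit) using the three standard
indicators with their conventional cutoffs: $|\mathrm{DFFITS}| >
2\sqrt{p/n}$, Cook's $D > 4/n$, leverage $h > 2p/n$ ($p = 6$ design
columns). A case is flagged when it combines high leverage with at least
one high influence indicator — leverage alone marks unusual trait
combinations, not harmful ones, and a single influence indicator without
leverage is usually a benign large residual near the centroid. The exact
conjunction used in any given published analysis is rarely printed; this
joint rule is the package's documented convention. Flagged cases are
reported with all three statistics and are never removed automatically.

## Power analysis

The omnibus gate — full versus null, 5 degrees of freedom — determines
whether any catalogue comparison is warranted, so its a-priori power is
the planning quantity. `simulate_power()` draws standard bivariate-normal
traits at the configured correlation, scales a coefficient pattern so the
*population* $R^2$ hits its target exactly (the design covariance of
$(E, N, E^2, EN, N^2)$ is available in closed form from the normal moment
identities, e.g. $\mathrm{Var}(E^2) = 2$, $\mathrm{Var}(EN) = 1 + \rho^2$,
$\mathrm{Cov}(E^2, EN) = 2\rho$), adds unit-variance noise and applies the
same chi-square LR test the pipeline gates on. The noncentral-F
distribution with $\lambda = nR^2/(1-R^2)$ is the analytic oracle; at the
study's sample sizes the LR and F tests agree to a few parts in a
thousand.

The default pattern puts everything on the main effects ($-1 : 1$).
Because the omnibus noncentrality depends on the total $R^2$ only, the
pattern choice is nearly immaterial: across main-effect, pure-curvature
and mixed patterns the simulated power at $n = 237$, $R^2 = 0.10$ stays
within about one percentage point of the oracle. The residual sensitivity
is real — quadratic regressors are heavy-tailed, so the realized
per-sample $R^2$ varies more under curvature-heavy patterns, costing a
fraction of a point of power — and is why the package's tests hold
non-default patterns to a 0.02 band rather than to Monte-Carlo error.

## The synthetic cohort generator

`generate_cohort()` emulates the cohort structure the analysis assumes:

* traits bivariate normal; defaults $E$: 4.69 (SD 0.95), $N$: 3.87
  (SD 1.07), $r_{EN} = -0.31$ on the common 1–7 scale, matching the
  descriptive moments of the smaller study cohort;
* the baseline outcome is a catalogue surface evaluated at
  population-centered traits plus Gaussian noise (default baseline 2.2,
  residual SD 0.8);
* the follow-up outcome shares the surface and carries over a
  configurable fraction (default 0.6, within the 0.47–0.71 range of
  observed one-year retest correlations) of the baseline residual, then
  goes missing completely at random at the configured rate (default
  45.57%, the larger of the two observed dropout rates; 18.21% mirrors
  the panel cohort). An optional logistic dependence of dropout on
  extraversion, with the marginal rate preserved, supports robustness
  experiments mimicking trait-dependent attrition;
* with `clip = TRUE` (default) traits and outcomes are truncated to the
  1–7 bounds and the clipped fraction is recorded. Recovery experiments
  use `clip = FALSE`: truncation moves the data off the generating
  surface, which is realistic but makes "is the generator recovered?"
  ill-posed.

What the generator does **not** emulate — and what passing recovery tests
therefore cannot certify about real data: item-level response processes
and measurement error (scores are treated as error-free continuous
values), the left-skew of real loneliness distributions beyond what
clipping induces, systematically missing-not-at-random dropout, and any
clustering (schools, waves). Recovery results should be read as "the
pipeline recovers what it assumes", a necessary but not sufficient
condition.

Canonical generating coefficients per model
(`generating_coefficients()`) use linear slopes $\mp 0.4$, quadratic
magnitudes 0.04 and composite interaction strength 0.1, chosen once so
that every model's own corner constraints hold strictly over a ±4-SD
centered trait range.

## Numerical choices and degenerate inputs

* Active-set solver: feasibility tolerance $10^{-9}$ (relative), dual
  feasibility at the same scale; a singular KKT subset is skipped, and an
  entirely infeasible system raises an error naming the model.
* Equality restrictions in `shape_predicate()` are checked as distance of
  the coefficient vector from the model's linear subspace, tolerance
  $10^{-8}$.
* Fewer than 10 rows, an all-missing column, a degenerate range box, a
  singular full design, out-of-bounds instrument scores, and
  `n <= K + 1` in the AICc correction all raise immediate, named errors
  rather than propagating nonsense.
* Noiseless data (zero residual variance) keep valid coefficients but an
  infinite log-likelihood; such fits are usable for geometry but
  excluded from information-theoretic comparison by the finiteness check
  in `akaike_weights()`.
* Problem sizes used by the test suite: recovery at $n = 2000$ with 200
  replicates per generating model, model recovery at $n = 1000$ with 200
  replicates, gate calibration at $n = 300$ with 3000 replicates, power
  at 10,000 replicates — sizes at which Monte-Carlo error is far below
  every asserted margin.

## Known limitations

* The catalogue is fixed by design; a user-defined hypothesis grammar is
  out of scope.
* FIML here is the conditional-likelihood variant: only the outcome may
  be missing. Missing predictors would require a joint trait-outcome
  model and are rejected at ingest instead.
* Sign-constrained parameters count as free in $K$; alternative
  conventions (e.g. mixture-of-chi-square accounting at boundaries) would
  shift AICc by fractions of a point for boundary solutions.
* The confidence-set construction is the cumulative-weight prefix rule;
  it inherits that rule's known conservatism when many models tie.
* Observed-information standard errors ignore active constraints; treat
  them as descriptive.
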